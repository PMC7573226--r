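# Maximum-likelihood fitting of the M-series site models, LRTs and
# empirical Bayes site identification.

# ---- parameter transforms -------------------------------------------------
# Free parameters live on an unconstrained (log / logit / stick-breaking)
# scale; bounds below keep the optimizer inside numerically safe territory:
# kappa in [0.01, 50], omega <= 50, beta shapes in [0.005, 99].

.LK_B <- log(c(0.01, 50))
.LS_B <- log(c(1e-3, 1e3))
.LO_B <- log(c(1e-4, 50))
.Z_B <- c(-30, 30)
.LPQ_B <- log(c(0.005, 99))
.LWS_B <- log(c(1e-3, 49))

.free_spec <- function(model) {
  name <- model@name
  K3 <- if (name == "M3") {
    if (!is.null(model@params$omegas)) length(model@params$omegas) else 3L
  } else 0L
  base_n <- c("logKappa", "logScale")
  base_l <- c(.LK_B[1], .LS_B[1]); base_u <- c(.LK_B[2], .LS_B[2])
  spec <- switch(name,
    M0 = list(n = "logOmega", l = .LO_B[1], u = .LO_B[2]),
    M1a = list(n = c("zP0", "zOmega0"), l = rep(.Z_B[1], 2), u = rep(.Z_B[2], 2)),
    M2a = list(n = c("zP0", "zP1", "zOmega0", "logOmega2m1"),
               l = c(rep(.Z_B[1], 3), .LWS_B[1]),
               u = c(rep(.Z_B[2], 3), .LWS_B[2])),
    M3 = list(n = c(paste0("zW", seq_len(K3 - 1L)), paste0("logOm", seq_len(K3))),
              l = c(rep(.Z_B[1], K3 - 1L), rep(.LO_B[1], K3)),
              u = c(rep(.Z_B[2], K3 - 1L), rep(.LO_B[2], K3))),
    M7 = list(n = c("logP", "logQ"), l = rep(.LPQ_B[1], 2), u = rep(.LPQ_B[2], 2)),
    M8 = list(n = c("zP0", "logP", "logQ", "logOmegaSm1"),
              l = c(.Z_B[1], rep(.LPQ_B[1], 2), .LWS_B[1]),
              u = c(.Z_B[2], rep(.LPQ_B[2], 2), .LWS_B[2])),
    M8a = list(n = c("zP0", "logP", "logQ"),
               l = c(.Z_B[1], rep(.LPQ_B[1], 2)),
               u = c(.Z_B[2], rep(.LPQ_B[2], 2))))
  list(names = c(base_n, spec$n), lower = c(base_l, spec$l),
       upper = c(base_u, spec$u), K3 = K3)
}

# free vector -> list(kappa, scale, model with params set, natural named vec)
.free_to_natural <- function(free, model, fs) {
  name <- model@name
  kappa <- exp(free[1L]); scale <- exp(free[2L])
  r <- free[-(1:2)]
  prm <- switch(name,
    M0 = list(omega = exp(r[1L])),
    M1a = list(p0 = stats::plogis(r[1L]),
               omega0 = stats::plogis(r[2L])),
    M2a = {
      p0 <- stats::plogis(r[1L]); p1 <- (1 - p0) * stats::plogis(r[2L])
      list(p0 = p0, p1 = p1, omega0 = stats::plogis(r[3L]),
           omega2 = 1 + exp(r[4L]))
    },
    M3 = {
      K <- fs$K3
      z <- r[seq_len(K - 1L)]
      w <- numeric(K); rem <- 1
      for (i in seq_len(K - 1L)) {
        w[i] <- rem * stats::plogis(z[i]); rem <- rem - w[i]
      }
      w[K] <- rem
      list(weights = w, omegas = exp(r[K - 1L + seq_len(K)]))
    },
    M7 = list(p = exp(r[1L]), q = exp(r[2L])),
    M8 = list(p0 = stats::plogis(r[1L]), p = exp(r[2L]), q = exp(r[3L]),
              omegaS = 1 + exp(r[4L])),
    M8a = list(p0 = stats::plogis(r[1L]), p = exp(r[2L]), q = exp(r[3L])))
  m2 <- new("SiteClassModel", name = name, params = prm, ncat = model@ncat)
  nat <- c(kappa = kappa, treeScale = scale, unlist(prm))
  list(kappa = kappa, scale = scale, model = m2, natural = nat)
}

# natural start values -> free vector
.natural_to_free <- function(start, model, fs) {
  name <- model@name
  clamp <- function(x, b) pmin(pmax(x, b[1] + 1e-9), b[2] - 1e-9)
  f <- c(clamp(log(start$kappa), .LK_B), clamp(log(start$treeScale), .LS_B))
  f <- c(f, switch(name,
    M0 = clamp(log(start$omega), .LO_B),
    M1a = c(stats::qlogis(start$p0), stats::qlogis(start$omega0)),
    M2a = c(stats::qlogis(start$p0),
            stats::qlogis(start$p1 / (1 - start$p0)),
            stats::qlogis(start$omega0),
            clamp(log(start$omega2 - 1), .LWS_B)),
    M3 = {
      w <- start$weights; K <- fs$K3
      z <- numeric(K - 1L); rem <- 1
      for (i in seq_len(K - 1L)) {
        z[i] <- stats::qlogis(w[i] / rem); rem <- rem - w[i]
      }
      c(z, clamp(log(start$omegas), .LO_B))
    },
    M7 = clamp(log(c(start$p, start$q)), .LPQ_B),
    M8 = c(stats::qlogis(start$p0), clamp(log(c(start$p, start$q)), .LPQ_B),
           clamp(log(start$omegaS - 1), .LWS_B)),
    M8a = c(stats::qlogis(start$p0), clamp(log(c(start$p, start$q)), .LPQ_B))))
  pmin(pmax(f, fs$lower + 1e-8), fs$upper - 1e-8)
}

# three deterministic multi-start tables per model
.default_starts <- function(name) {
  common <- list(list(kappa = 2, treeScale = 1),
                 list(kappa = 4, treeScale = 0.5),
                 list(kappa = 1, treeScale = 2))
  extras <- switch(name,
    M0 = list(list(omega = 0.3), list(omega = 0.05), list(omega = 1.2)),
    M1a = list(list(p0 = 0.7, omega0 = 0.1), list(p0 = 0.5, omega0 = 0.3),
               list(p0 = 0.9, omega0 = 0.05)),
    M2a = list(list(p0 = 0.6, p1 = 0.3, omega0 = 0.1, omega2 = 2),
               list(p0 = 0.45, p1 = 0.45, omega0 = 0.3, omega2 = 4),
               list(p0 = 0.8, p1 = 0.15, omega0 = 0.05, omega2 = 1.5)),
    M3 = list(list(weights = rep(1 / 3, 3), omegas = c(0.1, 0.5, 1.5)),
              list(weights = c(0.5, 0.3, 0.2), omegas = c(0.05, 0.3, 2)),
              list(weights = c(0.2, 0.5, 0.3), omegas = c(0.2, 1, 3))),
    M7 = list(list(p = 0.5, q = 2), list(p = 1, q = 1), list(p = 2, q = 5)),
    M8 = list(list(p0 = 0.9, p = 0.5, q = 2, omegaS = 3),
              list(p0 = 0.7, p = 1, q = 1, omegaS = 5),
              list(p0 = 0.95, p = 2, q = 5, omegaS = 1.5)),
    M8a = list(list(p0 = 0.9, p = 0.5, q = 2), list(p0 = 0.7, p = 1, q = 1),
               list(p0 = 0.95, p = 2, q = 5)))
  Map(c, common, extras)
}

# ---- fitting ---------------------------------------------------------------

#' Fit a codon site-class model by maximum likelihood
#'
#' Maximizes the mixture log-likelihood
#' \eqn{\sum_s \log \sum_k w_k L_s(\omega_k)} over the model parameters,
#' `kappa`, and (by default) a single multiplier rescaling all input branch
#' lengths; optionally all branch lengths are optimized.  Optimization uses
#' bounded quasi-Newton (L-BFGS-B) on transformed parameters from three
#' deterministic starting points, reporting the best.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree Rooted [ape::phylo] with branch lengths; the topology is
#'   taken as fixed.
#' @param model A [SiteClassModel-class] (parameters optional; used as a
#'   starting point when supplied).
#' @param frequencies `"F3x4"` (default), `"F61"`, or a length-61 numeric.
#' @param nstarts Number of deterministic multi-starts (1-3, default 3).
#' @param start Optional named list of natural-scale starting values
#'   (`kappa`, `treeScale`, plus model parameters), or a list of such
#'   lists; every supplied start is run in addition to the defaults (with
#'   explicit starts, `nstarts` may be 0).
#' @param optimizeBranches If `TRUE`, optimize every branch length instead
#'   of a single tree scale factor (slower).
#' @param control Passed to [stats::optim()] (defaults: `maxit = 500`,
#'   `factr = 1e7`).
#' @return A [CodonSiteFit-class].  Non-convergence is flagged in the
#'   `convergence` slot, never silent.
#' @export
fitSiteModel <- function(aln, tree, model,
                         frequencies = "F3x4",
                         nstarts = 3L, start = NULL,
                         optimizeBranches = FALSE,
                         control = list()) {
  stopifnot(is(model, "SiteClassModel"))
  pd <- .prepare_pruning_data(aln, tree)
  pi <- if (is.numeric(frequencies)) .check_pi(frequencies)
        else switch(match.arg(frequencies, c("F3x4", "F61")),
                    F3x4 = codonFrequenciesF3x4(aln),
                    F61 = codonFrequenciesF61(aln))
  fs <- .free_spec(model)
  cnt <- pd$patternCount
  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)

  nb <- nrow(pd$edge)
  lower <- fs$lower; upper <- fs$upper
  if (optimizeBranches) {
    lower <- c(lower, rep(log(1e-8), nb))
    upper <- c(upper, rep(log(100), nb))
  }

  objective <- function(free) {
    nat <- .free_to_natural(free[seq_along(fs$names)], model, fs)
    mix <- tryCatch(classWeightsOmegas(nat$model), error = function(e) NULL)
    if (is.null(mix)) return(1e10)
    elen <- if (optimizeBranches) exp(free[-seq_along(fs$names)])
            else pd$elen * nat$scale
    ll <- .class_loglik(pd, nat$kappa, mix$omegas, pi, elen = elen)
    lw <- log(mix$weights)
    lw[mix$weights == 0] <- -Inf
    pll <- .logsumexp_rows(sweep(ll, 2L, lw, "+"))
    val <- -sum(cnt * pll)
    if (!is.finite(val)) 1e10 else val
  }

  starts <- .default_starts(model@name)
  # a user-supplied model with complete parameters seeds the first start
  if (all(.model_param_names(model@name) %in% names(model@params)))
    starts[[1L]] <- utils::modifyList(starts[[1L]], model@params)
  # explicit starts (e.g. warm starts from a nested null) are all run, in
  # addition to `nstarts` default starts; with explicit starts nstarts
  # may be 0
  extra <- list()
  if (!is.null(start)) {
    if (!is.list(start[[1L]])) start <- list(start)
    extra <- lapply(start, function(s) utils::modifyList(starts[[1L]], s))
  }
  nstarts <- min(max(as.integer(nstarts), if (length(extra)) 0L else 1L),
                 length(starts))
  starts <- c(extra, starts[seq_len(nstarts)])
  nstarts <- length(starts)

  # forward-difference gradient memoizing the objective at the base point
  # (halves the evaluation count relative to optim's central differences)
  memo <- new.env(parent = emptyenv())
  obj_memo <- function(free) {
    v <- objective(free)
    memo$par <- free; memo$val <- v
    v
  }
  grad <- function(free) {
    f0 <- if (!is.null(memo$par) && isTRUE(all.equal(memo$par, free,
                                                     tolerance = 0)))
      memo$val else objective(free)
    h <- 1e-6 * pmax(abs(free), 1)
    vapply(seq_along(free), function(i) {
      fp <- free; fp[i] <- min(fp[i] + h[i], upper[i])
      hi <- fp[i] - free[i]
      if (hi == 0) { fp[i] <- free[i] - h[i]; hi <- -h[i] }
      (objective(fp) - f0) / hi
    }, numeric(1))
  }

  best <- NULL; trace <- numeric(0)
  for (i in seq_len(nstarts)) {
    f0 <- .natural_to_free(starts[[i]], model, fs)
    if (optimizeBranches) f0 <- c(f0, log(pmax(pd$elen, 1e-6)))
    opt <- stats::optim(f0, obj_memo, gr = grad, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctrl$maxit, factr = ctrl$factr))
    trace <- c(trace, -opt$value)
    if (is.null(best) || opt$value < best$value) {
      best <- opt; best$start_index <- i
    }
  }

  nat <- .free_to_natural(best$par[seq_along(fs$names)], model, fs)
  mix <- classWeightsOmegas(nat$model)
  elen <- if (optimizeBranches) exp(best$par[-seq_along(fs$names)])
          else pd$elen * nat$scale
  ll <- .class_loglik(pd, nat$kappa, mix$omegas, pi, elen = elen)
  sll <- ll[pd$patternIdx, , drop = FALSE]
  npar <- length(fs$names) + if (optimizeBranches) nb - 1L else 0L

  new("CodonSiteFit",
      model = nat$model,
      logLik = -best$value,
      params = nat$natural,
      weights = mix$weights,
      omegas = mix$omegas,
      siteClassLogLik = sll,
      pi = unname(pi),
      npar = as.integer(npar),
      convergence = list(converged = best$convergence == 0L,
                         code = best$convergence,
                         message = best$message,
                         counts = best$counts,
                         startLogLik = trace,
                         startIndex = best$start_index),
      data = c(pd, list(elen_fitted = elen, optimizeBranches = optimizeBranches)))
}

# profile the positive-selection class against a fitted null: optimize
# only (class weight, class omega) with every other parameter held at the
# null MLE, reusing the null's cached per-class site log-likelihoods.
# Cheap (one-class pruning per evaluation) and gives the full optimizer a
# near-converged interior start.
.seed_positive_class <- function(nullFit, baseCols) {
  pd <- nullFit@data
  pars <- as.list(nullFit@params)
  base_ll <- nullFit@siteClassLogLik[, baseCols, drop = FALSE]
  baseW <- nullFit@weights[baseCols]
  baseW <- baseW / sum(baseW)
  cache <- new.env(parent = emptyenv())
  objfn <- function(par) {
    w2 <- stats::plogis(par[1L])
    key <- sprintf("%.12g", par[2L])
    llpos <- cache[[key]]
    if (is.null(llpos)) {
      ws <- 1 + exp(par[2L])
      llpos <- .class_loglik(pd, pars$kappa, ws, nullFit@pi,
                             elen = pd$elen_fitted)[pd$patternIdx, 1L]
      cache[[key]] <- llpos
    }
    lw <- log(c(baseW * (1 - w2), w2))
    v <- -sum(.logsumexp_rows(sweep(cbind(base_ll, llpos), 2L, lw, "+")))
    if (!is.finite(v)) 1e10 else v
  }
  # two profile starts: a small extreme class and a larger mild class —
  # the profile surface is often bimodal in (weight, omega)
  best <- NULL
  for (p0s in list(c(stats::qlogis(0.1), log(2)),
                   c(stats::qlogis(0.3), log(0.5)))) {
    opt <- stats::optim(p0s, objfn, method = "L-BFGS-B",
                        lower = c(-30, log(1e-3)), upper = c(30, log(49)),
                        control = list(maxit = 60L, factr = 1e9))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(weight = stats::plogis(best$par[1L]), omega = 1 + exp(best$par[2L]))
}

# map a fitted null model's MLE to starts for its nesting alternative.
# Two starts per nesting: a boundary start sitting (numerically) at the
# null's optimum, so sequential fitting can only improve on the null
# log-likelihood, and an interior start whose positive class has been
# pre-optimized by .seed_positive_class so the optimizer has a gradient
# to follow and little distance to cover.
.warm_start_from <- function(nullFit, altName) {
  p <- as.list(nullFit@params)
  K <- nullFit@model@ncat
  base <- list(kappa = p$kappa, treeScale = p$treeScale)
  switch(paste(nullFit@model@name, altName, sep = ">"),
    "M7>M8" = {
      sd <- .seed_positive_class(nullFit, seq_len(K))
      list(c(base, list(p = p$p, q = p$q, p0 = 1 - 1e-13, omegaS = 2)),
           c(base, list(p = p$p, q = p$q,
                        p0 = min(max(1 - sd$weight, 1e-6), 1 - 1e-6),
                        omegaS = max(sd$omega, 1.001))))
    },
    "M8a>M8" = {
      sd <- .seed_positive_class(nullFit, seq_len(K))
      list(c(base, list(p0 = p$p0, p = p$p, q = p$q, omegaS = 1.001)),
           c(base, list(p0 = min(max(1 - sd$weight, 1e-6), 1 - 1e-6),
                        p = p$p, q = p$q, omegaS = max(sd$omega, 1.001))))
    },
    "M1a>M2a" = {
      sd <- .seed_positive_class(nullFit, 1:2)
      w2 <- min(max(sd$weight, 1e-6), 0.98)
      list(c(base, list(p0 = p$p0, p1 = (1 - p$p0) * (1 - 1e-13),
                        omega0 = p$omega0, omega2 = 1.001)),
           c(base, list(p0 = p$p0 * (1 - w2), p1 = (1 - p$p0) * (1 - w2),
                        omega0 = p$omega0, omega2 = max(sd$omega, 1.001))))
    },
    "M0>M3" = list(
      c(base, list(weights = c(1 - 2e-13, 1e-13, 1e-13),
                   omegas = rep(max(p$omega, 1e-4), 3))),
      c(base, list(weights = c(0.5, 0.4, 0.1),
                   omegas = c(max(p$omega, 1e-4) / 2,
                              max(p$omega, 1e-4), 2)))),
    NULL)
}

#' Fit a hierarchy of site-class models
#'
#' Fits the requested models in order, warm-starting each alternative from
#' the maximum-likelihood estimates of any already-fitted nested null
#' (M0 in M3, M1a in M2a, M7 in M8, M8a in M8) in addition to the default
#' deterministic starts.  Sequential nested fitting both speeds up the
#' alternative fits and guarantees the log-likelihood ordering of nested
#' models in practice.
#'
#' @inheritParams fitSiteModel
#' @param models Character vector of model names, e.g. `c("M7", "M8")`.
#' @param ... Passed on to [fitSiteModel()].
#' @return Named list of [CodonSiteFit-class] objects.
#' @export
fitSiteModelSeries <- function(aln, tree, models = c("M7", "M8"),
                               nstarts = 3L, ...) {
  fits <- list()
  for (m in models) {
    warm <- list()
    for (pair in .nested_pairs)
      if (pair[2L] == m && pair[1L] %in% names(fits))
        warm <- c(warm, .warm_start_from(fits[[pair[1L]]], m))
    # alternatives keep at least one default start besides the warm
    # starts: the warm starts inherit the null's beta shape, which can
    # pin the fit to a local optimum when the alternative reshapes it
    fits[[m]] <- fitSiteModel(aln, tree, siteClassModel(m),
                              nstarts = if (length(warm)) max(nstarts - 1L, 1L)
                                        else nstarts,
                              start = if (length(warm)) warm else NULL, ...)
  }
  fits
}

# ---- likelihood-ratio tests -----------------------------------------------

.nested_pairs <- list(c("M0", "M3"), c("M1a", "M2a"), c("M7", "M8"),
                      c("M8a", "M8"))

#' Likelihood-ratio test between nested site models
#'
#' Compares `2 (lnL_alt - lnL_null)` with a chi-squared reference whose
#' degrees of freedom equal the difference in free parameter counts.
#' Supported nestings: M0 in M3, M1a in M2a, M7 in M8, M8a in M8.  For
#' M8a vs M8 the default reference is chi-squared with 1 df (conservative);
#' `boundaryMixture = TRUE` uses the 50:50 mixture of a point mass at zero
#' and chi-squared(1) appropriate when the null fixes omegaS on the
#' boundary.
#'
#' @param nullFit,altFit [CodonSiteFit-class] objects for the nested pair.
#' @param boundaryMixture Use the boundary mixture reference (M8a-M8 only).
#' @return A list of class `lrtResult`: `null`, `alt`, `statistic`, `df`,
#'   `pValue`.
#' @export
lrtSiteModels <- function(nullFit, altFit, boundaryMixture = FALSE) {
  stopifnot(is(nullFit, "CodonSiteFit"), is(altFit, "CodonSiteFit"))
  pair <- c(nullFit@model@name, altFit@model@name)
  ok <- any(vapply(.nested_pairs, function(p) all(p == pair), logical(1)))
  if (!ok)
    stop(sprintf("models %s and %s are not a supported nested pair",
                 pair[1L], pair[2L]), call. = FALSE)
  stat <- 2 * (altFit@logLik - nullFit@logLik)
  if (stat < -1e-6)
    warning(sprintf("alternative fit is worse than null by %.3g log units; check convergence",
                    -stat / 2))
  stat <- max(stat, 0)
  df <- altFit@npar - nullFit@npar
  p <- if (boundaryMixture && all(pair == c("M8a", "M8")))
    0.5 * stats::pchisq(stat, df = 1L, lower.tail = FALSE) + 0.5 * (stat == 0)
  else stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(null = pair[1L], alt = pair[2L], statistic = stat,
                 df = df, pValue = min(p, 1)),
            class = "lrtResult")
}

#' @export
print.lrtResult <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2*dlnL = %.4f, df = %d, p = %.4g\n",
              x$null, x$alt, x$statistic, x$df, x$pValue))
  invisible(x)
}

# ---- empirical Bayes site identification ----------------------------------

.neb_posterior <- function(sll, weights, pc) {
  lw <- log(weights); lw[weights == 0] <- -Inf
  lj <- sweep(sll, 2L, lw, "+")
  tot <- .logsumexp_rows(lj)
  exp(lj[, pc] - tot)
}

#' Posterior probability that each site belongs to the omega > 1 class
#'
#' `method = "NEB"` plugs the MLEs into Bayes' rule (naive empirical
#' Bayes).  `method = "BEB"` averages the NEB posteriors over an 8 x 8 grid
#' on the positive-class weight and omega, weighting each grid point by the
#' data likelihood (flat prior); this likelihood-weighted grid average
#' follows the construction of Bayes empirical Bayes while remaining an
#' approximation of the published integrals, so NEB is always available
#' alongside.
#'
#' @param fit A [CodonSiteFit-class] from model M2a or M8.
#' @param method `"NEB"` or `"BEB"`.
#' @param omegaMax Upper edge of the omega grid for BEB (default 20).
#' @return Numeric vector, one posterior in `[0, 1]` per codon site.
#' @export
sitePosteriors <- function(fit, method = c("NEB", "BEB"), omegaMax = 20) {
  stopifnot(is(fit, "CodonSiteFit"))
  method <- match.arg(method)
  pc <- .positive_class(fit@model)  # errors for models without one
  if (method == "NEB")
    return(.neb_posterior(fit@siteClassLogLik, fit@weights, pc))

  pd <- fit@data
  pars <- fit@params
  K <- ncol(fit@siteClassLogLik) - 1L  # classes below the positive one
  gridN <- 8L
  wPos <- (2 * seq_len(gridN) - 1) / (2 * gridN)           # positive-class weight
  omS <- 1 + (2 * seq_len(gridN) - 1) / (2 * gridN) * (omegaMax - 1)

  # site log-likelihoods for the grid omegas (other classes fixed at MLE)
  llPos <- .class_loglik(pd, pars[["kappa"]], omS, fit@pi,
                         elen = pd$elen_fitted)
  llPos <- llPos[pd$patternIdx, , drop = FALSE]
  llBase <- fit@siteClassLogLik[, seq_len(K), drop = FALSE]
  baseW <- fit@weights[seq_len(K)]
  baseW <- baseW / sum(baseW)
  cnt <- rep(1, nrow(llBase))  # full site expansion; counts already expanded

  post <- matrix(0, nrow(llBase), gridN * gridN)
  lml <- numeric(gridN * gridN)
  idx <- 0L
  for (a in seq_len(gridN)) {
    for (b in seq_len(gridN)) {
      idx <- idx + 1L
      w <- c(baseW * (1 - wPos[a]), wPos[a])
      sll <- cbind(llBase, llPos[, b])
      lw <- log(w)
      lj <- sweep(sll, 2L, lw, "+")
      tot <- .logsumexp_rows(lj)
      lml[idx] <- sum(cnt * tot)
      post[, idx] <- exp(lj[, K + 1L] - tot)
    }
  }
  gw <- exp(lml - max(lml))
  gw <- gw / sum(gw)
  as.vector(post %*% gw)
}

#' Report positively selected sites above a posterior threshold
#'
#' @param posteriors Numeric vector from [sitePosteriors()].
#' @param threshold Posterior probability cutoff; sites with posterior
#'   strictly greater are reported (default 0.90).
#' @param aln Optional alignment used for reference-coordinate mapping.
#' @param referenceId Optional reference sequence id in `aln`.
#' @param offset Added to mapped reference positions (e.g. to convert
#'   mature-peptide numbering to full-length precursor numbering).
#' @return data.frame with columns `site`, `posterior`, `refPosition`
#'   (NA when no reference is supplied).
#' @export
selectedSites <- function(posteriors, threshold = 0.90, aln = NULL,
                          referenceId = NULL, offset = 0L) {
  hit <- which(posteriors > threshold)
  refpos <- rep(NA_integer_, length(hit))
  if (length(hit) && !is.null(aln) && !is.null(referenceId))
    refpos <- vapply(hit, function(j)
      mapToReference(aln, referenceId, j, offset = offset), integer(1))
  data.frame(site = hit, posterior = posteriors[hit], refPosition = refpos)
}
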