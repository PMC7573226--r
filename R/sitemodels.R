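#' Construct a site-class model
#'
#' Creates a [SiteClassModel-class] from a model name and its parameters.
#' Parameters may be left unset when the model is to be fitted (they are
#' then initialized by [fitSiteModel()]); fixed values are needed when the
#' model parameterizes the simulator.
#'
#' Model parameters:
#' \describe{
#'   \item{M0}{`omega`}
#'   \item{M1a}{`p0`, `omega0` (< 1); the second class has omega = 1}
#'   \item{M2a}{`p0`, `p1`, `omega0` (< 1), `omega2` (> 1)}
#'   \item{M3}{`weights`, `omegas` (equal length K)}
#'   \item{M7}{`p`, `q` (beta shape parameters)}
#'   \item{M8}{`p0`, `p`, `q`, `omegaS` (> 1)}
#'   \item{M8a}{`p0`, `p`, `q`; omegaS fixed at 1}
#' }
#'
#' @param name One of `"M0","M1a","M2a","M3","M7","M8","M8a"`.
#' @param ... Model parameters, see Details.
#' @param ncat Number of equal-probability categories for the beta
#'   component of M7/M8/M8a (default 10).
#' @return A [SiteClassModel-class].
#' @examples
#' siteClassModel("M8", p0 = 0.9, p = 0.5, q = 2, omegaS = 4)
#' @export
siteClassModel <- function(name, ..., ncat = 10L) {
  name <- match.arg(name, c("M0", "M1a", "M2a", "M3", "M7", "M8", "M8a"))
  params <- list(...)
  m <- new("SiteClassModel", name = name, params = params,
           ncat = as.integer(ncat))
  .check_model_params(m, complete = FALSE)
  m
}

.model_param_names <- function(name) {
  switch(name,
         M0 = "omega",
         M1a = c("p0", "omega0"),
         M2a = c("p0", "p1", "omega0", "omega2"),
         M3 = c("weights", "omegas"),
         M7 = c("p", "q"),
         M8 = c("p0", "p", "q", "omegaS"),
         M8a = c("p0", "p", "q"))
}

.check_model_params <- function(m, complete = TRUE) {
  p <- m@params
  need <- .model_param_names(m@name)
  extra <- setdiff(names(p), need)
  if (length(extra))
    stop(sprintf("unknown parameter(s) for %s: %s", m@name,
                 paste(extra, collapse = ", ")), call. = FALSE)
  if (complete && !all(need %in% names(p)))
    stop(sprintf("model %s requires parameters: %s", m@name,
                 paste(need, collapse = ", ")), call. = FALSE)
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  # [[ indexing: $ would partially match "omega" against "omegas"
  if (!is.null(p[["omega"]])) chk(p[["omega"]] >= 0, "omega must be >= 0")
  if (!is.null(p[["p0"]])) chk(p[["p0"]] >= 0 && p[["p0"]] <= 1,
                               "p0 must lie in [0,1]")
  if (!is.null(p[["p1"]])) {
    chk(p[["p1"]] >= 0 && p[["p1"]] <= 1, "p1 must lie in [0,1]")
    if (!is.null(p[["p0"]]))
      chk(p[["p0"]] + p[["p1"]] <= 1 + 1e-12, "p0 + p1 must be <= 1")
  }
  if (!is.null(p[["omega0"]])) chk(p[["omega0"]] >= 0 && p[["omega0"]] < 1,
                                   "omega0 must lie in [0,1)")
  if (!is.null(p[["omega2"]])) chk(p[["omega2"]] > 1, "omega2 must be > 1")
  if (!is.null(p[["omegaS"]])) chk(p[["omegaS"]] > 1, "omegaS must be > 1")
  if (!is.null(p[["p"]])) chk(p[["p"]] > 0, "beta parameter p must be > 0")
  if (!is.null(p[["q"]])) chk(p[["q"]] > 0, "beta parameter q must be > 0")
  if (!is.null(p[["weights"]])) {
    chk(all(p[["weights"]] >= 0) && abs(sum(p[["weights"]]) - 1) < 1e-8,
        "weights must be non-negative and sum to 1")
    chk(!is.null(p[["omegas"]]) &&
          length(p[["omegas"]]) == length(p[["weights"]]),
        "M3 needs omegas matching weights in length")
    chk(all(p[["omegas"]] >= 0), "omegas must be >= 0")
  }
  invisible(m)
}

# mean omega within each of ncat equal-probability bins of Beta(p, q)
.beta_category_means <- function(p, q, ncat) {
  # qbeta warns about precision for extreme shapes the optimizer may probe;
  # the clamp below keeps means inside their bins regardless
  br <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = ncat + 1L), p, q))
  mu <- p / (p + q)
  means <- ncat * mu * (stats::pbeta(br[-1L], p + 1, q) -
                          stats::pbeta(br[-(ncat + 1L)], p + 1, q))
  # numerical guard: clamp into the bin
  pmin(pmax(means, br[-(ncat + 1L)]), br[-1L])
}

#' Discretize a site-class model into weights and omegas
#'
#' Beta components are discretized into `ncat` equal-probability categories
#' represented by their within-bin mean omega.
#'
#' @param model A [SiteClassModel-class] with all parameters set.
#' @return List with numeric vectors `weights` and `omegas`.
#' @export
classWeightsOmegas <- function(model) {
  stopifnot(is(model, "SiteClassModel"))
  .check_model_params(model, complete = TRUE)
  p <- model@params
  K <- model@ncat
  switch(model@name,
    M0 = list(weights = 1, omegas = p$omega),
    M1a = list(weights = c(p$p0, 1 - p$p0), omegas = c(p$omega0, 1)),
    M2a = list(weights = c(p$p0, p$p1, 1 - p$p0 - p$p1),
               omegas = c(p$omega0, 1, p$omega2)),
    M3 = list(weights = p$weights, omegas = p$omegas),
    M7 = list(weights = rep(1 / K, K),
              omegas = .beta_category_means(p$p, p$q, K)),
    M8 = list(weights = c(rep(p$p0 / K, K), 1 - p$p0),
              omegas = c(.beta_category_means(p$p, p$q, K), p$omegaS)),
    M8a = list(weights = c(rep(p$p0 / K, K), 1 - p$p0),
               omegas = c(.beta_category_means(p$p, p$q, K), 1)))
}

# index/indices of classes with omega > 1 that represent the "positive
# selection" component (M2a: last class; M8: last class)
.positive_class <- function(model) {
  switch(model@name,
         M2a = length(classWeightsOmegas(model)$omegas),
         M8 = model@ncat + 1L,
         stop(sprintf("model %s has no positive-selection class", model@name),
              call. = FALSE))
}
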