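#' CodonRateMatrix: GY94-style instantaneous rate matrix
#'
#' A 61 x 61 reversible codon substitution rate matrix in the style of
#' Goldman-Yang: single-nucleotide exchanges only, transition/transversion
#' ratio `kappa`, nonsynonymous/synonymous ratio `omega`, target-codon
#' frequencies `pi`.  The matrix is normalized so that the expected number of
#' substitutions per codon site per unit branch length is one.
#'
#' @slot Q 61 x 61 rate matrix (rows sum to zero).
#' @slot kappa,omega Numeric scalars.
#' @slot pi Length-61 equilibrium frequency vector.
#' @slot scale The normalization constant divided out of the raw rates.
#' @export
setClass("CodonRateMatrix",
         representation(Q = "matrix", kappa = "numeric", omega = "numeric",
                        pi = "numeric", scale = "numeric"))

setValidity("CodonRateMatrix", function(object) {
  msg <- character(0)
  if (!all(dim(object@Q) == c(61L, 61L))) msg <- c(msg, "Q must be 61 x 61")
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (object@omega < 0) msg <- c(msg, "omega must be >= 0")
  if (length(msg)) msg else TRUE
})

.check_pi <- function(pi) {
  if (length(pi) != 61L)
    stop("pi must have length 61 (sense codons)", call. = FALSE)
  if (any(pi < 0))
    stop("pi entries must be non-negative", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-8)
    stop("pi must sum to 1", call. = FALSE)
  pi / sum(pi)
}

#' Build a GY94 codon rate matrix
#'
#' Off-diagonal rate from codon i to codon j is `pi[j]`, multiplied by
#' `kappa` when the single-nucleotide exchange is a transition and by
#' `omega` when it is nonsynonymous; codon pairs differing at more than one
#' position, and changes into or out of stop codons, have rate zero.  The
#' matrix is rescaled so that \eqn{-\sum_i \pi_i q_{ii} = 1}.
#'
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi Equilibrium frequencies over the 61 sense codons
#'   (order of [senseCodons()]); defaults to uniform.
#' @return A [CodonRateMatrix-class] object.
#' @examples
#' M <- buildRateMatrix(kappa = 2, omega = 0.5)
#' range(rowSums(rateMatrix(M)))   # rows sum to 0
#' @export
buildRateMatrix <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  pi <- .check_pi(pi)
  tab <- codonTables()
  ty <- tab$type
  Q <- matrix(0, 61L, 61L, dimnames = dimnames(ty))
  pim <- matrix(pi, 61L, 61L, byrow = TRUE)
  Q[ty == 1L] <- pim[ty == 1L]                # synonymous transversion
  Q[ty == 2L] <- kappa * pim[ty == 2L]        # synonymous transition
  Q[ty == 3L] <- omega * pim[ty == 3L]        # nonsynonymous transversion
  Q[ty == 4L] <- kappa * omega * pim[ty == 4L]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  new("CodonRateMatrix", Q = Q, kappa = kappa, omega = omega, pi = pi,
      scale = scale)
}

#' @describeIn buildRateMatrix Extract the numeric 61 x 61 rate matrix.
#' @param x A `CodonRateMatrix`.
#' @export
rateMatrix <- function(x) x@Q

#' @export
setMethod("show", "CodonRateMatrix", function(object) {
  cat(sprintf(
    "CodonRateMatrix (GY94): kappa = %.4g, omega = %.4g, scale = %.4g\n",
    object@kappa, object@omega, object@scale))
})

#' Transition probability matrix exp(Qt)
#'
#' Computed by eigendecomposition of the pi-symmetrized rate matrix, which is
#' numerically stable for large `t`.  This is the single implementation used
#' by both the sequence simulator and (in compiled form, from the identical
#' `Q`) the pruning likelihood.
#'
#' @param ratematrix A [CodonRateMatrix-class].
#' @param t Branch length in expected substitutions per codon site (>= 0).
#' @return 61 x 61 stochastic matrix.
#' @export
transitionMatrix <- function(ratematrix, t) {
  stopifnot(is(ratematrix, "CodonRateMatrix"), t >= 0)
  pi <- ratematrix@pi
  # guard zero frequencies (possible under F3x4 on sparse data)
  pi <- pmax(pi, 1e-300)
  d <- sqrt(pi)
  B <- ratematrix@Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- ((1 / d) %o% d) * (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  P[P < 0] <- 0
  dimnames(P) <- dimnames(ratematrix@Q)
  P
}

#' F3x4 codon frequency estimator
#'
#' Estimates codon equilibrium frequencies as the product of
#' position-specific nucleotide frequencies observed at the three codon
#' positions, with stop codons assigned zero mass and the remainder
#' renormalized.  This is the conventional default frequency model for
#' codon site-model analyses; see [codonFrequenciesF61()] for empirical
#' codon counts.
#'
#' @param aln A [CodonAlignment-class].
#' @return Numeric vector of length 61 summing to 1 (order [senseCodons()]).
#' @export
codonFrequenciesF3x4 <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"), length(aln) > 0L)
  m <- .aln_matrix(aln)
  pos <- (seq_len(ncol(m)) - 1L) %% 3L + 1L
  nt <- c("A", "C", "G", "T")
  f <- matrix(0, 3L, 4L, dimnames = list(NULL, nt))
  for (p in 1:3) {
    counts <- table(factor(m[, pos == p, drop = FALSE], levels = nt))
    if (sum(counts) == 0)
      stop(sprintf("codon position %d has no observed nucleotides", p),
           call. = FALSE)
    f[p, ] <- counts / sum(counts)
  }
  cods <- senseCodons()
  sp <- do.call(rbind, strsplit(cods, ""))
  pi <- f[1L, sp[, 1L]] * f[2L, sp[, 2L]] * f[3L, sp[, 3L]]
  pi <- pi / sum(pi)
  stats::setNames(pi, cods)
}

#' Empirical (F61) codon frequencies
#'
#' @param aln A [CodonAlignment-class].
#' @param pseudocount Added to every sense-codon count (default 0.1) so no
#'   frequency is exactly zero.
#' @return Numeric vector of length 61 summing to 1.
#' @export
codonFrequenciesF61 <- function(aln, pseudocount = 0.1) {
  stopifnot(is(aln, "CodonAlignment"), length(aln) > 0L)
  cm <- .codon_matrix(aln)
  counts <- table(factor(cm, levels = senseCodons()))
  pi <- (as.numeric(counts) + pseudocount)
  stats::setNames(pi / sum(pi), senseCodons())
}
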