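#' @import methods
NULL

#' CodonAlignment: an aligned set of coding sequences
#'
#' A thin S4 wrapper around [Biostrings::DNAStringSet] enforcing the codon
#' alignment contract: all sequences equal length, length divisible by three,
#' unique sequence ids, alphabet restricted to `A,C,G,T,N,-`, and gaps
#' occurring only as whole-codon triples.
#'
#' @slot .Data see [Biostrings::DNAStringSet]
#' @export
setClass("CodonAlignment", contains = "DNAStringSet")

#' ProteinAlignment: an aligned set of amino-acid sequences
#'
#' Wraps [Biostrings::AAStringSet]; all sequences equal length with unique
#' ids, alphabet restricted to the 20 amino acids plus `-`, `X` and `*`.
#'
#' @export
setClass("ProteinAlignment", contains = "AAStringSet")

.check_common_aln <- function(object, what) {
  msg <- character(0)
  if (length(object) == 0L) return(msg)
  w <- Biostrings::width(object)
  if (length(unique(w)) != 1L)
    msg <- c(msg, sprintf("all %s sequences must have equal length", what))
  nm <- names(object)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "all sequences must be named")
  else if (anyDuplicated(nm))
    msg <- c(msg, "sequence ids must be unique")
  msg
}

setValidity("CodonAlignment", function(object) {
  msg <- .check_common_aln(object, "codon")
  if (length(object)) {
    w <- unique(Biostrings::width(object))
    if (length(w) == 1L && w %% 3L != 0L)
      msg <- c(msg, "alignment length must be divisible by 3")
    s <- as.character(object)
    if (any(grepl("[^ACGTN-]", s)))
      msg <- c(msg, "codon alignments may contain only A,C,G,T,N,-")
    # gaps only in whole-codon triples
    if (length(w) == 1L && w %% 3L == 0L && any(grepl("-", s, fixed = TRUE))) {
      cod <- .chunk_codons(s)
      bad <- grepl("-", cod) & cod != "---"
      if (any(bad))
        msg <- c(msg, "gaps must occur in whole-codon triples")
    }
  }
  if (length(msg)) msg else TRUE
})

setValidity("ProteinAlignment", function(object) {
  msg <- .check_common_aln(object, "protein")
  if (length(object)) {
    s <- as.character(object)
    if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX*-]", s)))
      msg <- c(msg, "protein alignments may contain only amino acids, '-', 'X', '*'")
  }
  if (length(msg)) msg else TRUE
})

# split equal-length sequences into codon triples; returns character matrix
# (nseq x ncodon) for vector input
.chunk_codons <- function(s) {
  n <- nchar(s[1L])
  starts <- seq.int(1L, n, by = 3L)
  res <- vapply(s, function(x) substring(x, starts, starts + 2L),
                character(length(starts)), USE.NAMES = FALSE)
  # vapply drops to a plain vector for single-codon alignments
  if (length(starts) == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Construct a CodonAlignment
#'
#' @param x A named character vector, [Biostrings::DNAStringSet], or a
#'   character matrix (rows = sequences) of single characters or codons.
#' @return A [CodonAlignment-class] object.
#' @examples
#' codonAlignment(c(s1 = "ATGGCT", s2 = "ATG---"))
#' @export
codonAlignment <- function(x) {
  if (is.matrix(x)) x <- apply(x, 1L, paste0, collapse = "")
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  new("CodonAlignment", x)
}

#' Construct a ProteinAlignment
#'
#' @param x A named character vector, [Biostrings::AAStringSet], or a
#'   character matrix (rows = sequences).
#' @return A [ProteinAlignment-class] object.
#' @examples
#' proteinAlignment(c(a = "MKV", b = "MRV"))
#' @export
proteinAlignment <- function(x) {
  if (is.matrix(x)) x <- apply(x, 1L, paste0, collapse = "")
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  new("ProteinAlignment", x)
}

# character matrix view (nseq x ncol), rownames = ids
.aln_matrix <- function(aln) {
  s <- as.character(aln)
  if (length(s) == 0L) return(matrix(character(0), 0L, 0L))
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- names(aln)
  m
}

# codon matrix view (nseq x ncodon)
.codon_matrix <- function(aln) {
  s <- as.character(aln)
  if (length(s) == 0L) return(matrix(character(0), 0L, 0L))
  m <- .chunk_codons(s)
  rownames(m) <- names(aln)
  m
}

#' Number of codon columns in a codon alignment
#' @param x A [CodonAlignment-class].
#' @return Integer scalar.
#' @export
codonColumns <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  if (length(x) == 0L) return(0L)
  Biostrings::width(x)[1L] %/% 3L
}

#' @export
setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d sequences x %d codons (%d nt)\n",
              length(object), codonColumns(object),
              if (length(object)) Biostrings::width(object)[1L] else 0L))
  if (length(object)) callNextMethod()
})

#' @export
setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns\n",
              length(object),
              if (length(object)) Biostrings::width(object)[1L] else 0L))
  if (length(object)) callNextMethod()
})

#' SiteClassModel: a named omega-mixture model over codon sites
#'
#' The M-series site models describe among-site variation of the
#' nonsynonymous/synonymous rate ratio omega as a finite mixture of site
#' classes.  Supported models: `M0` (one ratio), `M1a` (nearly neutral),
#' `M2a` (positive selection), `M3` (discrete), `M7` (beta), `M8`
#' (beta plus a class with omega > 1) and `M8a` (beta plus a class with
#' omega fixed at 1).
#'
#' @slot name Model name.
#' @slot params Named list of model parameters (free or fixed).
#' @slot ncat Integer; number of equal-probability categories used to
#'   discretize the beta component of M7/M8/M8a.
#' @export
setClass("SiteClassModel",
         representation(name = "character", params = "list", ncat = "integer"))

#' CodonSiteFit: a fitted site-class model
#'
#' Holds the maximized log-likelihood, parameter estimates, the discretized
#' class weights/omegas, per-site per-class log-likelihoods and convergence
#' diagnostics from [fitSiteModel()].
#'
#' @slot model The fitted [SiteClassModel-class] (params at the MLE).
#' @slot logLik Maximized log-likelihood.
#' @slot params Named numeric vector of estimates (includes `kappa` and
#'   `treeScale`).
#' @slot weights,omegas Numeric vectors: discretized mixture weights and
#'   class omega values at the MLE.
#' @slot siteClassLogLik Matrix (sites x classes) of per-site conditional
#'   log-likelihoods at the MLE.
#' @slot pi Codon equilibrium frequencies used (length 61).
#' @slot npar Number of free parameters.
#' @slot convergence List of optimizer diagnostics.
#' @slot data List holding the compressed pruning data (tree edges, tip
#'   state patterns) so posteriors can be recomputed without the inputs.
#' @export
setClass("CodonSiteFit",
         representation(model = "SiteClassModel", logLik = "numeric",
                        params = "numeric", weights = "numeric",
                        omegas = "numeric", siteClassLogLik = "matrix",
                        pi = "numeric", npar = "integer",
                        convergence = "list", data = "list"))

#' @export
setMethod("show", "SiteClassModel", function(object) {
  p <- object@params
  ptxt <- if (length(p)) {
    paste(sprintf("%s=%s", names(p),
                  vapply(p, function(v) paste(signif(unlist(v), 4), collapse = ","),
                         character(1))), collapse = ", ")
  } else "(no parameters set)"
  cat(sprintf("SiteClassModel %s: %s\n", object@name, ptxt))
})

#' @export
setMethod("show", "CodonSiteFit", function(object) {
  cat(sprintf("CodonSiteFit [%s]  lnL = %.4f  (%d free parameters)\n",
              object@model@name, object@logLik, object@npar))
  cat("  estimates: ",
      paste(sprintf("%s=%.4g", names(object@params), object@params),
            collapse = "  "), "\n", sep = "")
  if (!isTRUE(object@convergence$converged))
    cat("  WARNING: optimizer did not report convergence\n")
})

#' @describeIn CodonSiteFit Maximized log-likelihood.
#' @param object A `CodonSiteFit`.
#' @export
setMethod("logLik", "CodonSiteFit", function(object) {
  structure(object@logLik, df = object@npar, class = "logLik")
})

#' Accessors for fitted site models
#'
#' `fitParams()` returns the named MLE vector, `fitModelName()` the model
#' name, `classOmegas()`/`classWeights()` the discretized mixture at the MLE.
#'
#' @param fit A [CodonSiteFit-class].
#' @return See individual descriptions.
#' @export
fitParams <- function(fit) fit@params

#' @rdname fitParams
#' @export
fitModelName <- function(fit) fit@model@name

#' @rdname fitParams
#' @export
classOmegas <- function(fit) fit@omegas

#' @rdname fitParams
#' @export
classWeights <- function(fit) fit@weights
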