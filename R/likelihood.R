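# Data preparation and the pruning likelihood surface.

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Validate alignment/tree compatibility and compress sites into patterns.
.prepare_pruning_data <- function(aln, tree) {
  stopifnot(is(aln, "CodonAlignment"))
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0", call. = FALSE)
  if (!setequal(names(aln), tree$tip.label))
    stop("tree tip labels and alignment ids do not match", call. = FALSE)

  cm <- .codon_matrix(aln)[tree$tip.label, , drop = FALSE]
  tab <- codonTables()
  if (any(cm %in% tab$stops)) {
    bad <- which(matrix(cm %in% tab$stops, nrow(cm)), arr.ind = TRUE)[1L, ]
    stop(sprintf("stop codon in sequence '%s' at codon %d; remove stop codons before analysis",
                 rownames(cm)[bad[1L]], bad[2L]), call. = FALSE)
  }
  st <- match(cm, tab$codons)
  st[is.na(st)] <- 0L  # gaps / N-containing codons are missing data
  states <- matrix(as.integer(st), nrow(cm), ncol(cm))

  key <- apply(states, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  patternIdx <- match(key, key[upat])
  tp <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tp$tip.label)
  list(edge = tp$edge, elen = tp$edge.length, ntip = ntip,
       nnode = ntip + tp$Nnode, root = ntip + 1L,
       tipStates = states[, upat, drop = FALSE],
       patternIdx = patternIdx,
       patternCount = as.vector(table(factor(patternIdx,
                                             levels = seq_len(sum(upat))))),
       nSites = ncol(states))
}

# per-pattern, per-class log-likelihoods; omegas is a vector (one per class)
.class_loglik <- function(pd, kappa, omegas, pi, treeScale = 1,
                          elen = NULL) {
  K <- length(omegas)
  Qcube <- array(0, c(61L, 61L, K))
  for (k in seq_len(K))
    Qcube[, , k] <- buildRateMatrix(kappa, omegas[k], pi)@Q
  el <- if (is.null(elen)) pd$elen * treeScale else elen
  prune_loglik_cpp(pd$edge, el, pd$ntip, pd$nnode, pd$root,
                   pd$tipStates, Qcube, pi)
}

#' Per-site, per-class pruning log-likelihoods
#'
#' Felsenstein pruning over the 61 sense-codon states on a fixed rooted
#' topology, one pass per omega class.  Gap- or N-containing codons are
#' treated as missing data (unit partial likelihood); stop codons in the
#' data are rejected with an error.
#'
#' @param aln A [CodonAlignment-class]; ids must match the tree tips.
#' @param tree A rooted [ape::phylo] with branch lengths in expected
#'   substitutions per codon site.
#' @param kappa Transition/transversion rate ratio.
#' @param omegas Numeric vector of per-class omega values.
#' @param pi Codon frequencies (default [codonFrequenciesF3x4()] of `aln`).
#' @param treeScale Multiplier applied to all branch lengths.
#' @return Matrix (codon sites x classes) of log-likelihoods.
#' @export
siteLogLikelihood <- function(aln, tree, kappa, omegas,
                              pi = codonFrequenciesF3x4(aln),
                              treeScale = 1) {
  pd <- .prepare_pruning_data(aln, tree)
  ll <- .class_loglik(pd, kappa, omegas, .check_pi(pi), treeScale)
  out <- ll[pd$patternIdx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
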