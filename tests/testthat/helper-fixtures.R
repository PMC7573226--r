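# Shared fixtures and independent oracles used across the suite.

AA20 <- sort(setdiff(unique(senseCodonAminoAcids()), c("*")))

# random gapped protein alignment as a named character vector
random_protein_aln <- function(nseq, ncol, gap_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(AA20, nseq * ncol, replace = TRUE), nseq, ncol)
  if (gap_prob > 0)
    m[matrix(runif(nseq * ncol) < gap_prob, nseq, ncol)] <- "-"
  rownames(m) <- sprintf("s%02d", seq_len(nseq))
  proteinAlignment(m)
}

# exhaustive per-column differential-substitution oracle, written directly
# from the definition: foreground shares one residue, background shares a
# single different residue, no gaps/ambiguity anywhere in the column
brute_diffsub <- function(aln, foreground, background) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  fi <- match(foreground, rownames(m))
  bi <- match(background, rownames(m))
  bad <- c("-", "X", "*")
  hits <- integer(0)
  for (j in seq_len(ncol(m))) {
    fg <- m[fi, j]; bg <- m[bi, j]
    if (any(c(fg, bg) %in% bad)) next
    if (length(unique(fg)) == 1L && length(unique(bg)) == 1L &&
        fg[1L] != bg[1L])
      hits <- c(hits, j)
  }
  hits
}

# brute-force phylogenetic likelihood: sum over all internal-node state
# assignments, independent of the pruning recursion
brute_codon_loglik <- function(aln, tree, kappa, omega, pi) {
  cods <- senseCodons()
  s <- as.character(aln)
  cm <- t(vapply(s, function(x)
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3)),
    character(nchar(s[1]) / 3), USE.NAMES = FALSE))
  rownames(cm) <- names(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  M <- buildRateMatrix(kappa, omega, pi)
  Ps <- lapply(tr$edge.length, function(t) transitionMatrix(M, t))
  ints <- (nt + 1):(nt + tr$Nnode)
  grid <- as.matrix(expand.grid(rep(list(1:61), length(ints))))
  S <- ncol(cm)
  out <- numeric(S)
  for (si in seq_len(S)) {
    tipst <- match(cm[tr$tip.label, si], cods)
    # vectorized over the full grid of internal-state assignments
    st <- matrix(0L, nrow(grid), nt + tr$Nnode)
    st[, seq_len(nt)] <- rep(tipst, each = nrow(grid))
    st[, ints] <- grid
    pr <- pi[st[, nt + 1]]
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * Ps[[e]][cbind(st[, tr$edge[e, 1]], st[, tr$edge[e, 2]])]
    out[si] <- log(sum(pr))
  }
  out
}

random_codon_aln <- function(ids, ncodons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codonAlignment(stats::setNames(
    vapply(seq_along(ids), function(i)
      paste0(sample(senseCodons(), ncodons, replace = TRUE), collapse = ""),
      character(1)), ids))
}
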