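#' CodonSubstitutionSpec: parameters of the generative codon model
#'
#' Bundles the GY94 parameters used to evolve a codon alignment: `kappa`,
#' codon frequencies `pi`, and a [SiteClassModel-class] with fixed parameter
#' values supplying the among-site omega mixture.
#'
#' @slot kappa Transition/transversion rate ratio.
#' @slot pi Length-61 frequency vector over the sense codons.
#' @slot siteClass A [SiteClassModel-class] with fixed parameters.
#' @export
setClass("CodonSubstitutionSpec",
         representation(kappa = "numeric", pi = "numeric",
                        siteClass = "SiteClassModel"))

setValidity("CodonSubstitutionSpec", function(object) {
  msg <- character(0)
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (length(object@pi) != 61L) msg <- c(msg, "pi must have length 61")
  else {
    if (any(object@pi < 0)) msg <- c(msg, "pi entries must be >= 0")
    if (abs(sum(object@pi) - 1) > 1e-12) msg <- c(msg, "pi must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CodonSubstitutionSpec-class
#' @param kappa,pi,siteClass See slot descriptions.
#' @return A `CodonSubstitutionSpec`.
#' @export
codonSubstitutionSpec <- function(kappa = 2,
                                  pi = rep(1 / 61, 61),
                                  siteClass = siteClassModel("M0", omega = 0.2)) {
  new("CodonSubstitutionSpec", kappa = kappa, pi = pi / sum(pi),
      siteClass = siteClass)
}

#' Simulate a Yule (pure-birth) tree
#'
#' A constant-rate pure-birth process conditioned on the number of tips:
#' starting from two lineages, exponential waiting times (rate = number of
#' extant lineages) separate uniform lineage splits until `nLeaves` lineages
#' exist; a final exponential waiting time runs to the present.  Branch
#' lengths are multiplied by `depthScale` so they read as expected
#' substitutions per codon site.
#'
#' @param nLeaves Number of tips (>= 2).
#' @param depthScale Positive multiplier applied to all branch lengths.
#'   The default 0.5 yields root-to-tip path lengths around one substitution
#'   per codon site for tens of taxa, typical of a plant gene family at
#'   order depth.
#' @param seed Integer RNG seed; identical seeds give identical trees.
#' @return An [ape::phylo] rooted tree with tip labels `t1..tn`.
#' @examples
#' tr <- simulateYuleTree(6, seed = 1)
#' ape::Ntip(tr)
#' @export
simulateYuleTree <- function(nLeaves, depthScale = 0.5, seed = 1L) {
  if (nLeaves < 2) stop("nLeaves must be >= 2", call. = FALSE)
  if (depthScale <= 0) stop("depthScale must be positive", call. = FALSE)
  set.seed(seed)
  # active lineages: own id, parent id, birth time; root has id 0
  lin_id <- c(1L, 2L); lin_par <- c(0L, 0L); lin_start <- c(0, 0)
  int_id <- integer(0); int_par <- integer(0)
  int_start <- numeric(0); int_end <- numeric(0)
  idc <- 2L; tnow <- 0
  while (length(lin_id) < nLeaves) {
    k <- length(lin_id)
    tnow <- tnow + stats::rexp(1L, rate = k)
    i <- sample.int(k, 1L)
    sp_id <- lin_id[i]
    int_id <- c(int_id, sp_id); int_par <- c(int_par, lin_par[i])
    int_start <- c(int_start, lin_start[i]); int_end <- c(int_end, tnow)
    lin_id <- c(lin_id[-i], idc + 1L, idc + 2L)
    lin_par <- c(lin_par[-i], sp_id, sp_id)
    lin_start <- c(lin_start[-i], tnow, tnow)
    idc <- idc + 2L
  }
  tnow <- tnow + stats::rexp(1L, rate = nLeaves)

  n <- nLeaves
  # ape numbering: tips 1..n (by lineage id order), root n+1, internals onward
  tip_ids <- sort(lin_id)
  int_ids <- c(0L, sort(int_id))
  nodemap <- stats::setNames(c(seq_len(n), n + seq_along(int_ids)),
                             c(tip_ids, int_ids))
  parent_of <- c(stats::setNames(lin_par, lin_id), stats::setNames(int_par, int_id))
  start_of <- c(stats::setNames(lin_start, lin_id), stats::setNames(int_start, int_id))
  end_of <- c(stats::setNames(rep(tnow, n), lin_id), stats::setNames(int_end, int_id))
  child_ids <- c(tip_ids, setdiff(int_ids, 0L))
  edge <- cbind(unname(nodemap[as.character(parent_of[as.character(child_ids)])]),
                unname(nodemap[as.character(child_ids)]))
  elen <- unname(end_of[as.character(child_ids)] -
                   start_of[as.character(child_ids)]) * depthScale
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a codon alignment under a site-class omega mixture
#'
#' Each site draws its omega class once from the mixture (the site-model
#' assumption: no branch heterogeneity), the root codon is drawn from `pi`,
#' and states evolve along each branch using transition probabilities
#' `exp(Qt)` from the identical GY94 matrix code used by the likelihood
#' engine ([buildRateMatrix()], [transitionMatrix()]).  Alignments are
#' gap-free and never contain stop codons.
#'
#' @param tree An [ape::phylo] rooted tree with branch lengths.
#' @param spec A [CodonSubstitutionSpec-class].
#' @param nCodons Number of codon sites (>= 1).
#' @param seed Integer RNG seed.
#' @return A list with elements `alignment` ([CodonAlignment-class]),
#'   `siteOmega` (true per-site omega), `siteClass` (class index per site).
#' @examples
#' tr <- simulateYuleTree(4, seed = 1)
#' sim <- simulateCodonAlignment(tr, codonSubstitutionSpec(), 10, seed = 2)
#' sim$alignment
#' @export
simulateCodonAlignment <- function(tree, spec, nCodons, seed = 1L) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object", call. = FALSE)
  if (nCodons < 1) stop("nCodons must be >= 1", call. = FALSE)
  validObject(spec)
  mix <- classWeightsOmegas(spec@siteClass)
  K <- length(mix$omegas)
  set.seed(seed)
  siteClass <- sample.int(K, nCodons, replace = TRUE, prob = mix$weights)
  Qs <- lapply(mix$omegas, function(om)
    buildRateMatrix(spec@kappa, om, spec@pi))

  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  states <- matrix(NA_integer_, nnode, nCodons)
  root <- ntip + 1L
  states[root, ] <- sample.int(61L, nCodons, replace = TRUE, prob = spec@pi)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; chi <- tr$edge[e, 2L]
    t_e <- tr$edge.length[e]
    for (k in seq_len(K)) {
      sk <- which(siteClass == k)
      if (!length(sk)) next
      if (t_e == 0) {
        states[chi, sk] <- states[par, sk]
        next
      }
      P <- transitionMatrix(Qs[[k]], t_e)
      pstates <- states[par, sk]
      for (st in unique(pstates)) {
        idx <- sk[pstates == st]
        states[chi, idx] <- sample.int(61L, length(idx), replace = TRUE,
                                       prob = P[st, ])
      }
    }
  }
  cods <- senseCodons()
  seqs <- vapply(seq_len(ntip), function(i)
    paste0(cods[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tr$tip.label
  list(alignment = codonAlignment(seqs),
       siteOmega = mix$omegas[siteClass],
       siteClass = siteClass)
}

#' Plant strictly convergent substitutions into an alignment
#'
#' Selects columns where all sequences outside the foreground share one
#' amino acid with no gaps or ambiguities, then rewrites the foreground at
#' `nSites` of these columns to a common amino acid differing from the
#' background one.  On codon alignments the lexicographically smallest codon
#' encoding the target amino acid is used, so output is deterministic given
#' the seed.
#'
#' @param aln A [ProteinAlignment-class] or [CodonAlignment-class].
#' @param foreground Character vector (length >= 1) of sequence ids.
#' @param nSites Number of columns to plant (>= 0).
#' @param seed Integer RNG seed.
#' @return List with `alignment` (same class as input), `columns` (planted
#'   column indices, protein/codon coordinates, sorted) and `targetAa`.
#' @export
plantConvergentSubstitutions <- function(aln, foreground, nSites, seed = 1L) {
  stopifnot(is(aln, "ProteinAlignment") || is(aln, "CodonAlignment"))
  ids <- names(aln)
  if (!all(foreground %in% ids))
    stop("foreground ids must be present in the alignment", call. = FALSE)
  if (nSites < 0) stop("nSites must be >= 0", call. = FALSE)
  is_codon <- is(aln, "CodonAlignment")
  pm <- if (is_codon) {
    cm <- .codon_matrix(aln)
    matrix(.translate_codons(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  } else .aln_matrix(aln)
  bg <- setdiff(ids, foreground)
  if (!length(bg)) stop("at least one background sequence required", call. = FALSE)

  bad <- c("-", "X", "*")
  eligible <- which(vapply(seq_len(ncol(pm)), function(j) {
    col <- pm[, j]
    if (any(col %in% bad)) return(FALSE)
    length(unique(col[bg])) == 1L
  }, logical(1)))
  if (nSites == 0L)
    return(list(alignment = aln, columns = integer(0), targetAa = character(0)))
  if (length(eligible) < nSites)
    stop(sprintf("only %d eligible columns but %d sites requested",
                 length(eligible), nSites), call. = FALSE)
  set.seed(seed)
  cols <- sort(sample(eligible, nSites))
  aa20 <- setdiff(sort(unique(senseCodonAminoAcids())), character(0))
  target <- vapply(cols, function(j) {
    b <- pm[bg[1L], j]
    sample(setdiff(aa20, b), 1L)
  }, character(1))

  if (is_codon) {
    cm <- .codon_matrix(aln)
    tab <- codonTables()
    for (i in seq_along(cols)) {
      cod <- tab$codons[tab$aa == target[i]][1L]  # lexicographically smallest
      cm[foreground, cols[i]] <- cod
    }
    out <- codonAlignment(cm)
  } else {
    pm2 <- .aln_matrix(aln)
    for (i in seq_along(cols)) pm2[foreground, cols[i]] <- target[i]
    out <- proteinAlignment(pm2)
  }
  list(alignment = out, columns = cols, targetAa = target)
}

#' Simulate a per-species gene-dosage table
#'
#' Generates a species table with alpha/beta subunit gene counts and a
#' photosynthetic-type label, emulating a census in which species with the
#' NAD-ME subtype of C4 photosynthesis carry a non-1:1 beta/alpha gene
#' ratio more often than other species.  Defaults reproduce the published
#' census structure: 92 angiosperm species, 7 of them C4-NAD-ME, with
#' conditional non-1:1 probabilities 0.715 (C4-NAD-ME) and 0.186 (other).
#'
#' @param nSpecies Number of species (>= 1).
#' @param pC4 Probability a species is labeled `C4-NAD-ME`.
#' @param pNon11C4,pNon11NonC4 Conditional probabilities of a non-1:1
#'   beta/alpha ratio given the group.
#' @param ratioProbs Named probability vector over non-1:1 ratios
#'   (`"beta:alpha"` strings).
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `species`, `clade`,
#'   `photosynthesis_type`, `n_alpha`, `n_beta`.
#' @export
simulateDosageTable <- function(nSpecies = 92L,
                                pC4 = 7 / 92,
                                pNon11C4 = 0.715,
                                pNon11NonC4 = 0.186,
                                ratioProbs = c("2:1" = 0.80, "3:1" = 0.05,
                                               "4:1" = 0.05, "1:2" = 0.10),
                                seed = 1L) {
  if (nSpecies < 1) stop("nSpecies must be >= 1", call. = FALSE)
  probs <- c(pC4, pNon11C4, pNon11NonC4, ratioProbs)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  clades <- c("rosids", "asterids", "monocots", "caryophyllales", "magnoliids")
  is_c4 <- stats::runif(nSpecies) < pC4
  non11 <- stats::runif(nSpecies) < ifelse(is_c4, pNon11C4, pNon11NonC4)
  ratio <- rep("1:1", nSpecies)
  if (any(non11))
    ratio[non11] <- sample(names(ratioProbs), sum(non11), replace = TRUE,
                           prob = ratioProbs)
  parts <- do.call(rbind, strsplit(ratio, ":", fixed = TRUE))
  data.frame(
    species = sprintf("species_%03d", seq_len(nSpecies)),
    clade = clades[(seq_len(nSpecies) - 1L) %% length(clades) + 1L],
    photosynthesis_type = ifelse(is_c4, "C4-NAD-ME", "C3"),
    n_alpha = as.integer(parts[, 2L]),
    n_beta = as.integer(parts[, 1L]),
    stringsAsFactors = FALSE
  )
}

#' Simulate a base genome gene order
#'
#' @param nGenes Total number of genes.
#' @param nChrom Number of chromosomes; genes split contiguously.
#' @param seed Integer RNG seed (reserved; layout is deterministic).
#' @return A genome data.frame with columns `chrom`, `start`, `end`,
#'   `gene_id`, `family_id`, `strand`, `ordinal`.
#' @export
simulateBaseGenome <- function(nGenes = 500L, nChrom = 5L, seed = 1L) {
  if (nGenes < 1) stop("nGenes must be >= 1", call. = FALSE)
  chrom_idx <- sort(rep_len(seq_len(nChrom), nGenes))
  chrom <- sprintf("chr%02d", chrom_idx)
  ord <- unlist(lapply(split(seq_len(nGenes), chrom), seq_along), use.names = FALSE)
  data.frame(
    chrom = chrom,
    start = (ord - 1L) * 1000L + 1L,
    end = (ord - 1L) * 1000L + 601L,
    gene_id = sprintf("g%05d", seq_len(nGenes)),
    family_id = sprintf("f%05d", seq_len(nGenes)),
    strand = "+",
    ordinal = ord,
    stringsAsFactors = FALSE
  )
}

#' Simulate a genome derived by whole-genome duplication
#'
#' Each round duplicates every chromosome; every newly created gene copy is
#' then independently retained with probability `retentionProb`
#' (fractionation).  After all rounds, `nTranspositions` randomly chosen
#' genes are relocated to a random position on a random chromosome
#' (single-gene transposition).  Homolog pairs link every base gene to all
#' of its surviving descendants, including the untouched original copy.
#'
#' @param base A genome data.frame from [simulateBaseGenome()].
#' @param rounds Number of WGD rounds (>= 0).
#' @param retentionProb Retention probability for duplicated copies.
#' @param nTranspositions Number of single-gene relocations.
#' @param seed Integer RNG seed.
#' @return List with `genome` (derived genome data.frame) and `pairs`
#'   (data.frame `query_id` = base gene, `target_id` = derived gene).
#' @export
simulateWgdGenome <- function(base, rounds = 1L, retentionProb = 0.6,
                              nTranspositions = 0L, seed = 1L) {
  if (!nrow(base)) stop("base genome is empty", call. = FALSE)
  if (rounds < 0) stop("rounds must be >= 0", call. = FALSE)
  if (retentionProb < 0 || retentionProb > 1)
    stop("retentionProb must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  g <- base
  g$origin <- base$gene_id
  for (r in seq_len(rounds)) {
    dup <- g
    dup$chrom <- paste0(dup$chrom, "_d", r)
    dup$gene_id <- paste0(dup$gene_id, "_d", r)
    keep <- stats::runif(nrow(dup)) < retentionProb
    g <- rbind(g, dup[keep, , drop = FALSE])
    g <- .renumber_genome_keep_origin(g)
  }
  if (nTranspositions > 0L) {
    mv <- sample.int(nrow(g), min(nTranspositions, nrow(g)))
    for (i in mv) {
      dest_chr <- sample(unique(g$chrom), 1L)
      slots <- sum(g$chrom == dest_chr & !(seq_len(nrow(g)) %in% i))
      pos <- sample.int(slots + 1L, 1L)
      g$chrom[i] <- dest_chr
      g$ordinal[i] <- pos - 0.5  # insert between existing ordinals
      g <- .renumber_genome_keep_origin(g)
    }
  }
  pairs <- data.frame(query_id = g$origin, target_id = g$gene_id,
                      stringsAsFactors = FALSE)
  g$origin <- NULL
  list(genome = g, pairs = pairs[order(pairs$query_id, pairs$target_id), ,
                                 drop = FALSE])
}

.renumber_genome_keep_origin <- function(g) {
  g <- g[order(g$chrom, g$ordinal), , drop = FALSE]
  g$ordinal <- unlist(lapply(split(seq_len(nrow(g)), g$chrom), seq_along),
                      use.names = FALSE)
  g$start <- (g$ordinal - 1L) * 1000L + 1L
  g$end <- g$start + 600L
  rownames(g) <- NULL
  g
}
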