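test_that("Yule trees have the requested size and deterministic structure", {
  tr <- simulateYuleTree(2, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(tr$Nnode, 1L)  # a single cherry
  expect_identical(ape::write.tree(simulateYuleTree(9, seed = 42)),
                   ape::write.tree(simulateYuleTree(9, seed = 42)))
  expect_false(identical(ape::write.tree(simulateYuleTree(9, seed = 42)),
                         ape::write.tree(simulateYuleTree(9, seed = 43))))
  expect_error(simulateYuleTree(1), "nLeaves")

  for (s in 1:200) {
    tr <- simulateYuleTree(50, depthScale = 0.7, seed = s)
    expect_equal(ape::Ntip(tr), 50L)
    expect_true(all(tr$edge.length >= 0))
    expect_true(ape::is.rooted(tr))
  }
})

test_that("codon simulation respects branch lengths and omega constraints", {
  tr <- simulateYuleTree(5, seed = 2)
  tr0 <- tr; tr0$edge.length[] <- 0
  sim0 <- simulateCodonAlignment(tr0, codonSubstitutionSpec(), 30, seed = 3)
  expect_equal(length(unique(as.character(sim0$alignment))), 1L)

  # omega = 0 forbids amino-acid change anywhere on the tree
  spec <- codonSubstitutionSpec(siteClass = siteClassModel("M0", omega = 0))
  sim <- simulateCodonAlignment(tr, spec, 60, seed = 4)
  prot <- suppressWarnings(translateCodonAlignment(sim$alignment))
  expect_equal(length(unique(as.character(prot))), 1L)

  # never a stop codon; deterministic under a fixed seed
  stops <- paraselect:::codonTables()$stops
  for (s in 1:5) {
    sim <- simulateCodonAlignment(
      tr, codonSubstitutionSpec(siteClass = siteClassModel("M0", omega = 0.5)),
      40, seed = s)
    cm <- paraselect:::.codon_matrix(sim$alignment)
    expect_false(any(cm %in% stops))
  }
  a <- simulateCodonAlignment(tr, spec, 25, seed = 11)
  b <- simulateCodonAlignment(tr, spec, 25, seed = 11)
  expect_identical(as.character(a$alignment), as.character(b$alignment))
  expect_identical(a$siteClass, b$siteClass)
})

test_that("simulated chains reach the stationary codon distribution", {
  # two-leaf tree with one very long branch: the far leaf's codon
  # frequencies must match pi within multinomial error
  tr <- ape::read.tree(text = "(near:0.0,far:50.0);")
  pi <- rep(1 / 61, 61)
  spec <- codonSubstitutionSpec(kappa = 2, pi = pi,
                                siteClass = siteClassModel("M0", omega = 0.5))
  for (s in 1:10) {
    sim <- simulateCodonAlignment(tr, spec, 2000, seed = s)
    cm <- paraselect:::.codon_matrix(sim$alignment)
    counts <- table(factor(cm["far", ], levels = senseCodons()))
    p <- suppressWarnings(stats::chisq.test(as.numeric(counts), p = pi)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("planted convergent substitutions satisfy the strict pattern", {
  base <- proteinAlignment(stats::setNames(rep(strrep("ACDEFGHIKLMNPQRSTVWY", 3), 6),
                                           sprintf("s%d", 1:6)))
  fg <- c("s1", "s2")
  out0 <- plantConvergentSubstitutions(base, fg, 0, seed = 1)
  expect_identical(as.character(out0$alignment), as.character(base))

  out <- plantConvergentSubstitutions(base, fg, 5, seed = 1)
  m <- paraselect:::.aln_matrix(out$alignment)
  for (j in out$columns) {
    expect_equal(length(unique(m[fg, j])), 1L)
    expect_equal(length(unique(m[setdiff(rownames(m), fg), j])), 1L)
    expect_false(m[fg[1], j] == m["s3", j])
  }
  # untouched elsewhere
  expect_identical(m[, -out$columns],
                   paraselect:::.aln_matrix(base)[, -out$columns])
  # shortage error
  expect_error(plantConvergentSubstitutions(base, fg, 10000, seed = 1),
               "eligible")
})

test_that("planting on codon alignments uses the smallest encoding codon", {
  cods <- rep(paste0(rep("ATGGCTCGT", 5), collapse = ""), 4)
  aln <- codonAlignment(stats::setNames(cods, sprintf("s%d", 1:4)))
  out <- plantConvergentSubstitutions(aln, "s1", 3, seed = 2)
  tab <- paraselect:::codonTables()
  cm <- paraselect:::.codon_matrix(out$alignment)
  for (i in seq_along(out$columns)) {
    cod <- unname(cm["s1", out$columns[i]])
    aa <- out$targetAa[i]
    expect_identical(cod, tab$codons[tab$aa == aa][1])
  }
})

test_that("dosage table generator hits its planted probabilities", {
  t0 <- simulateDosageTable(50, pC4 = 0.2, pNon11C4 = 0, pNon11NonC4 = 0,
                            seed = 1)
  expect_true(all(t0$n_alpha == 1 & t0$n_beta == 1))
  t1 <- simulateDosageTable(40, pC4 = 1, seed = 2)
  expect_true(all(t1$photosynthesis_type == "C4-NAD-ME"))

  big <- simulateDosageTable(1e4, pC4 = 0.5, pNon11C4 = 0.7,
                             pNon11NonC4 = 0.1, seed = 3)
  c4 <- big$photosynthesis_type == "C4-NAD-ME"
  non11 <- !(big$n_beta == big$n_alpha)
  phat <- mean(non11[c4])
  se <- sqrt(0.7 * 0.3 / sum(c4))
  expect_lt(abs(phat - 0.7), 3 * se)
  expect_identical(simulateDosageTable(30, seed = 9),
                   simulateDosageTable(30, seed = 9))
})

test_that("WGD simulation duplicates, fractionates and relocates genes", {
  base <- simulateBaseGenome(60, nChrom = 3)
  id0 <- simulateWgdGenome(base, rounds = 0, nTranspositions = 0, seed = 1)
  expect_identical(id0$genome$gene_id, base$gene_id)
  expect_true(all(id0$pairs$query_id == id0$pairs$target_id))

  full <- simulateWgdGenome(base, rounds = 1, retentionProb = 1, seed = 2)
  counts <- table(full$pairs$query_id)
  expect_true(all(counts == 2L))

  base2 <- simulateBaseGenome(500, nChrom = 5)
  half <- simulateWgdGenome(base2, rounds = 1, retentionProb = 0.5, seed = 3)
  retained <- nrow(half$genome) - nrow(base2)
  se <- sqrt(0.5 * 0.5 / nrow(base2))
  expect_lt(abs(retained / nrow(base2) - 0.5), 3 * se)
  expect_error(simulateWgdGenome(base2[0, ], 1), "empty")

  # ordinals stay contiguous per chromosome after transposition
  tp <- simulateWgdGenome(base, rounds = 1, retentionProb = 0.8,
                          nTranspositions = 5, seed = 4)
  for (ch in unique(tp$genome$chrom)) {
    o <- sort(tp$genome$ordinal[tp$genome$chrom == ch])
    expect_identical(o, seq_along(o))
  }
})
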