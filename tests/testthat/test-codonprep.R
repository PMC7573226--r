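test_that("backtranslate maps residues to their source codons", {
  out <- backtranslate(proteinAlignment(c(a = "M-A")), c(a = "ATGGCT"))
  expect_identical(as.character(out), c(a = "ATG---GCT"))
  # terminal stop is stripped before matching
  out2 <- backtranslate(proteinAlignment(c(a = "MA")), c(a = "ATGGCTTAA"))
  expect_identical(unname(as.character(out2)), "ATGGCT")
  expect_identical(length(backtranslate(proteinAlignment(character(0)),
                                        character(0))), 0L)

  expect_error(backtranslate(proteinAlignment(c(a = "MA")), c(b = "ATGGCT")),
               "missing coding sequence")
  expect_error(backtranslate(proteinAlignment(c(a = "MK")), c(a = "ATGGCT")),
               "residue 2")
  expect_error(backtranslate(proteinAlignment(c(a = "MA")), c(a = "ATGGC")),
               "multiple of 3")
})

test_that("translate/backtranslate round-trips random alignments", {
  set.seed(31)
  for (rep in 1:5) {
    cods <- senseCodons()
    n <- 10; L <- 30
    cm <- matrix(sample(cods, n * L, replace = TRUE), n, L)
    cm[matrix(runif(n * L) < 0.1, n, L)] <- "---"
    rownames(cm) <- sprintf("s%d", 1:n)
    aln <- codonAlignment(cm)
    prot <- translateCodonAlignment(aln)
    cds <- vapply(seq_len(n), function(i)
      paste0(cm[i, cm[i, ] != "---"], collapse = ""), character(1))
    names(cds) <- rownames(cm)
    back <- backtranslate(prot, cds)
    expect_identical(as.character(back), as.character(aln))
    expect_identical(as.character(translateCodonAlignment(back)),
                     as.character(prot))
  }
})

test_that("coverage filter keeps columns at or above the threshold", {
  # gap-free alignment passes unchanged
  aln <- random_codon_aln(sprintf("s%d", 1:4), 12, seed = 7)
  fl <- coverageFilter(aln)
  expect_identical(as.character(fl$alignment), as.character(aln))
  expect_identical(fl$kept, 1:12)

  # 20 sequences, one column gapped in 2 (coverage 0.90):
  # removed at 0.95, retained at 0.90 (inclusive boundary)
  cm <- matrix("ATG", 20, 5)
  cm[1:2, 3] <- "---"
  rownames(cm) <- sprintf("s%02d", 1:20)
  aln20 <- codonAlignment(cm)
  expect_identical(coverageFilter(aln20, 0.95)$kept, c(1:2, 4:5))
  expect_identical(coverageFilter(aln20, 0.90)$kept, 1:5)

  # with 240 sequences a column needs >= 228 present codons at 0.95
  cm <- matrix("AAA", 240, 2)
  cm[1:12, 1] <- "---"   # 228 present -> kept
  cm[1:13, 2] <- "---"   # 227 present -> dropped
  rownames(cm) <- sprintf("q%03d", 1:240)
  expect_identical(coverageFilter(codonAlignment(cm), 0.95)$kept, 1L)

  # N-containing codons count as missing
  cmn <- matrix("ATG", 10, 2)
  cmn[1, 1] <- "ATN"
  rownames(cmn) <- sprintf("s%d", 1:10)
  expect_identical(coverageFilter(codonAlignment(cmn), 0.95)$kept, 2L)

  # idempotence and extreme thresholds
  gappy <- codonAlignment(c(a = "ATG---AAA", b = "---------", c = "ATGGGGAAA"))
  once <- coverageFilter(gappy, 0.6)
  twice <- coverageFilter(once$alignment, 0.6)
  expect_identical(as.character(twice$alignment), as.character(once$alignment))
  expect_identical(coverageFilter(gappy, 1e-9)$kept, 1:3)  # only all-gap columns drop
  expect_identical(coverageFilter(gappy, 1)$kept, integer(0))  # b is all gaps
  expect_error(coverageFilter(gappy, 0), "minCoverage")
})

test_that("codon position extraction partitions the alignment", {
  aln <- codonAlignment(c(a = "ATGGCT"))
  expect_identical(unname(as.character(codonPositionExtract(aln, 3))), "GT")
  expect_error(codonPositionExtract(aln, 4), "position")

  gaps <- codonAlignment(c(a = "------"))
  expect_identical(unname(as.character(codonPositionExtract(gaps, 2))), "--")

  r <- random_codon_aln(c("x", "y", "z"), 20, seed = 3)
  p1 <- as.character(codonPositionExtract(r, 1))
  p2 <- as.character(codonPositionExtract(r, 2))
  p3 <- as.character(codonPositionExtract(r, 3))
  rebuilt <- vapply(seq_along(p1), function(i) {
    paste0(as.vector(rbind(strsplit(p1[i], "")[[1]],
                           strsplit(p2[i], "")[[1]],
                           strsplit(p3[i], "")[[1]])), collapse = "")
  }, character(1))
  expect_identical(rebuilt, unname(as.character(r)))
})

test_that("translation follows the ambiguity and stop rules", {
  expect_warning(
    prot <- translateCodonAlignment(codonAlignment(c(a = "ATG---TAA"))),
    "codon 3")
  expect_identical(unname(as.character(prot)), "M-*")
  expect_identical(
    unname(as.character(translateCodonAlignment(codonAlignment(c(a = "ATN"))))),
    "X")
})

test_that("mature-region slicing keeps columns from the reference residue", {
  aln <- proteinAlignment(c(r = "M-KL", o = "MAKL"))
  expect_identical(as.character(matureRegionSlice(aln, "r", 1)),
                   as.character(aln))
  sliced <- matureRegionSlice(aln, "r", 2)
  expect_identical(unname(as.character(sliced)), c("KL", "KL"))
  expect_error(matureRegionSlice(aln, "zz", 1), "not found")
  expect_error(matureRegionSlice(aln, "r", 5), "firstMatureResidue")

  # slicing + offset mapping returns full-length numbering
  full <- proteinAlignment(c(r = "MAPKLVD", o = "MAPRLVD"))
  sl <- matureRegionSlice(full, "r", 4)  # mature starts at K (residue 4)
  expect_identical(mapToReference(sl, "r", 2, offset = 3), 5L)
  expect_identical(mapToReference(full, "r", 5), 5L)
})
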