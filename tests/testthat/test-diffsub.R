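test_that("shared-strict scan finds exactly the defining pattern", {
  aln <- proteinAlignment(c(f1 = "MKV", f2 = "MKV", b1 = "MRV", b2 = "MRV"))
  hits <- strictDiffSubShared(aln, c("f1", "f2"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$column, 2L)
  expect_equal(hits$fgAa, "K")
  expect_equal(hits$bgAa, "R")
  expect_equal(hits$mode, "shared-strict")

  # foreground identical to background alignment-wide: nothing to report
  same <- proteinAlignment(c(f = "MKV", b1 = "MKV", b2 = "MKV"))
  expect_equal(nrow(strictDiffSubShared(same, "f")), 0L)
  expect_error(strictDiffSubShared(aln, character(0)), "foreground")
  expect_error(strictDiffSubShared(aln, "zz"), "missing")
})

test_that("scanner equals the brute-force definition on random alignments", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(4:8, 1)
    aln <- random_protein_aln(n, 50, gap_prob = 0.05)
    ids <- names(aln)
    fg <- sample(ids, sample(1:2, 1))
    bg <- setdiff(ids, fg)
    got <- strictDiffSubShared(aln, fg)$column
    expect_identical(got, brute_diffsub(aln, fg, bg))
  }
})

test_that("single-sequence scan is the singleton case of the shared scan", {
  set.seed(13)
  for (rep in 1:50) {
    aln <- random_protein_aln(6, 40, gap_prob = 0.08)
    focal <- names(aln)[1]
    a <- strictDiffSubSingle(aln, focal)
    b <- strictDiffSubShared(aln, focal)
    expect_identical(a$column, b$column)
    expect_true(all(a$mode == "single-sequence"))
  }
  # a focal identical to one background sequence yields nothing
  aln <- proteinAlignment(c(x = "MKV", y = "MKV", z = "MAV"))
  expect_equal(nrow(strictDiffSubSingle(aln, "x")), 0L)
})

test_that("scanner output is invariant under row reordering and renaming", {
  aln <- random_protein_aln(7, 30, gap_prob = 0.05, seed = 21)
  fg <- names(aln)[c(2, 5)]
  h1 <- strictDiffSubShared(aln, fg)
  perm <- sample(seq_along(aln))
  shuffled <- proteinAlignment(stats::setNames(as.character(aln)[perm],
                                               names(aln)[perm]))
  h2 <- strictDiffSubShared(shuffled, fg)
  expect_identical(h1$column, h2$column)
  renamed <- proteinAlignment(stats::setNames(as.character(aln),
                                              paste0("zz_", names(aln))))
  h3 <- strictDiffSubShared(renamed, paste0("zz_", fg))
  expect_identical(h1$column, h3$column)
})

test_that("gap policy: default strict, relaxed mode tolerates background gaps", {
  aln <- proteinAlignment(c(f = "MK", b1 = "MR", b2 = "-R", b3 = "MR",
                            b4 = "MR", b5 = "MR"))
  strict <- strictDiffSubSingle(aln, "f")
  expect_identical(strict$column, 2L)  # column 1 has a background gap
  relaxed <- strictDiffSubSingle(aln, "f", allowBackgroundGaps = TRUE,
                                 minBackgroundCoverage = 0.8)
  expect_identical(relaxed$column, 2L)  # col 1: K==K, no differential change
  aln2 <- proteinAlignment(c(f = "AK", b1 = "MR", b2 = "-R", b3 = "MR",
                             b4 = "MR", b5 = "MR"))
  expect_identical(strictDiffSubSingle(aln2, "f", allowBackgroundGaps = TRUE,
                                       minBackgroundCoverage = 0.8)$column,
                   c(1L, 2L))
  # ignore list removes sequences from consideration entirely
  aln3 <- proteinAlignment(c(f = "K", beta2 = "K", b1 = "R", b2 = "R"))
  expect_equal(nrow(strictDiffSubShared(aln3, "f")), 0L)
  expect_equal(strictDiffSubShared(aln3, "f", ignore = "beta2")$column, 1L)
})

test_that("planted convergence is recovered exactly on conserved backgrounds", {
  base <- proteinAlignment(stats::setNames(
    rep(strrep("ACDEFGHIKLMNPQRSTVWY", 2), 8), sprintf("s%d", 1:8)))
  for (s in 1:25) {
    fg <- c("s1", "s2", "s3")
    pl <- plantConvergentSubstitutions(base, fg, 6, seed = s)
    got <- strictDiffSubShared(pl$alignment, fg)$column
    expect_identical(got, pl$columns)   # precision = recall = 1
    # foreground of size one, single-sequence definition
    pl1 <- plantConvergentSubstitutions(base, "s5", 4, seed = s + 100)
    got1 <- strictDiffSubSingle(pl1$alignment, "s5")$column
    expect_identical(got1, pl1$columns)
  }
})

test_that("identity census counts conserved columns and per-sequence diffs", {
  aln <- proteinAlignment(c(a = "MK", b = "MR"))
  cz <- identityCensus(aln)
  expect_equal(cz$nIdentical, 1L)
  expect_equal(cz$nColumns, 2L)

  all_same <- proteinAlignment(c(a = "MKV", b = "MKV", c = "MKV"))
  cz2 <- identityCensus(all_same)
  expect_equal(cz2$nIdentical, 3L)
  expect_true(all(cz2$diffCounts == 0))

  # brute-force check on random fixtures
  set.seed(5)
  for (rep in 1:20) {
    aln <- random_protein_aln(5, 30, gap_prob = 0.1)
    m <- paraselect:::.aln_matrix(aln)
    ident <- sum(vapply(seq_len(ncol(m)), function(j)
      length(unique(m[, j])) == 1L && !m[1, j] %in% c("-", "X", "*"),
      logical(1)))
    expect_equal(identityCensus(aln)$nIdentical, ident)
  }
})

test_that("pairwise differences count gap-residue but not gap-gap", {
  aln <- proteinAlignment(c(a = "MK-", b = "MR-", c = "M-K"))
  expect_equal(pairwiseDiff(aln, "a", "a"), 0L)
  expect_equal(pairwiseDiff(aln, "a", "b"), 1L)
  expect_equal(pairwiseDiff(aln, "a", "c"), 2L)
  set.seed(8)
  for (rep in 1:20) {
    aln <- random_protein_aln(4, 25, gap_prob = 0.15)
    expect_equal(pairwiseDiff(aln, "s01", "s03"),
                 pairwiseDiff(aln, "s03", "s01"))
  }
  expect_error(pairwiseDiff(aln, "s01", "nope"), "present")
})

test_that("reference mapping is a bijection over non-gap columns", {
  aln <- proteinAlignment(c(r = "M-KL", o = "MAKL"))
  expect_equal(mapToReference(aln, "r", 3), 2L)
  expect_equal(mapToReference(aln, "r", 1), 1L)
  expect_error(mapToReference(aln, "r", 2), "gapped")
  expect_equal(mapToReference(aln, "r", 2, nearest = TRUE), 1L)

  set.seed(99)
  aln <- random_protein_aln(3, 40, gap_prob = 0.2)
  ref <- paraselect:::.aln_matrix(aln)["s01", ]
  nongap <- which(ref != "-")
  mapped <- vapply(nongap, function(j) mapToReference(aln, "s01", j),
                   integer(1))
  expect_identical(mapped, seq_along(nongap))
})
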