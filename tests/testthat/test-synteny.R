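identity_setup <- function(nGenes = 120, nChrom = 2) {
  g <- simulateBaseGenome(nGenes, nChrom = nChrom)
  pairs <- data.frame(query_id = g$gene_id, target_id = g$gene_id,
                      stringsAsFactors = FALSE)
  list(genome = g, pairs = pairs)
}

test_that("self-synteny: one full-window hit containing the query", {
  s <- identity_setup()
  q <- s$genome$gene_id[30]  # interior of chr01
  hits <- findSyntenicRegions(q, s$genome, s$genome, s$pairs, window = 40)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$anchors, 40L)
  expect_true(hits$containsQueryHomolog)
  expect_equal(classifyContext(q, hits, s$pairs), "syntenic")

  # near a chromosome end the anchor count caps at the chromosome length
  qe <- s$genome$gene_id[1]
  he <- findSyntenicRegions(qe, s$genome, s$genome, s$pairs, window = 40)
  expect_equal(he$anchors, 21L)  # query + right half-window
})

test_that("anchor threshold: a lone homolog is not a syntenic region", {
  s <- identity_setup()
  q <- s$genome$gene_id[30]
  lone <- s$pairs[s$pairs$query_id == q, , drop = FALSE]
  hits <- findSyntenicRegions(q, s$genome, s$genome, lone, minAnchors = 4)
  expect_equal(nrow(hits), 0L)
  expect_equal(classifyContext(q, hits, lone), "transposed")
  nohom <- s$pairs[s$pairs$query_id == "nothere", , drop = FALSE]
  expect_error(findSyntenicRegions(q, s$genome, s$genome, nohom), "empty")
  expect_equal(classifyContext(q, data.frame(), nohom), "absent")
})

test_that("reported anchors are true homolog pairs inside both windows", {
  base <- simulateBaseGenome(300, nChrom = 3)
  wgd <- simulateWgdGenome(base, rounds = 1, retentionProb = 0.7, seed = 8)
  q <- base$gene_id[150]
  hits <- findSyntenicRegions(q, base, wgd$genome, wgd$pairs, window = 40)
  expect_gt(nrow(hits), 0L)
  qrow <- base[base$gene_id == q, ]
  for (i in seq_len(nrow(hits))) {
    ap <- hits$anchorPairs[[i]]
    for (r in seq_len(nrow(ap))) {
      expect_true(any(wgd$pairs$query_id == ap[r, "query"] &
                        wgd$pairs$target_id == ap[r, "target"]))
      qo <- base$ordinal[base$gene_id == ap[r, "query"]]
      expect_lte(abs(qo - qrow$ordinal), 20)
      to <- wgd$genome$ordinal[wgd$genome$gene_id == ap[r, "target"]]
      expect_true(to >= hits$ordinalStart[i] && to <= hits$ordinalEnd[i])
    }
  }
})

test_that("WGD with full retention yields syntenic depth two", {
  base <- simulateBaseGenome(200, nChrom = 2)
  wgd <- simulateWgdGenome(base, rounds = 1, retentionProb = 1, seed = 4)
  q <- base$gene_id[50]
  hits <- findSyntenicRegions(q, base, wgd$genome, wgd$pairs)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$containsQueryHomolog))
  expect_equal(unname(syntenicDepth(list(derived = hits))["derived"]), 2L)
  # identity comparison, single-copy genome: depth 1
  s <- identity_setup()
  h1 <- findSyntenicRegions(s$genome$gene_id[30], s$genome, s$genome, s$pairs)
  expect_equal(unname(syntenicDepth(list(self = h1))["self"]), 1L)
})

test_that("a relocated duplicate is classified as transposed", {
  base <- simulateBaseGenome(200, nChrom = 2)
  wgd <- simulateWgdGenome(base, rounds = 1, retentionProb = 1, seed = 5)
  q <- base$gene_id[60]  # lives on chr01; its block has no chr02 homologs
  g <- wgd$genome
  # relocate both homologs of the query to chr02 while neighbours stay
  for (tid in wgd$pairs$target_id[wgd$pairs$query_id == q]) {
    i <- which(g$gene_id == tid)
    g$chrom[i] <- "chr02"
    g$ordinal[i] <- max(g$ordinal[g$chrom == "chr02"]) + 1L
  }
  g <- g[order(g$chrom, g$ordinal), ]
  g$ordinal <- unlist(lapply(split(seq_len(nrow(g)), g$chrom), seq_along),
                      use.names = FALSE)
  hits <- findSyntenicRegions(q, base, g, wgd$pairs)
  expect_gt(nrow(hits), 0L)  # the neighbourhood blocks are still found
  expect_false(any(hits$containsQueryHomolog))
  expect_equal(classifyContext(q, hits, wgd$pairs), "transposed")
})

test_that("raising minAnchors never increases the number of hits", {
  base <- simulateBaseGenome(300, nChrom = 3)
  wgd <- simulateWgdGenome(base, rounds = 1, retentionProb = 0.5, seed = 9)
  q <- base$gene_id[100]
  counts <- vapply(c(4, 8, 12, 20), function(k)
    nrow(findSyntenicRegions(q, base, wgd$genome, wgd$pairs,
                             minAnchors = k)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tandem homolog arrays collapse to a single anchor", {
  base <- simulateBaseGenome(50, nChrom = 1)
  # target genome = base plus a tandem triplication of gene 25
  tg <- base
  extra <- tg[rep(25, 2), ]
  extra$gene_id <- paste0(extra$gene_id, c("_t1", "_t2"))
  extra$ordinal <- extra$ordinal + c(0.1, 0.2)
  tg <- rbind(tg, extra)
  tg <- tg[order(tg$chrom, tg$ordinal), ]
  tg$ordinal <- seq_len(nrow(tg))
  pairs <- data.frame(query_id = c(base$gene_id, rep(base$gene_id[25], 2)),
                      target_id = c(base$gene_id, extra$gene_id))
  q <- base$gene_id[25]
  hits <- findSyntenicRegions(q, base, tg, pairs, window = 10)
  expect_equal(nrow(hits), 1L)
  expect_lte(hits$anchors, 11L)  # the tandem copies add no extra anchors
})

test_that("genome annotation and homolog pair IO round-trips", {
  g <- simulateBaseGenome(30, nChrom = 2)
  f <- tempfile(fileext = ".tsv")
  writeGenomeAnnotation(g, f)
  g2 <- readGenomeAnnotation(f)
  expect_equal(g2$gene_id, g$gene_id)
  expect_equal(g2$ordinal, g$ordinal)
  pf <- tempfile(fileext = ".tsv")
  pairs <- data.frame(query_id = g$gene_id[1:5], target_id = g$gene_id[6:10])
  writeHomologPairs(pairs, pf)
  expect_equal(readHomologPairs(pf), pairs)
})
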