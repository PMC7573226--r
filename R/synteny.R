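# Windowed collinear-anchor micro-synteny search and syntenic/transposed
# classification of duplicated genes.  Windows are measured in gene
# ordinals, not base pairs; collinearity is the longest strictly monotone
# (either orientation) anchor chain within the window.

.ensure_ordinals <- function(genome) {
  stopifnot(all(c("chrom", "gene_id") %in% names(genome)))
  if (anyDuplicated(genome$gene_id))
    stop("gene ids must be unique", call. = FALSE)
  if (!"ordinal" %in% names(genome)) {
    stopifnot("start" %in% names(genome))
    genome <- genome[order(genome$chrom, genome$start), , drop = FALSE]
    genome$ordinal <- unlist(lapply(split(seq_len(nrow(genome)), genome$chrom),
                                    seq_along), use.names = FALSE)
  }
  genome
}

# longest strictly monotone chain (both coordinates strict; either
# orientation in the target); O(n^2) DP, windows are small
.longest_chain <- function(qo, to) {
  n <- length(qo)
  if (n == 0L) return(integer(0))
  best_dir <- integer(0); best_len <- 0L
  for (dir in c(1L, -1L)) {
    tt <- dir * to
    dp <- rep(1L, n); prev <- rep(0L, n)
    ord <- order(qo, tt)
    qs <- qo[ord]; ts <- tt[ord]
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (qs[j] < qs[i] && ts[j] < ts[i] && dp[j] + 1L > dp[i]) {
          dp[i] <- dp[j] + 1L; prev[i] <- j
        }
      }
    }
    if (max(dp) > best_len) {
      best_len <- max(dp)
      k <- which.max(dp); chain <- integer(0)
      while (k != 0L) {
        chain <- c(k, chain); k <- prev[k]
      }
      best_dir <- ord[chain]
    }
  }
  best_dir
}

#' Find syntenic regions supporting a query gene's genomic context
#'
#' Considers the window of `window` genes centered on the query, seeds
#' candidate target regions from the homologs of all windowed query genes,
#' and scores each region by the longest strictly monotone chain of
#' homolog anchor pairs (either orientation; strand is ignored).  Homologs
#' of one query gene lying within `tandemCollapse` ordinals of each other
#' collapse to a single anchor so tandem arrays do not inflate counts.
#' Regions with at least `minAnchors` chained anchors are reported, ranked
#' by anchor count with ties broken by target coordinate.
#'
#' @param queryGene Query gene id (must be present in `queryGenome`).
#' @param queryGenome,targetGenome Genome data.frames with columns `chrom`,
#'   `start`, `end`, `gene_id` (ordinals are derived from gene order if
#'   absent).
#' @param pairs Homolog pairs data.frame with columns `query_id`,
#'   `target_id`.
#' @param window Window size in genes (default 40).
#' @param minAnchors Minimum chained anchors per reported region
#'   (default 4).
#' @param tandemCollapse Ordinal distance within which same-query homologs
#'   collapse (default 2).
#' @return data.frame of hits: `chrom`, `ordinalStart`, `ordinalEnd`,
#'   `anchors`, `containsQueryHomolog`, plus a list column `anchorPairs`
#'   of 2-column matrices (query gene, target gene).
#' @export
findSyntenicRegions <- function(queryGene, queryGenome, targetGenome, pairs,
                                window = 40L, minAnchors = 4L,
                                tandemCollapse = 2L) {
  queryGenome <- .ensure_ordinals(queryGenome)
  targetGenome <- .ensure_ordinals(targetGenome)
  if (!queryGene %in% queryGenome$gene_id)
    stop(sprintf("query gene '%s' not in query genome", queryGene),
         call. = FALSE)
  if (!nrow(pairs)) stop("homolog pair list is empty", call. = FALSE)
  stopifnot(all(c("query_id", "target_id") %in% names(pairs)))

  qrow <- queryGenome[queryGenome$gene_id == queryGene, ]
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  qwin <- queryGenome[queryGenome$chrom == qrow$chrom &
                        queryGenome$ordinal >= qrow$ordinal - left &
                        queryGenome$ordinal <= qrow$ordinal + right, ]

  rel <- pairs[pairs$query_id %in% qwin$gene_id, , drop = FALSE]
  rel <- rel[rel$target_id %in% targetGenome$gene_id, , drop = FALSE]
  empty <- data.frame(chrom = character(0), ordinalStart = integer(0),
                      ordinalEnd = integer(0), anchors = integer(0),
                      containsQueryHomolog = logical(0))
  empty$anchorPairs <- list()
  if (!nrow(rel)) return(empty)

  tidx <- match(rel$target_id, targetGenome$gene_id)
  rel$t_chrom <- targetGenome$chrom[tidx]
  rel$t_ord <- targetGenome$ordinal[tidx]
  rel$q_ord <- qwin$ordinal[match(rel$query_id, qwin$gene_id)]

  qhoms <- pairs$target_id[pairs$query_id == queryGene]

  hits <- list()
  for (chr in unique(rel$t_chrom)) {
    sub <- rel[rel$t_chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$t_ord), , drop = FALSE]
    gap <- c(0, diff(sub$t_ord))
    cluster <- cumsum(gap > window)
    for (cl in unique(cluster)) {
      anc <- sub[cluster == cl, , drop = FALSE]
      # collapse tandem duplicates: same query gene, nearby target ordinals
      keep <- rep(TRUE, nrow(anc))
      for (g in unique(anc$query_id)) {
        w <- which(anc$query_id == g)
        if (length(w) > 1L) {
          last_ord <- anc$t_ord[w[1L]]
          for (k in w[-1L]) {
            if (anc$t_ord[k] - last_ord <= tandemCollapse) keep[k] <- FALSE
            else last_ord <- anc$t_ord[k]
          }
        }
      }
      anc <- anc[keep, , drop = FALSE]
      chain <- .longest_chain(anc$q_ord, anc$t_ord)
      if (length(chain) < minAnchors) next
      ch <- anc[chain, , drop = FALSE]
      lo <- min(ch$t_ord); hi <- max(ch$t_ord)
      contains <- any(anc$target_id %in% qhoms)
      hits[[length(hits) + 1L]] <- list(
        chrom = chr, ordinalStart = lo, ordinalEnd = hi,
        anchors = length(chain), containsQueryHomolog = contains,
        anchorPairs = cbind(query = ch$query_id, target = ch$target_id))
    }
  }
  if (!length(hits)) return(empty)
  out <- data.frame(
    chrom = vapply(hits, `[[`, character(1), "chrom"),
    ordinalStart = vapply(hits, function(h) as.integer(h$ordinalStart), integer(1)),
    ordinalEnd = vapply(hits, function(h) as.integer(h$ordinalEnd), integer(1)),
    anchors = vapply(hits, function(h) as.integer(h$anchors), integer(1)),
    containsQueryHomolog = vapply(hits, `[[`, logical(1), "containsQueryHomolog"),
    stringsAsFactors = FALSE)
  out$anchorPairs <- lapply(hits, `[[`, "anchorPairs")
  ord <- order(-out$anchors, out$chrom, out$ordinalStart)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a gene's genomic context in a target genome
#'
#' `"syntenic"` when a reported region contains a homolog of the query
#' itself, `"transposed"` when homologs exist in the target genome but no
#' region contains one (the gene moved to a new genomic context), and
#' `"absent"` when no homolog exists.
#'
#' @param queryGene Query gene id.
#' @param hits Result of [findSyntenicRegions()].
#' @param pairs Homolog pairs data.frame.
#' @return One of `"syntenic"`, `"transposed"`, `"absent"`.
#' @export
classifyContext <- function(queryGene, hits, pairs) {
  qhoms <- pairs$target_id[pairs$query_id == queryGene]
  if (!length(qhoms)) return("absent")
  if (nrow(hits) && any(hits$containsQueryHomolog)) return("syntenic")
  "transposed"
}

#' Syntenic depth across target genomes
#'
#' The number of reported syntenic regions per target genome, a proxy for
#' retained polyploid copies of the query's block.
#'
#' @param results Named list of [findSyntenicRegions()] results, one per
#'   target genome.
#' @return Named integer vector of hit counts.
#' @export
syntenicDepth <- function(results) {
  stopifnot(length(results) >= 1L)
  vapply(results, nrow, integer(1))
}

#' Read / write BED-like genome annotations and homolog pairs
#'
#' Genome annotations are tab-separated with columns `chrom`, `start`,
#' `end`, `gene_id`, `family_id`, `strand`; homolog pairs are two
#' tab-separated columns `query_id`, `target_id`.
#'
#' @param path File path.
#' @return `readGenomeAnnotation()`/`readHomologPairs()` return
#'   data.frames; writers return `path` invisibly.
#' @export
readGenomeAnnotation <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  .ensure_ordinals(g)
}

#' @rdname readGenomeAnnotation
#' @param genome A genome data.frame.
#' @export
writeGenomeAnnotation <- function(genome, path) {
  cols <- intersect(c("chrom", "start", "end", "gene_id", "family_id",
                      "strand"), names(genome))
  utils::write.table(genome[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readGenomeAnnotation
#' @export
readHomologPairs <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(p)[1:2] <- c("query_id", "target_id")
  p
}

#' @rdname readGenomeAnnotation
#' @param pairs A homolog pairs data.frame.
#' @export
writeHomologPairs <- function(pairs, path) {
  utils::write.table(pairs[, c("query_id", "target_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
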