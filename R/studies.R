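# Simulation-study drivers: planted-signal recovery, test calibration and
# power, parameter recovery, and synteny-block recovery.  These run the
# package end-to-end on generated data and are used by the acceptance
# checks; sizes are arguments so studies scale from smoke tests to full
# calibrations.

#' Planted convergent-substitution recovery study
#'
#' For each seed, plants strictly convergent substitutions on a conserved
#' background and scans for them; reports exact-recovery precision and
#' recall of the shared-strict scanner.
#'
#' @param nSeeds Number of independent planted fixtures.
#' @param seed Base RNG seed.
#' @param nSeq,nColumns,nForeground,nSites Fixture dimensions.
#' @return List with `precision`, `recall` (pooled over seeds) and
#'   `nExact` (seeds recovered exactly).
#' @export
diffsubRecoveryStudy <- function(nSeeds = 100L, seed = 1L, nSeq = 8L,
                                 nColumns = 60L, nForeground = 3L,
                                 nSites = 6L) {
  aa <- sort(unique(senseCodonAminoAcids()))
  tp <- fp <- fn <- 0L
  nExact <- 0L
  for (i in seq_len(nSeeds)) {
    set.seed(seed + i)
    cons <- sample(aa, nColumns, replace = TRUE)
    base <- proteinAlignment(stats::setNames(
      rep(paste0(cons, collapse = ""), nSeq), sprintf("s%02d", seq_len(nSeq))))
    fg <- sprintf("s%02d", seq_len(nForeground))
    pl <- plantConvergentSubstitutions(base, fg, nSites, seed = seed + i)
    got <- strictDiffSubShared(pl$alignment, fg)$column
    tp <- tp + length(intersect(got, pl$columns))
    fp <- fp + length(setdiff(got, pl$columns))
    fn <- fn + length(setdiff(pl$columns, got))
    if (identical(got, pl$columns)) nExact <- nExact + 1L
  }
  list(precision = if (tp + fp) tp / (tp + fp) else 1,
       recall = if (tp + fn) tp / (tp + fn) else 1,
       nExact = nExact)
}

.study_sim <- function(nTaxa, nCodons, siteClass, kappa, seed) {
  tr <- simulateYuleTree(nTaxa, depthScale = 0.5, seed = seed)
  spec <- codonSubstitutionSpec(kappa = kappa, siteClass = siteClass)
  sim <- simulateCodonAlignment(tr, spec, nCodons, seed = seed + 10000L)
  c(sim, list(tree = tr))
}

#' Type-I error calibration of the M7-vs-M8 test
#'
#' Simulates alignments under M7 (no positive selection), fits M7 and M8
#' (warm-started series) and records the LRT p-value per replicate.
#'
#' @param nReplicates Number of replicates.
#' @param seed Base RNG seed.
#' @param nTaxa,nCodons Design size (defaults 12 taxa, 300 codons).
#' @param p,q Beta parameters of the generating M7 model.
#' @param kappa Generating transition/transversion ratio.
#' @param alpha Nominal test level.
#' @return List with `pValues`, `rejectionRate` and the design used.
#' @export
lrtCalibrationStudy <- function(nReplicates = 60L, seed = 1L, nTaxa = 12L,
                                nCodons = 300L, p = 0.5, q = 1.5,
                                kappa = 2, alpha = 0.05) {
  pv <- numeric(nReplicates)
  for (i in seq_len(nReplicates)) {
    sim <- .study_sim(nTaxa, nCodons, siteClassModel("M7", p = p, q = q),
                      kappa, seed + 37L * i)
    fits <- fitSiteModelSeries(sim$alignment, sim$tree, c("M7", "M8"),
                               nstarts = 1)
    pv[i] <- lrtSiteModels(fits$M7, fits$M8)$pValue
  }
  list(pValues = pv, rejectionRate = mean(pv < alpha),
       design = c(nTaxa = nTaxa, nCodons = nCodons, n = nReplicates))
}

#' Power and site-recovery study under M8
#'
#' Simulates under M8 with a positively selected class, fits the M7/M8
#' pair, and pools empirical-Bayes site identification across replicates.
#'
#' @inheritParams lrtCalibrationStudy
#' @param p0 Weight of the beta component in the generating M8.
#' @param omegaS Selected-class omega of the generating M8.
#' @param threshold Posterior probability threshold for flagging sites.
#' @param method Posterior method used for flagging (`"BEB"` or `"NEB"`).
#' @param computePosteriors If `FALSE`, skip site identification and
#'   report only the LRT rejection rate (faster for power studies).
#' @return List with `rejectionRate`, `fdr` (pooled false discovery rate
#'   of flagged sites against the true simulated class), `nFlagged`,
#'   `pValues`.
#' @export
selectionRecoveryStudy <- function(nReplicates = 30L, seed = 1L,
                                   nTaxa = 12L, nCodons = 300L,
                                   p0 = 0.85, p = 0.5, q = 1.5,
                                   omegaS = 4, kappa = 2,
                                   threshold = 0.90, method = "BEB",
                                   alpha = 0.05,
                                   computePosteriors = TRUE) {
  pv <- numeric(nReplicates)
  tp <- fp <- 0L
  for (i in seq_len(nReplicates)) {
    sim <- .study_sim(nTaxa, nCodons,
                      siteClassModel("M8", p0 = p0, p = p, q = q,
                                     omegaS = omegaS),
                      kappa, seed + 101L * i)
    fits <- fitSiteModelSeries(sim$alignment, sim$tree, c("M7", "M8"),
                               nstarts = 1)
    pv[i] <- lrtSiteModels(fits$M7, fits$M8)$pValue
    if (computePosteriors) {
      post <- sitePosteriors(fits$M8, method)
      flagged <- which(post > threshold)
      truly <- which(sim$siteOmega > 1)
      tp <- tp + length(intersect(flagged, truly))
      fp <- fp + length(setdiff(flagged, truly))
    }
  }
  list(rejectionRate = mean(pv < alpha),
       fdr = if (tp + fp) fp / (tp + fp) else 0,
       nFlagged = tp + fp,
       pValues = pv)
}

#' One-ratio (M0) parameter recovery study
#'
#' @inheritParams lrtCalibrationStudy
#' @param omega,kappa Generating parameter values.
#' @return List with per-seed `omegaHat`, `kappaHat` and their medians.
#' @export
m0RecoveryStudy <- function(nReplicates = 20L, seed = 1L, nTaxa = 16L,
                            nCodons = 500L, omega = 0.3, kappa = 2) {
  oh <- kh <- numeric(nReplicates)
  for (i in seq_len(nReplicates)) {
    sim <- .study_sim(nTaxa, nCodons, siteClassModel("M0", omega = omega),
                      kappa, seed + 211L * i)
    f <- fitSiteModel(sim$alignment, sim$tree, siteClassModel("M0"),
                      nstarts = 1)
    oh[i] <- fitParams(f)[["omega"]]
    kh[i] <- fitParams(f)[["kappa"]]
  }
  list(omegaHat = oh, kappaHat = kh,
       omegaMedian = stats::median(oh), kappaMedian = stats::median(kh))
}

#' Homeologous-block recovery study on simulated WGD genomes
#'
#' For each seed, simulates one round of whole-genome duplication with
#' fractionation, then asks whether the micro-synteny search reports both
#' the original and the duplicated block of an interior query gene with at
#' least `minAnchors` anchors.
#'
#' @param nSeeds Number of simulated genomes.
#' @param seed Base RNG seed.
#' @param nGenes,nChrom Base genome size.
#' @param retentionProb Duplicate retention probability.
#' @param window,minAnchors Synteny search parameters.
#' @return List with `bothBlocksRate`, per-seed logical `bothBlocks` and
#'   `depth` (hit counts).
#' @export
syntenyRecoveryStudy <- function(nSeeds = 50L, seed = 1L, nGenes = 500L,
                                 nChrom = 5L, retentionProb = 0.6,
                                 window = 40L, minAnchors = 4L) {
  both <- logical(nSeeds)
  depth <- integer(nSeeds)
  base <- simulateBaseGenome(nGenes, nChrom = nChrom)
  query <- base$gene_id[base$chrom == base$chrom[1]][
    ceiling(sum(base$chrom == base$chrom[1]) / 2)]
  qchrom <- base$chrom[base$gene_id == query]
  for (i in seq_len(nSeeds)) {
    wgd <- simulateWgdGenome(base, rounds = 1, retentionProb = retentionProb,
                             seed = seed + i)
    hits <- findSyntenicRegions(query, base, wgd$genome, wgd$pairs,
                                window = window, minAnchors = minAnchors)
    depth[i] <- nrow(hits)
    both[i] <- all(c(qchrom, paste0(qchrom, "_d1")) %in% hits$chrom)
  }
  list(bothBlocksRate = mean(both), bothBlocks = both, depth = depth)
}
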