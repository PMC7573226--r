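# Orchestration: a single structured configuration drives alignment prep,
# differential-substitution scanning, the dosage census, site-model
# selection tests and synteny classification, with per-stage outputs and a
# consolidated run report.

.STAGE_ORDER <- c("prep", "diffsub", "dosage", "siteselect", "synteny")

.DEFAULT_THRESHOLDS <- list(coverage = 0.95, posterior = 0.90,
                            window = 40L, min_anchors = 4L)

# small FNV-1a hash for reproducibility stamps (no external digest
# dependency needed)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stage_seed <- function(seed, stage) {
  i <- match(stage, .STAGE_ORDER)
  as.integer((as.numeric(seed) * 1009 + i * 101) %% 2147483647)
}

#' Validate an analysis configuration
#'
#' Accepts a YAML file path or a nested list; checks every field and
#' cross-reference (file existence, foreground ids present in the
#' alignment, tree/alignment label agreement), fills threshold defaults
#' (coverage 0.95, posterior 0.90, window 40, min anchors 4), and reports
#' *all* violations at once rather than failing at the first.
#'
#' @param config Path to a YAML configuration file, or an equivalent list
#'   with entries `seed`, `outdir`, `stages`, `inputs`, `analysis`,
#'   `thresholds`.
#' @return The validated config list (class `paraselectConfig`).
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  if (is.null(config$seed)) note("seed: required")
  else if (!is.numeric(config$seed)) note("seed: must be an integer")
  if (is.null(config$outdir)) note("outdir: required")

  stages <- config$stages
  if (is.null(stages)) stages <- .STAGE_ORDER
  bad <- setdiff(stages, .STAGE_ORDER)
  if (length(bad)) note(sprintf("stages: unknown stage(s) %s",
                                paste(bad, collapse = ", ")))
  stages <- .STAGE_ORDER[.STAGE_ORDER %in% stages]
  config$stages <- stages
  if (!length(stages)) note("stages: at least one stage required")

  config$thresholds <- utils::modifyList(.DEFAULT_THRESHOLDS,
                                         as.list(config$thresholds))
  th <- config$thresholds
  if (th$coverage <= 0 || th$coverage > 1)
    note("thresholds.coverage: must lie in (0, 1]")
  if (th$posterior < 0 || th$posterior > 1)
    note("thresholds.posterior: must lie in [0, 1]")
  if (th$window < 1) note("thresholds.window: must be >= 1")
  if (th$min_anchors < 1) note("thresholds.min_anchors: must be >= 1")

  ins <- as.list(config$inputs)
  need_file <- function(field) {
    p <- ins[[field]]
    if (is.null(p)) {
      note(sprintf("inputs.%s: required for requested stages", field))
      return(NULL)
    }
    if (!file.exists(p)) {
      note(sprintf("inputs.%s: file not found: %s", field, p))
      return(NULL)
    }
    p
  }

  if ("prep" %in% stages || "siteselect" %in% stages)
    need_file("codon_alignment")
  if ("diffsub" %in% stages) need_file("protein_alignment")
  if ("dosage" %in% stages) need_file("species_table")
  if ("siteselect" %in% stages) need_file("tree")
  if ("synteny" %in% stages) {
    need_file("query_genome"); need_file("target_genome")
    need_file("homolog_pairs")
  }

  an <- as.list(config$analysis)
  if ("diffsub" %in% stages) {
    if (is.null(an$foreground) || !length(an$foreground))
      note("analysis.foreground: required for diffsub")
    else if (!is.null(ins$protein_alignment) &&
             file.exists(ins$protein_alignment)) {
      aln <- readAlignment(ins$protein_alignment, "protein")
      miss <- setdiff(an$foreground, names(aln))
      if (length(miss))
        note(sprintf("analysis.foreground: id(s) absent from alignment: %s",
                     paste(miss, collapse = ", ")))
      if (!is.null(an$reference_id) && !an$reference_id %in% names(aln))
        note(sprintf("analysis.reference_id: '%s' absent from alignment",
                     an$reference_id))
    }
  }
  if ("siteselect" %in% stages &&
      !is.null(ins$codon_alignment) && !is.null(ins$tree) &&
      file.exists(ins$codon_alignment %||% "") &&
      file.exists(ins$tree %||% "")) {
    aln <- readAlignment(ins$codon_alignment, "codon")
    tr <- ape::read.tree(ins$tree)
    if (!setequal(names(aln), tr$tip.label))
      note("inputs.tree: tip labels do not match codon alignment ids")
  }
  if ("synteny" %in% stages && is.null(an$query_gene))
    note("analysis.query_gene: required for synteny")

  if (length(errs))
    stop(paste(c("invalid configuration:", paste(" -", errs)),
               collapse = "\n"), call. = FALSE)
  config$analysis <- an
  config$inputs <- ins
  structure(config, class = c("paraselectConfig", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in dependency order (prep, diffsub,
#' dosage, siteselect, synteny).  Each stage writes its outputs under
#' `<outdir>/<stage>/`; a stage failure halts downstream stages but
#' preserves completed outputs.  All randomness derives from the single
#' top-level seed via per-stage substreams, so outputs are deterministic
#' for a fixed configuration.
#'
#' @param config A validated configuration (see [validateConfig()]); a
#'   path or raw list is validated first.
#' @return A run report list (per-stage summaries, package version, config
#'   hash, wall-clock seconds per stage), also written to
#'   `<outdir>/report.json`.
#' @export
runAnalysis <- function(config) {
  if (!inherits(config, "paraselectConfig")) config <- validateConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(outdir, "run.log"), open = "at")
  on.exit(close(logcon), add = TRUE)
  hash <- .config_hash(unclass(config))
  .log_line(logcon, "run start: config hash %s, seed %s", hash, config$seed)

  report <- list(package = "paraselect",
                 version = as.character(utils::packageVersion("paraselect")),
                 configHash = hash, seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  for (stage in config$stages) {
    sdir <- file.path(outdir, stage)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      switch(stage,
             prep = .stage_prep(config, sdir, state),
             diffsub = .stage_diffsub(config, sdir, state),
             dosage = .stage_dosage(config, sdir, state),
             siteselect = .stage_siteselect(config, sdir, state),
             synteny = .stage_synteny(config, sdir, state)),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "stageError"))
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "stageError")) {
      .log_line(logcon, "stage %s FAILED after %.2fs: %s", stage, el, res$error)
      report$stages[[stage]] <- list(status = "failed", error = res$error,
                                     seconds = round(el, 3))
      break
    }
    .log_line(logcon, "stage %s done in %.2fs", stage, el)
    report$stages[[stage]] <- c(list(status = "ok", seconds = round(el, 3)),
                                res)
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(logcon, "run end: %d stage(s) recorded", length(report$stages))
  invisible(report)
}

.stage_prep <- function(config, sdir, state) {
  aln <- readAlignment(config$inputs$codon_alignment, "codon")
  if (!is.null(config$inputs$cds)) {
    # inputs may arrive as a protein alignment + CDS; back-translate first
    prot <- translateCodonAlignment(aln)
    state$protein_full <- prot
  }
  fl <- coverageFilter(aln, config$thresholds$coverage)
  writeAlignment(fl$alignment, file.path(sdir, "filtered_codon.fasta"))
  utils::write.table(
    data.frame(kept_codon_column = fl$kept),
    file.path(sdir, "kept_columns.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  prot <- suppressWarnings(translateCodonAlignment(fl$alignment))
  writeAlignment(prot, file.path(sdir, "filtered_protein.fasta"))
  state$codon_filtered <- fl$alignment
  state$protein_filtered <- prot
  list(nSequences = length(aln), codonColumnsIn = codonColumns(aln),
       codonColumnsKept = length(fl$kept))
}

.stage_diffsub <- function(config, sdir, state) {
  aln <- readAlignment(config$inputs$protein_alignment, "protein")
  an <- config$analysis
  shared <- strictDiffSubShared(aln, an$foreground,
                                ignore = an$ignore %||% character(0),
                                referenceId = an$reference_id)
  singles <- do.call(rbind, lapply(an$foreground, function(f)
    strictDiffSubSingle(aln, f, ignore = setdiff(an$foreground, f),
                        referenceId = an$reference_id)))
  utils::write.table(shared, file.path(sdir, "shared_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(singles, file.path(sdir, "single_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  census <- identityCensus(aln)
  summary <- list(nSharedHits = nrow(shared), nSingleHits = nrow(singles),
                  nIdenticalColumns = census$nIdentical,
                  nColumns = census$nColumns)
  jsonlite::write_json(summary, file.path(sdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary
}

.stage_dosage <- function(config, sdir, state) {
  tab <- utils::read.table(config$inputs$species_table, header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  rep <- dosageReport(tab)
  utils::write.table(.table_ratios(tab), file.path(sdir, "ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(nSpecies = rep$nSpecies,
              ratioCounts = as.list(rep$ratioCounts),
              proportions = as.list(rep$proportions),
              fisherP = rep$fisherP)
  jsonlite::write_json(out, file.path(sdir, "dosage.json"),
                       auto_unbox = TRUE, digits = NA)
  list(nSpecies = rep$nSpecies, fisherP = rep$fisherP)
}

.stage_siteselect <- function(config, sdir, state) {
  aln <- state$codon_filtered %||%
    readAlignment(config$inputs$codon_alignment, "codon")
  tree <- ape::read.tree(config$inputs$tree)
  models <- config$analysis$models %||% c("M7", "M8")
  nstarts <- config$analysis$nstarts %||% 3L
  fits <- fitSiteModelSeries(aln, tree, models, nstarts = nstarts)
  lrts <- list()
  for (pair in .nested_pairs) {
    if (all(pair %in% names(fits))) {
      lr <- lrtSiteModels(fits[[pair[1L]]], fits[[pair[2L]]])
      lrts[[paste(pair, collapse = "_vs_")]] <-
        list(statistic = lr$statistic, df = lr$df, pValue = lr$pValue)
    }
  }
  posterior_model <- intersect(c("M8", "M2a"), names(fits))
  sites <- NULL
  if (length(posterior_model)) {
    fit <- fits[[posterior_model[1L]]]
    neb <- sitePosteriors(fit, "NEB")
    beb <- sitePosteriors(fit, "BEB")
    thr <- config$thresholds$posterior
    sites <- data.frame(site = seq_along(neb), NEB = neb, BEB = beb,
                        selected = beb > thr)
    if (!is.null(config$analysis$reference_id) &&
        config$analysis$reference_id %in% names(aln))
      sites$refPosition <- vapply(sites$site, function(j)
        mapToReference(aln, config$analysis$reference_id, j, nearest = TRUE),
        integer(1))
    utils::write.table(sites, file.path(sdir, "site_posteriors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fitrep <- lapply(fits, function(f)
    list(logLik = f@logLik, npar = f@npar,
         params = as.list(f@params),
         converged = isTRUE(f@convergence$converged)))
  jsonlite::write_json(list(fits = fitrep, lrt = lrts),
                       file.path(sdir, "fits.json"), auto_unbox = TRUE,
                       digits = NA)
  list(models = names(fits),
       logLik = vapply(fits, function(f) f@logLik, numeric(1)),
       lrt = lrts,
       nSelected = if (is.null(sites)) NA_integer_ else sum(sites$selected))
}

.stage_synteny <- function(config, sdir, state) {
  qg <- readGenomeAnnotation(config$inputs$query_genome)
  tg <- readGenomeAnnotation(config$inputs$target_genome)
  pairs <- readHomologPairs(config$inputs$homolog_pairs)
  th <- config$thresholds
  hits <- findSyntenicRegions(config$analysis$query_gene, qg, tg, pairs,
                              window = th$window,
                              minAnchors = th$min_anchors)
  cls <- classifyContext(config$analysis$query_gene, hits, pairs)
  utils::write.table(hits[, setdiff(names(hits), "anchorPairs")],
                     file.path(sdir, "synteny_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(queryGene = config$analysis$query_gene,
                            classification = cls, nHits = nrow(hits)),
                       file.path(sdir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)
  list(classification = cls, nHits = nrow(hits))
}
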