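# Strict differential-substitution scanning of protein alignments against a
# foreground partition, identity/divergence censuses and reference mapping.

.diffsub_scan <- function(pm, foreground, background, mode,
                          allowBackgroundGaps = FALSE,
                          minBackgroundCoverage = 0.8,
                          referenceRow = NULL, offset = 0L) {
  bad <- c("-", "X", "*")
  fi <- match(foreground, rownames(pm))
  bi <- match(background, rownames(pm))
  hits <- list()
  for (j in seq_len(ncol(pm))) {
    col <- pm[, j]
    fg <- col[fi]
    if (any(fg %in% bad)) next
    if (length(unique(fg)) != 1L) next
    bg <- col[bi]
    if (allowBackgroundGaps) {
      keep <- !(bg %in% bad)
      if (mean(keep) < minBackgroundCoverage) next
      bg <- bg[keep]
      if (!length(bg)) next
    } else {
      if (any(bg %in% bad)) next
    }
    if (length(unique(bg)) != 1L) next
    if (fg[1L] == bg[1L]) next
    hits[[length(hits) + 1L]] <- list(column = j, fgAa = fg[1L], bgAa = bg[1L])
  }
  if (!length(hits))
    return(data.frame(column = integer(0), refPosition = integer(0),
                      fgAa = character(0), bgAa = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  df <- data.frame(
    column = vapply(hits, `[[`, integer(1), "column"),
    refPosition = NA_integer_,
    fgAa = vapply(hits, `[[`, character(1), "fgAa"),
    bgAa = vapply(hits, `[[`, character(1), "bgAa"),
    mode = mode, stringsAsFactors = FALSE)
  if (!is.null(referenceRow))
    df$refPosition <- vapply(df$column, function(cl) {
      if (referenceRow[cl] == "-") NA_integer_
      else sum(referenceRow[seq_len(cl)] != "-") + as.integer(offset)
    }, integer(1))
  df
}

#' Strictly differentially substituted columns shared by a foreground
#'
#' Reports alignment columns where every foreground sequence carries one
#' identical amino acid, every background sequence carries one identical
#' *different* amino acid, and (by default) no gap or ambiguity occurs in
#' any considered sequence.  `X` and other ambiguity codes never match any
#' amino acid.
#'
#' @param aln A [ProteinAlignment-class].
#' @param foreground Non-empty character vector of foreground ids.
#' @param background Background ids; defaults to all remaining sequences
#'   not listed in `ignore`.
#' @param ignore Ids excluded from the scan entirely (e.g. a paralog of a
#'   focal species).
#' @param allowBackgroundGaps Relax the background condition to "all
#'   non-gap background residues agree", requiring background coverage of
#'   at least `minBackgroundCoverage`.
#' @param minBackgroundCoverage Minimum non-gap background fraction under
#'   the relaxed policy (default 0.8).
#' @param referenceId Optional id used to report reference residue numbers
#'   (1-based on the ungapped reference).
#' @param offset Added to reference positions (mature-slice to full-length
#'   numbering).
#' @return data.frame with columns `column`, `refPosition`, `fgAa`, `bgAa`,
#'   `mode`, ordered by column.
#' @examples
#' aln <- proteinAlignment(c(f1 = "MKV", f2 = "MKV", b1 = "MRV", b2 = "MRV"))
#' strictDiffSubShared(aln, c("f1", "f2"))
#' @export
strictDiffSubShared <- function(aln, foreground, background = NULL,
                                ignore = character(0),
                                allowBackgroundGaps = FALSE,
                                minBackgroundCoverage = 0.8,
                                referenceId = NULL, offset = 0L) {
  stopifnot(is(aln, "ProteinAlignment"))
  ids <- names(aln)
  if (!length(foreground)) stop("foreground must be non-empty", call. = FALSE)
  if (!all(foreground %in% ids))
    stop("foreground ids missing from alignment", call. = FALSE)
  if (is.null(background)) background <- setdiff(ids, c(foreground, ignore))
  if (!length(background)) stop("background must be non-empty", call. = FALSE)
  if (length(intersect(foreground, background)))
    stop("foreground and background must be disjoint", call. = FALSE)
  pm <- .aln_matrix(aln)
  refrow <- if (!is.null(referenceId)) pm[referenceId, ] else NULL
  .diffsub_scan(pm, foreground, background, "shared-strict",
                allowBackgroundGaps, minBackgroundCoverage, refrow, offset)
}

#' Differential substitutions of a single focal sequence
#'
#' Columns where the focal sequence has an amino acid differing from a
#' single amino acid shared by all background sequences; equivalent to
#' [strictDiffSubShared()] with a singleton foreground.
#'
#' @param aln A [ProteinAlignment-class].
#' @param focalId The focal sequence id.
#' @inheritParams strictDiffSubShared
#' @return data.frame as in [strictDiffSubShared()], `mode =
#'   "single-sequence"`.
#' @export
strictDiffSubSingle <- function(aln, focalId, background = NULL,
                                ignore = character(0),
                                allowBackgroundGaps = FALSE,
                                minBackgroundCoverage = 0.8,
                                referenceId = NULL, offset = 0L) {
  stopifnot(is(aln, "ProteinAlignment"))
  ids <- names(aln)
  if (!focalId %in% ids)
    stop(sprintf("focal id '%s' not in alignment", focalId), call. = FALSE)
  if (is.null(background)) background <- setdiff(ids, c(focalId, ignore))
  if (focalId %in% background)
    stop("focal sequence may not be in the background", call. = FALSE)
  if (!length(background)) stop("background must be non-empty", call. = FALSE)
  pm <- .aln_matrix(aln)
  refrow <- if (!is.null(referenceId)) pm[referenceId, ] else NULL
  .diffsub_scan(pm, focalId, background, "single-sequence",
                allowBackgroundGaps, minBackgroundCoverage, refrow, offset)
}

#' Identity census of an alignment
#'
#' A column counts as identical iff all sequences share one amino acid (a
#' gap never counts as identity).  Per-sequence difference counts are taken
#' against the column-wise majority residue (most frequent non-gap amino
#' acid, ties broken alphabetically).
#'
#' @param aln A non-empty [ProteinAlignment-class].
#' @return List with `nIdentical`, `nColumns`, and `diffCounts` (named
#'   integer vector per sequence).
#' @export
identityCensus <- function(aln) {
  stopifnot(is(aln, "ProteinAlignment"), length(aln) > 0L)
  pm <- .aln_matrix(aln)
  bad <- c("-", "X", "*")
  ident <- vapply(seq_len(ncol(pm)), function(j) {
    col <- pm[, j]
    !any(col %in% bad) && length(unique(col)) == 1L
  }, logical(1))
  consensus <- vapply(seq_len(ncol(pm)), function(j) {
    col <- pm[, j]
    col <- col[!(col %in% bad)]
    if (!length(col)) return(NA_character_)
    tb <- table(col)
    names(tb)[which.max(tb)][1L]  # table is alphabetical; ties -> first
  }, character(1))
  diffs <- apply(pm, 1L, function(s) sum(s != consensus, na.rm = TRUE))
  list(nIdentical = sum(ident), nColumns = ncol(pm),
       diffCounts = diffs)
}

#' Number of differing columns between two aligned sequences
#'
#' Gap versus residue counts as a difference; gap versus gap does not.
#'
#' @param aln A [ProteinAlignment-class] (or [CodonAlignment-class]).
#' @param idA,idB Sequence ids.
#' @return Integer count.
#' @export
pairwiseDiff <- function(aln, idA, idB) {
  ids <- names(aln)
  if (!idA %in% ids || !idB %in% ids)
    stop("both ids must be present in the alignment", call. = FALSE)
  m <- if (is(aln, "CodonAlignment")) .codon_matrix(aln) else .aln_matrix(aln)
  sum(m[idA, ] != m[idB, ])
}

#' Map an alignment column to a reference residue number
#'
#' Returns the 1-based index of the reference residue occupying `column`
#' on the ungapped reference sequence, plus `offset` (used to translate
#' mature-slice numbering back to full-length precursor numbering).  For
#' codon alignments the column is a codon column and the result a codon
#' (residue) number.
#'
#' @param aln A [ProteinAlignment-class] or [CodonAlignment-class].
#' @param referenceId Reference sequence id.
#' @param column 1-based alignment column (codon column for codon
#'   alignments).
#' @param offset Integer added to the result.
#' @param nearest If `TRUE` and the reference is gapped at `column`,
#'   return the nearest preceding reference residue instead of erroring.
#' @return Integer residue number.
#' @export
mapToReference <- function(aln, referenceId, column, offset = 0L,
                           nearest = FALSE) {
  stopifnot(is(aln, "ProteinAlignment") || is(aln, "CodonAlignment"))
  if (!referenceId %in% names(aln))
    stop(sprintf("reference '%s' not in alignment", referenceId), call. = FALSE)
  is_codon <- is(aln, "CodonAlignment")
  ref <- if (is_codon) .codon_matrix(aln)[referenceId, ]
         else .aln_matrix(aln)[referenceId, ]
  gap <- if (is_codon) "---" else "-"
  if (column < 1L || column > length(ref))
    stop("column out of range", call. = FALSE)
  if (ref[column] == gap && !nearest)
    stop(sprintf("reference is gapped at column %d", column), call. = FALSE)
  n <- sum(ref[seq_len(column)] != gap)
  if (n == 0L)
    stop("no reference residue at or before the requested column", call. = FALSE)
  as.integer(n + offset)
}
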