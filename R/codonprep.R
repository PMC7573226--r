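# Codon alignment preparation: back-translation, the codon-coverage filter,
# codon-position extraction, translation and mature-region slicing.
# All coordinates are 1-based, closed intervals.

#' Back-translate a protein alignment onto its coding sequences
#'
#' Replaces each aligned amino acid with its source codon and each protein
#' gap with `---`.  Each coding sequence must translate exactly to the
#' ungapped protein sequence under the standard genetic code (a terminal
#' stop codon, if present, is stripped first).
#'
#' @param proteinAln A [ProteinAlignment-class].
#' @param cds Named character vector (or list) of ungapped coding sequences,
#'   names matching the alignment ids.
#' @return A [CodonAlignment-class] with 3x the protein column count.
#' @examples
#' backtranslate(proteinAlignment(c(a = "M-A")), c(a = "ATGGCT"))
#' @export
backtranslate <- function(proteinAln, cds) {
  stopifnot(is(proteinAln, "ProteinAlignment"))
  cds <- vapply(cds, as.character, character(1))
  ids <- names(proteinAln)
  if (length(proteinAln) == 0L) return(codonAlignment(character(0)))
  missing_cds <- setdiff(ids, names(cds))
  if (length(missing_cds))
    stop(sprintf("missing coding sequence for: %s",
                 paste(missing_cds, collapse = ", ")), call. = FALSE)
  pm <- .aln_matrix(proteinAln)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    s <- toupper(cds[[id]])
    if (nchar(s) %% 3L != 0L)
      stop(sprintf("coding sequence '%s' length is not a multiple of 3", id),
           call. = FALSE)
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    aas <- .translate_codons(codons)
    if (length(aas) && aas[length(aas)] == "*") {
      codons <- codons[-length(codons)]
      aas <- aas[-length(aas)]
    }
    prot <- pm[id, ]
    ungapped <- prot[prot != "-"]
    if (length(aas) != length(ungapped))
      stop(sprintf("'%s': cds encodes %d residues but protein has %d",
                   id, length(aas), length(ungapped)), call. = FALSE)
    mism <- which(aas != ungapped)
    if (length(mism))
      stop(sprintf("'%s': translation mismatch at residue %d (cds '%s' -> %s, protein %s)",
                   id, mism[1L], codons[mism[1L]], aas[mism[1L]],
                   ungapped[mism[1L]]), call. = FALSE)
    gapped <- rep("---", length(prot))
    gapped[prot != "-"] <- codons
    out[i] <- paste0(gapped, collapse = "")
  }
  names(out) <- ids
  codonAlignment(out)
}

#' Filter codon columns by coverage
#'
#' A codon column is kept iff the fraction of sequences holding a non-gap,
#' non-N codon there is at least `minCoverage`; the boundary is inclusive,
#' so only columns strictly below the threshold are eliminated.  Column
#' order is preserved.
#'
#' @param aln A [CodonAlignment-class].
#' @param minCoverage Coverage threshold in (0, 1]; default 0.95.
#' @return List with `alignment` (filtered [CodonAlignment-class]) and
#'   `kept` (1-based kept codon-column indices in input coordinates).
#' @export
coverageFilter <- function(aln, minCoverage = 0.95) {
  stopifnot(is(aln, "CodonAlignment"))
  if (minCoverage <= 0 || minCoverage > 1)
    stop("minCoverage must lie in (0, 1]", call. = FALSE)
  if (length(aln) == 0L) return(list(alignment = aln, kept = integer(0)))
  cm <- .codon_matrix(aln)
  present <- !grepl("[-N]", cm)
  dim(present) <- dim(cm)
  cov <- colMeans(present)
  kept <- which(cov >= minCoverage)
  list(alignment = codonAlignment(cm[, kept, drop = FALSE]), kept = kept)
}

#' Extract one codon position as a nucleotide alignment
#'
#' @param aln A [CodonAlignment-class].
#' @param position Codon position: 1, 2 or 3 (3 is the nearly neutral
#'   marker used for topology inference).
#' @return A [Biostrings::DNAStringSet] with one column per codon.
#' @export
codonPositionExtract <- function(aln, position) {
  stopifnot(is(aln, "CodonAlignment"))
  if (!position %in% 1:3)
    stop("position must be 1, 2 or 3", call. = FALSE)
  m <- .aln_matrix(aln)
  if (!ncol(m)) return(Biostrings::DNAStringSet(stats::setNames(character(0), NULL)))
  keep <- seq.int(position, ncol(m), by = 3L)
  seqs <- apply(m[, keep, drop = FALSE], 1L, paste0, collapse = "")
  Biostrings::DNAStringSet(seqs)
}

#' Translate a codon alignment
#'
#' Standard genetic code; `---` becomes `-`, any codon containing `N` or a
#' partial gap becomes `X`, and stop codons are translated to `*` and
#' reported via a warning.
#'
#' @param aln A [CodonAlignment-class].
#' @return A [ProteinAlignment-class].
#' @export
translateCodonAlignment <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  if (length(aln) == 0L) return(proteinAlignment(character(0)))
  cm <- .codon_matrix(aln)
  pm <- matrix(.translate_codons(cm), nrow(cm), ncol(cm),
               dimnames = dimnames(cm))
  stops <- which(pm == "*", arr.ind = TRUE)
  if (nrow(stops))
    warning(sprintf("stop codon(s) at: %s",
                    paste(sprintf("%s codon %d", rownames(cm)[stops[, 1L]],
                                  stops[, 2L]), collapse = "; ")))
  proteinAlignment(pm)
}

#' Slice an alignment to the mature-protein region
#'
#' Keeps all alignment columns at or after the column holding the
#' reference's `firstMatureResidue`-th residue (codon, for codon
#' alignments), dropping the presequence columns.
#'
#' @param aln A [ProteinAlignment-class] or [CodonAlignment-class].
#' @param referenceId Reference sequence id.
#' @param firstMatureResidue 1-based residue index on the ungapped
#'   reference (1 returns the alignment unchanged).
#' @return An alignment of the same class.
#' @export
matureRegionSlice <- function(aln, referenceId, firstMatureResidue) {
  stopifnot(is(aln, "ProteinAlignment") || is(aln, "CodonAlignment"))
  if (!referenceId %in% names(aln))
    stop(sprintf("reference '%s' not found in alignment", referenceId),
         call. = FALSE)
  is_codon <- is(aln, "CodonAlignment")
  m <- if (is_codon) .codon_matrix(aln) else .aln_matrix(aln)
  ref <- m[referenceId, ]
  gap <- if (is_codon) "---" else "-"
  nongap <- which(ref != gap)
  if (firstMatureResidue < 1L || firstMatureResidue > length(nongap))
    stop(sprintf("firstMatureResidue must lie in 1..%d", length(nongap)),
         call. = FALSE)
  from <- nongap[firstMatureResidue]
  out <- m[, seq(from, ncol(m)), drop = FALSE]
  if (is_codon) codonAlignment(out) else proteinAlignment(out)
}

#' Read an alignment from FASTA
#'
#' Ids are taken up to the first whitespace of the FASTA header.
#'
#' @param path FASTA file path.
#' @param type `"codon"` or `"protein"`.
#' @return A [CodonAlignment-class] or [ProteinAlignment-class].
#' @export
readAlignment <- function(path, type = c("codon", "protein")) {
  type <- match.arg(type)
  if (type == "codon") {
    x <- Biostrings::readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    new("CodonAlignment", x)
  } else {
    x <- Biostrings::readAAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    new("ProteinAlignment", x)
  }
}

#' Write an alignment to FASTA (60-column wrapped)
#'
#' @param aln A [CodonAlignment-class], [ProteinAlignment-class] or any
#'   `XStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln, path, width = 60L)
  invisible(path)
}
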