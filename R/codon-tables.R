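# Static codon machinery shared by the simulator and the likelihood engine.
# All indices refer to the 61 sense codons of the standard genetic code,
# ordered lexicographically over A < C < G < T.

.codon_env <- new.env(parent = emptyenv())

.build_codon_tables <- function() {
  nt <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all64 <- sort(all64)
  gc <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc[all64])
  sense <- all64[aa64 != "*"]
  stopifnot(length(sense) == 61L)
  aa61 <- unname(gc[sense])

  # pairwise change classification: 0 = not a single-nucleotide exchange,
  # 1 syn transversion, 2 syn transition, 3 nonsyn transversion, 4 nonsyn transition
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  type <- matrix(0L, 61L, 61L, dimnames = list(sense, sense))
  split3 <- do.call(rbind, strsplit(sense, ""))
  for (i in seq_len(61L)) {
    for (j in seq_len(61L)) {
      if (i == j) next
      diffpos <- which(split3[i, ] != split3[j, ])
      if (length(diffpos) != 1L) next
      ts <- is_transition(split3[i, diffpos], split3[j, diffpos])
      syn <- aa61[i] == aa61[j]
      type[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
    }
  }
  list(
    codons = sense,
    aa = aa61,
    type = type,
    stops = setdiff(all64, sense),
    codon_index = stats::setNames(seq_len(61L), sense)
  )
}

codonTables <- function() {
  if (is.null(.codon_env$tables)) {
    .codon_env$tables <- .build_codon_tables()
  }
  .codon_env$tables
}

#' The 61 sense codons of the standard genetic code
#'
#' Codons are ordered lexicographically over A < C < G < T; this ordering
#' fixes the state indexing used by the rate matrix, the simulator and the
#' pruning likelihood.
#'
#' @return Character vector of length 61.
#' @export
senseCodons <- function() codonTables()$codons

#' Amino acids encoded by the 61 sense codons
#'
#' @return Character vector of length 61, one-letter amino-acid codes,
#'   parallel to [senseCodons()].
#' @export
senseCodonAminoAcids <- function() codonTables()$aa

# translate a vector of codon strings; "---" -> "-", any N/partial gap -> "X",
# stops -> "*"
.translate_codons <- function(codons) {
  tab <- codonTables()
  out <- character(length(codons))
  out[] <- "X"
  out[codons == "---"] <- "-"
  known <- match(codons, tab$codons)
  out[!is.na(known)] <- tab$aa[known[!is.na(known)]]
  out[codons %in% tab$stops] <- "*"
  out
}
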