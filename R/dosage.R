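# Gene-dosage census: beta/alpha copy ratios per species, contingency with
# photosynthetic type, and an exact test implemented by hypergeometric
# enumeration.

.gcd <- function(a, b) {
  while (b != 0L) {
    t <- b; b <- a %% b; a <- t
  }
  a
}

#' Classify a beta/alpha gene-copy ratio
#'
#' Reduces the ratio by its greatest common divisor and renders it as
#' `"beta:alpha"`.  Species with zero alpha copies classify as `"k:0"` and
#' are flagged rather than dropped.
#'
#' @param nBeta,nAlpha Non-negative integer copy numbers, not both zero.
#' @return List with `ratio` (string), `oneToOne` (logical) and
#'   `zeroAlpha` (logical flag).
#' @examples
#' classifyRatio(2, 1)   # "2:1", not 1:1
#' classifyRatio(3, 3)   # "1:1"
#' @export
classifyRatio <- function(nBeta, nAlpha) {
  nBeta <- as.integer(nBeta); nAlpha <- as.integer(nAlpha)
  if (nBeta < 0L || nAlpha < 0L)
    stop("copy numbers must be non-negative", call. = FALSE)
  if (nBeta + nAlpha == 0L)
    stop("at least one of nBeta, nAlpha must be positive", call. = FALSE)
  g <- max(.gcd(nBeta, nAlpha), 1L)
  b <- nBeta %/% g; a <- nAlpha %/% g
  list(ratio = sprintf("%d:%d", b, a),
       oneToOne = b == 1L && a == 1L,
       zeroAlpha = nAlpha == 0L)
}

.table_ratios <- function(table) {
  stopifnot(all(c("species", "photosynthesis_type", "n_alpha", "n_beta")
                %in% names(table)))
  cl <- Map(classifyRatio, table$n_beta, table$n_alpha)
  data.frame(species = table$species,
             photosynthesis_type = table$photosynthesis_type,
             ratio = vapply(cl, `[[`, character(1), "ratio"),
             oneToOne = vapply(cl, `[[`, logical(1), "oneToOne"),
             zeroAlpha = vapply(cl, `[[`, logical(1), "zeroAlpha"),
             stringsAsFactors = FALSE)
}

#' Build the 2x2 dosage contingency table
#'
#' Rows: species with C4-NAD-ME photosynthesis versus all other retained
#' species (C3-C4 intermediates count as "other"); columns: non-1:1 versus
#' 1:1 beta/alpha gene dosage.
#'
#' @param table A gene-family data.frame with columns `species`,
#'   `photosynthesis_type`, `n_alpha`, `n_beta`.
#' @param groupRule Function mapping the table to a logical vector (TRUE =
#'   group 1); default: `photosynthesis_type == "C4-NAD-ME"`.
#' @return List with `table` (2x2 integer matrix), `proportions` (non-1:1
#'   fraction per group).
#' @export
buildContingency <- function(table, groupRule = NULL) {
  r <- .table_ratios(table)
  g1 <- if (is.null(groupRule)) table$photosynthesis_type == "C4-NAD-ME"
        else groupRule(table)
  if (!any(g1) || all(g1))
    stop("both groups must contain at least one species", call. = FALSE)
  non11 <- !r$oneToOne
  m <- matrix(c(sum(g1 & non11), sum(g1 & !non11),
                sum(!g1 & non11), sum(!g1 & !non11)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("C4-NAD-ME", "other"),
                              c("non-1:1", "1:1")))
  list(table = m,
       proportions = c(group1 = mean(non11[g1]), group2 = mean(non11[!g1])))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration with fixed margins: the p-value is the sum of
#' hypergeometric point probabilities of all tables whose probability does
#' not exceed that of the observed table (point-probability rule, with
#' numerical slack 1e-12).  Degenerate tables with a zero row or column
#' margin give p = 1.
#'
#' @param tab A 2x2 matrix of non-negative counts (or a length-4 vector
#'   `a, b, c, d` filled by row).
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(5, 2, 16, 69), 2, byrow = TRUE))
#' @export
fisherExactTwoSided <- function(tab) {
  if (is.list(tab) && !is.null(tab$table)) tab <- tab$table
  tab <- as.vector(t(as.matrix(tab)))
  if (length(tab) != 4L || any(tab < 0))
    stop("tab must be a 2x2 table of non-negative counts", call. = FALSE)
  a <- tab[1L]; b <- tab[2L]; cc <- tab[3L]; d <- tab[4L]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  n <- r1 + r2
  if (n == 0L) stop("table total must be positive", call. = FALSE)
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) return(1)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  av <- lo:hi
  logp <- lchoose(r1, av) + lchoose(r2, c1 - av) - lchoose(n, c1)
  p_all <- exp(logp)
  p_obs <- p_all[av == a]
  min(sum(p_all[p_all <= p_obs + 1e-12]), 1)
}

#' Structured dosage census report
#'
#' Counts species by reduced beta/alpha ratio and by group, and runs the
#' exact contingency test when both groups are represented.
#'
#' @param table A gene-family data.frame (see [buildContingency()]).
#' @return List with `ratioCounts`, `nSpecies`, `proportions`,
#'   `contingency`, `fisherP` (NA when the test is not applicable) and
#'   `zeroAlphaSpecies`.
#' @export
dosageReport <- function(table) {
  if (!nrow(table)) stop("table must be non-empty", call. = FALSE)
  r <- .table_ratios(table)
  rc <- sort(table(r$ratio), decreasing = TRUE)
  cont <- tryCatch(buildContingency(table), error = function(e) NULL)
  p <- if (is.null(cont)) NA_real_ else fisherExactTwoSided(cont$table)
  list(nSpecies = nrow(table),
       ratioCounts = rc,
       proportions = if (is.null(cont)) NULL else cont$proportions,
       contingency = if (is.null(cont)) NULL else cont$table,
       fisherP = p,
       zeroAlphaSpecies = r$species[r$zeroAlpha])
}
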