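# Cohort-level contingency statistics: chi-square (no continuity
# correction by default), two-sided Fisher exact, and Cochran-Mantel-
# Haenszel across sex strata.

#' Contingency tests for diagnosis-by-genotype tables
#'
#' @param counts a 2 x K nonnegative integer matrix (e.g. genotype rows,
#'   diagnosis columns), or a 2 x 2 x S array of per-stratum tables when
#'   `stratum` results are wanted.
#' @param stratum optional 2 x 2 x S array of per-stratum (e.g. per-sex)
#'   tables for the CMH test; ignored if `counts` is already 3-dimensional.
#' @param correct apply continuity correction to chi-square / CMH
#'   (default `FALSE`).
#' @return list with `chi_square` (statistic, p), `fisher` (two-sided p,
#'   2 x 2 tables only) and `cmh` (statistic, p; requires >= 2 strata).
#'   Expected cell counts below 5 trigger a warning.
#' @export
contingency_tests <- function(counts, stratum = NULL, correct = FALSE) {
  if (length(dim(counts)) == 3) { stratum <- counts; counts <- apply(counts, c(1, 2), sum) }
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("empty margin in contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5))
    warning("expected cell count(s) below 5; chi-square approximation is rough")
  chi <- suppressWarnings(chisq.test(counts, correct = correct))
  out <- list(chi_square = list(statistic = unname(chi$statistic),
                                p = unname(chi$p.value)))
  if (all(dim(counts) == c(2, 2)))
    out$fisher <- list(p = fisher.test(counts)$p.value)
  if (!is.null(stratum)) {
    if (length(dim(stratum)) != 3 || dim(stratum)[3] < 2)
      stop("CMH requires a 2 x 2 x S array with >= 2 strata")
    cmh <- mantelhaen.test(stratum, correct = correct)
    out$cmh <- list(statistic = unname(cmh$statistic), p = unname(cmh$p.value))
  }
  out
}
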