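# Two-tailed category statistics used for the territory comparisons.
# These are thin, contract-enforcing wrappers over the standard tests; the
# test suite verifies them against independent enumeration oracles.

#' Two-tailed chi-square test on a category table
#'
#' No continuity correction; errors on tables with a zero margin.
#'
#' @param tab Matrix of non-negative counts.
#' @return Two-tailed p-value.
#' @export
chi_square_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square is undefined for tables with a zero margin")
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test (two-sided by summing all tables with
#' probability at most that of the observed table).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @export
fisher_exact_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  fisher.test(tab)$p.value
}

#' Two-tailed Mann-Whitney test
#'
#' Exact null distribution for small samples without ties (combined
#' n <= 20); normal approximation with tie correction (no continuity
#' correction) otherwise.
#'
#' @param x,y Numeric samples.
#' @export
mann_whitney_two_tailed <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= 20
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)$p.value)
}
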