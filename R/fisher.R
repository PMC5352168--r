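# The study's core statistic: a two-sided Fisher exact test on the 2x2
# contingency table contrasting one focal gene's read counts against the
# summed counts of all remaining genes at the two incubation temperatures.
# Under the null that the focal gene's share of the library is the same at
# both temperatures (odds ratio theta = 1), the focal count at the low
# temperature is hypergeometric given the table margins; the two-sided
# p-value sums the probabilities of all tables with the same margins that
# are no more probable than the observed one (probability-mass convention,
# with a 1 + 1e-7 relative guard against floating-point strictness).

#' Scalar probability-mass two-sided Fisher p (no validation)
#' @noRd
.fisher_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  c1 <- n11 + n21
  n <- r1 + n21 + n22
  # a zero margin admits a single table: the observed one
  if (r1 == 0 || c1 == 0 || c1 == n || r1 == n) {
    return(1)
  }
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  d <- dhyper(lo:hi, r1, n - r1, c1)
  p <- sum(d[d <= d[n11 - lo + 1] * (1 + 1e-7)])
  # extreme tables can underflow the observed density to 0; keep p in (0, 1]
  min(max(p, .Machine$double.xmin), 1)
}

#' Two-sided Fisher exact test for gene-vs-remaining count tables
#'
#' Exact two-sided p-value for the 2x2 table with cells `n11` (focal gene,
#' low temperature), `n12` (focal gene, high temperature), `n21` and `n22`
#' (all remaining genes at the two temperatures). Vectorized over tables.
#' The two-sided value is the probability-mass sum: over all tables sharing
#' the observed margins, the hypergeometric probabilities not exceeding the
#' observed table's probability (times a `1 + 1e-7` relative guard).
#'
#' Degenerate tables whose focal-gene margin (or either column margin) is
#' zero admit a single table and return `p = 1`; such genes are flagged
#' untestable downstream.
#'
#' @param n11,n12,n21,n22 Non-negative integer cell counts (recycled to a
#'   common length).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_two_sided_p(10, 10, 1000, 1000)  # modal table: p = 1
#' fisher_two_sided_p(5, 0, 0, 5)          # 2/choose(10,5) = 2/252
#' @export
fisher_two_sided_p <- function(n11, n12, n21, n22) {
  len <- max(length(n11), length(n12), length(n21), length(n22))
  cells <- list(n11 = rep_len(as.numeric(n11), len),
                n12 = rep_len(as.numeric(n12), len),
                n21 = rep_len(as.numeric(n21), len),
                n22 = rep_len(as.numeric(n22), len))
  bad <- cells$n11 < 0 | cells$n12 < 0 | cells$n21 < 0 | cells$n22 < 0 |
    cells$n11 != floor(cells$n11) | cells$n12 != floor(cells$n12) |
    cells$n21 != floor(cells$n21) | cells$n22 != floor(cells$n22)
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    stop("all cells must be non-negative integers", call. = FALSE)
  }
  vapply(seq_along(cells$n11), function(i) {
    .fisher_p(cells$n11[i], cells$n12[i], cells$n21[i], cells$n22[i])
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_(j >= i) p_(j) * m / j`, capped
#' at 1 and mapped back to input order (delegates to
#' [stats::p.adjust()][stats::p.adjust] with `method = "BH"`).
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) {
    return(numeric(0))
  }
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Direction of temperature bias for a contingency table
#'
#' Compares the focal gene's proportion of each column:
#' `n11 / (n11 + n21)` (low temperature, 26 degrees C) against
#' `n12 / (n12 + n22)` (high, 31 degrees C). Strictly larger at the low
#' temperature gives `"low"`, strictly larger at the high temperature
#' `"high"`, an exact tie `"none"`. Vectorized.
#'
#' @inheritParams fisher_two_sided_p
#' @return Character vector in `c("low", "high", "none")`.
#' @export
classify_direction <- function(n11, n12, n21, n22) {
  # compare n11/(n11+n21) vs n12/(n12+n22) by cross-multiplication so the
  # tie test is exact; double arithmetic avoids integer overflow at
  # library-scale totals
  n11 <- as.numeric(n11); n12 <- as.numeric(n12)
  n21 <- as.numeric(n21); n22 <- as.numeric(n22)
  lhs <- n11 * (n12 + n22)
  rhs <- n12 * (n11 + n21)
  both_zero <- (n11 + n21) == 0 | (n12 + n22) == 0
  out <- dplyr::case_when(
    both_zero ~ "none",
    lhs > rhs ~ "low",
    lhs < rhs ~ "high",
    .default = "none"
  )
  out
}
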