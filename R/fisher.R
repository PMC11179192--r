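#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the count `a` follows a hypergeometric
#' distribution. The two-sided p-value follows the probability-ordering
#' rule: the sum of the probabilities of all tables (with the same margins)
#' whose probability does not exceed that of the observed table, using the
#' conventional `1 + 1e-7` relative tolerance for ties. A table with an
#' all-zero margin carries no information and returns `p = 1`.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = allele
#'   (ref/alt), columns = outcome (spliced/unspliced): `a`, `b` = ref
#'   spliced/unspliced, `c`, `d` = alt spliced/unspliced.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + b # ref row total
  m2 <- c + d # alt row total
  k <- a + c  # spliced column total
  n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) {
    return(1)
  }
  support <- max(0L, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
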