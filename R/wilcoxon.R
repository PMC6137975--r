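#' Exact null distribution of the signed-rank statistic
#'
#' Counts, for ranks `1..n` with no ties, the number of sign assignments
#' yielding each possible value of the positive-rank sum W+. Dynamic
#' programming over ranks (polynomial multiplication); the counts sum to
#' `2^n`.
#'
#' @param n number of nonzero differences.
#' @return numeric vector of length `n(n+1)/2 + 1`; element `i` is the
#'   count of assignments with `W+ = i - 1`.
#' @keywords internal
signrank_counts <- function(n) {
  counts <- 1
  for (r in seq_len(n)) {
    shifted <- c(numeric(r), counts)
    counts <- c(counts, numeric(r)) + shifted
  }
  counts
}

#' One-sample Wilcoxon signed-rank test against a reference value
#'
#' Tests the null hypothesis that the data are symmetrically distributed
#' around `mu`. Zero differences are dropped before ranking; absolute
#' differences are ranked with midranks. The two-sided p-value uses the
#' exact null distribution (by convolution over sign assignments) when
#' `n <= 25` and no ties are present among the absolute differences;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x numeric vector of observations (non-finite values dropped).
#' @param mu reference value under the null.
#' @return list with `statistic` (W+), `p_value`, `n` (nonzero
#'   differences used) and `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, mu = 0) {
  d <- x[is.finite(x)] - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; no evidence against symmetry")
    return(list(statistic = 0, p_value = 1, n = 0L, exact = NA))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    counts <- signrank_counts(n)
    total <- 2^n
    cum <- cumsum(counts)
    p_le <- cum[w + 1] / total
    p_ge <- (total - if (w == 0) 0 else cum[w]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = w, p_value = p, n = n, exact = TRUE))
  }
  mu_w <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(list(statistic = w, p_value = 1, n = n,
                               exact = FALSE))
  z <- (w - mu_w - sign(w - mu_w) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p_value = p, n = n, exact = FALSE)
}
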