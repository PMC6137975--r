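#' Multiple-testing adjustment of window p-values
#'
#' Two estimators gate the ternary methylation scores at level `alpha`:
#'
#' * `"bh"` — Benjamini-Hochberg step-up adjusted p-values: for sorted
#'   p-values `p(1) <= ... <= p(m)`, `q(i) = min_{j >= i} m p(j) / j`,
#'   clipped at 1. Monotone and never below the raw p-value.
#' * `"local"` — a tail-area false-discovery estimate in the style of
#'   the two-group model: two-sided p-values are probit-transformed to
#'   half-normal scores `z = qnorm(1 - p/2)`; the null scale `sigma` is
#'   fitted by truncated maximum likelihood on the scores below their
#'   75th percentile (assumed null-dominated), the null proportion
#'   `eta0` follows from the truncated mass, and
#'   `Fdr(z) = eta0 * S0(z) / S_emp(z)` (clipped to `[0, 1]`,
#'   monotonized in p).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` (default) or `"local"`.
#' @param alpha nominal FDR level; recorded for provenance, not used in
#'   the adjustment itself.
#' @return numeric vector of q-values, same length and order as
#'   `p_values`; `NA` inputs propagate.
#' @export
adjust_fdr <- function(p_values, method = c("bh", "local"), alpha = 0.05) {
  method <- match.arg(method)
  if (length(p_values) == 0L) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p_values))
  p <- p_values[ok]
  q[ok] <- switch(method, bh = fdr_bh(p), local = fdr_local(p))
  q
}

fdr_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

fdr_local <- function(p, trunc_quantile = 0.75) {
  m <- length(p)
  z <- stats::qnorm(1 - pmin(pmax(p, 1e-15), 1 - 1e-15) / 2)
  z0 <- stats::quantile(z, trunc_quantile, names = FALSE)
  zc <- z[z <= z0]
  if (z0 <= 0 || length(zc) < 2L) return(rep(1, m))
  # truncated half-normal likelihood for the null scale
  nll <- function(log_sigma) {
    s <- exp(log_sigma)
    -sum(stats::dnorm(zc, 0, s, log = TRUE) + log(2) -
           log(2 * stats::pnorm(z0 / s) - 1))
  }
  s_hat <- exp(stats::optimize(nll, c(log(0.05), log(10)))$minimum)
  eta0 <- min(1, (length(zc) / m) / (2 * stats::pnorm(z0 / s_hat) - 1))
  s0 <- 2 * stats::pnorm(z / s_hat, lower.tail = FALSE)      # null survival
  s_emp <- (m + 1 - rank(z, ties.method = "min")) / m        # empirical tail
  q <- pmin(1, eta0 * s0 / s_emp)
  # enforce monotonicity: larger p never gets a smaller q
  o <- order(p)
  q[o] <- cummax(q[o])
  q
}
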