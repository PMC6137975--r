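#' Split probes into reference and analysis subsets
#'
#' Draws, independently within each chromosome, a random fraction of the
#' probes (without replacement) to serve as the reference subset from
#' which the base level of methylation is estimated; the remainder forms
#' the analysis subset used for windowed testing. Subset size is
#' `round(fraction * n)` (half away from zero), clamped to `[1, n - 1]`.
#'
#' @param probes probe table with `probe_id` and `chrom`.
#' @param fraction fraction reserved for the reference, in `(0, 1)`;
#'   default 0.2.
#' @param seed integer seed making the draw reproducible.
#' @return list with `reference` and `analysis` probe tables; together
#'   they partition the input.
#' @export
split_probes <- function(probes, fraction = 0.2, seed = 1L) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly in (0, 1)", call. = FALSE)
  counts <- table(probes$chrom)
  small <- names(counts)[counts < 10L]
  if (length(small))
    stop(sprintf("chromosome(s) with fewer than 10 probes: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  with_local_seed(seed, {
    ref_idx <- unlist(lapply(split(seq_len(nrow(probes)), probes$chrom),
                             function(idx) {
      n <- length(idx)
      k <- min(max(floor(fraction * n + 0.5), 1L), n - 1L)
      idx[sample.int(n, k)]
    }), use.names = FALSE)
    list(reference = probes[sort(ref_idx), , drop = FALSE],
         analysis = probes[-sort(ref_idx), , drop = FALSE])
  })
}

#' Reference mean (base level of methylation)
#'
#' Arithmetic mean of the reference subset's per-probe condition-averaged
#' signals; missing values are excluded.
#'
#' @param values numeric vector of per-probe signals.
#' @return the reference mean, a single finite number.
#' @export
estimate_reference_mean <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L)
    stop("cannot estimate a reference mean from all-missing signals",
         call. = FALSE)
  mean(v)
}

#' Two-component Gaussian mixture fit by expectation-maximization
#'
#' Characterizes the bimodal empirical signal distribution with a
#' two-component Gaussian mixture. Initialization places the component
#' means at paired quantiles of the data (10th/90th by default, with
#' four further deterministic restarts); the best log-likelihood wins.
#' Components are returned in ascending-mean order. Convergence when the
#' log-likelihood improves by less than `tol` or after `max_iter`
#' iterations; the log-likelihood is non-decreasing across iterations by
#' construction of EM. A restart whose component variance collapses
#' below `1e-6` is flagged degenerate and discarded; if every restart
#' degenerates the fit is refused with an error.
#'
#' @param x numeric vector of signals; at least 50 finite values.
#' @param tol convergence tolerance on the log-likelihood (default
#'   `1e-8`).
#' @param max_iter maximum EM iterations (default 500).
#' @return object of class `mixture_fit`: `lambda`, `mu`, `sigma` (each
#'   length 2, means ascending), `log_likelihood`, `n_iterations`,
#'   `converged`, `loglik_trace`, and `one_component` (TRUE when the
#'   fitted components are too close to represent genuine bimodality;
#'   separation `(mu2 - mu1) / mean(sigma) < 2`).
#' @export
fit_bimodal_mixture <- function(x, tol = 1e-8, max_iter = 500L) {
  x <- x[is.finite(x)]
  if (length(x) < 50L)
    stop("mixture fit requires at least 50 finite values", call. = FALSE)
  inits <- list(c(0.10, 0.90), c(0.20, 0.80), c(0.05, 0.95),
                c(0.30, 0.70), c(0.25, 0.75))
  best <- NULL
  for (qs in inits) {
    fit <- em_gauss2(x, stats::quantile(x, qs, names = FALSE),
                     tol = tol, max_iter = max_iter)
    if (is.null(fit)) next  # degenerate restart
    if (is.null(best) || fit$log_likelihood > best$log_likelihood)
      best <- fit
  }
  if (is.null(best))
    stop("mixture fit refused: every restart collapsed a component variance",
         call. = FALSE)
  if (best$mu[1] > best$mu[2]) {
    o <- order(best$mu)
    best$mu <- best$mu[o]; best$sigma <- best$sigma[o]
    best$lambda <- best$lambda[o]
  }
  best$one_component <-
    (best$mu[2] - best$mu[1]) / mean(best$sigma) < 2
  class(best) <- "mixture_fit"
  best
}

em_gauss2 <- function(x, mu0, tol, max_iter) {
  n <- length(x)
  lambda <- c(0.5, 0.5)
  mu <- as.numeric(mu0)
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * stats::sd(x) / 10
  sigma <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lg1 <- log(lambda[1]) + stats::dnorm(x, mu[1], sigma[1], log = TRUE)
    lg2 <- log(lambda[2]) + stats::dnorm(x, mu[2], sigma[2], log = TRUE)
    mx <- pmax(lg1, lg2)
    den <- mx + log(exp(lg1 - mx) + exp(lg2 - mx))
    ll <- sum(den)
    trace <- c(trace, ll)
    g1 <- exp(lg1 - den)
    g2 <- 1 - g1
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    lambda <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    v1 <- sum(g1 * (x - mu[1])^2) / n1
    v2 <- sum(g2 * (x - mu[2])^2) / n2
    if (v1 < 1e-6 || v2 < 1e-6) return(NULL)
    sigma <- sqrt(c(v1, v2))
    if (ll - ll_old < tol && it > 1L) {
      return(list(lambda = lambda, mu = mu, sigma = sigma,
                  log_likelihood = ll, n_iterations = it,
                  converged = TRUE, loglik_trace = trace))
    }
    ll_old <- ll
  }
  list(lambda = lambda, mu = mu, sigma = sigma, log_likelihood = ll_old,
       n_iterations = max_iter, converged = FALSE, loglik_trace = trace)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture\n")
  cat(sprintf("  component 1: lambda = %.3f, mu = %.3f, sigma = %.3f\n",
              x$lambda[1], x$mu[1], x$sigma[1]))
  cat(sprintf("  component 2: lambda = %.3f, mu = %.3f, sigma = %.3f\n",
              x$lambda[2], x$mu[2], x$sigma[2]))
  cat(sprintf("  log-likelihood %.3f after %d iteration(s); converged: %s\n",
              x$log_likelihood, x$n_iterations, x$converged))
  if (isTRUE(x$one_component))
    cat("  note: components overlap heavily; effectively one-component\n")
  invisible(x)
}

#' Per-chromosome, per-condition reference models
#'
#' For every chromosome and condition, averages the reference-subset
#' probes' signals across replicates, takes their arithmetic mean as the
#' reference mean (base level of methylation), and fits the
#' two-component mixture as a diagnostic. `ref_stat = "mixture"` uses
#' the mixture mean `lambda1*mu1 + lambda2*mu2` instead (numerically
#' identical in expectation).
#'
#' @param ref_probes reference probe table from [split_probes()].
#' @param signal probe x sample matrix.
#' @param samples sample metadata (`sample_id`, `condition`).
#' @param condition condition label.
#' @param ref_stat `"mean"` (default) or `"mixture"`.
#' @param fit_mixture fit the diagnostic mixture (needs >= 50 probes per
#'   chromosome); default TRUE.
#' @return data frame (chrom, condition, n_subset, mu_ref, lambda1, mu1,
#'   sigma1, lambda2, mu2, sigma2, loglik, converged) with the fits in
#'   attribute `"mixtures"`.
#' @export
reference_models <- function(ref_probes, signal, samples, condition,
                             ref_stat = c("mean", "mixture"),
                             fit_mixture = TRUE) {
  ref_stat <- match.arg(ref_stat)
  vals <- condition_means(signal, samples, condition)
  chroms <- sort(unique(ref_probes$chrom))
  fits <- stats::setNames(vector("list", length(chroms)), chroms)
  rows <- lapply(chroms, function(chrom) {
    ids <- ref_probes$probe_id[ref_probes$chrom == chrom]
    v <- vals[intersect(ids, names(vals))]
    mu_ref <- estimate_reference_mean(v)
    fit <- NULL
    if (fit_mixture && sum(is.finite(v)) >= 50L)
      fit <- fit_bimodal_mixture(v)
    if (ref_stat == "mixture") {
      if (is.null(fit))
        stop("ref_stat='mixture' needs a mixture fit (>= 50 probes)",
             call. = FALSE)
      mu_ref <- sum(fit$lambda * fit$mu)
    }
    fits[[chrom]] <<- fit
    data.frame(
      chrom = chrom, condition = condition, n_subset = length(v),
      mu_ref = mu_ref,
      lambda1 = if (is.null(fit)) NA_real_ else fit$lambda[1],
      mu1 = if (is.null(fit)) NA_real_ else fit$mu[1],
      sigma1 = if (is.null(fit)) NA_real_ else fit$sigma[1],
      lambda2 = if (is.null(fit)) NA_real_ else fit$lambda[2],
      mu2 = if (is.null(fit)) NA_real_ else fit$mu[2],
      sigma2 = if (is.null(fit)) NA_real_ else fit$sigma[2],
      loglik = if (is.null(fit)) NA_real_ else fit$log_likelihood,
      converged = if (is.null(fit)) NA else fit$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mixtures") <- fits
  out
}
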