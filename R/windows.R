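#' Consecutive analysis windows tiling a genome
#'
#' @param chroms character vector of chromosome names.
#' @param lengths numeric vector of chromosome lengths (bp), parallel to
#'   `chroms`.
#' @param window_size window size in bp.
#' @return data frame (window_id, chrom, start, end) of consecutive
#'   0-based half-open windows `[0,w), [w,2w), ...` per chromosome, the
#'   last truncated at the chromosome end. Windows never span
#'   chromosomes; per chromosome the window lengths sum exactly to the
#'   chromosome length.
#' @export
window_grid <- function(chroms, lengths, window_size) {
  stopifnot(length(chroms) == length(lengths), window_size > 0,
            all(lengths > 0))
  rows <- lapply(seq_along(chroms), function(i) {
    n <- ceiling(lengths[i] / window_size)
    start <- (seq_len(n) - 1) * window_size
    end <- pmin(start + window_size, lengths[i])
    data.frame(chrom = rep(chroms[i], n), start = start, end = end,
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, rows)
  w$window_id <- sprintf("%s:%.0f-%.0f", w$chrom, w$start, w$end)
  w[, c("window_id", "chrom", "start", "end")]
}

#' Assign probes to windows by midpoint containment
#'
#' @param probes probe table with `chrom`, `start`, `end`.
#' @param windows window grid from [window_grid()].
#' @return character vector of window ids, parallel to `probes` rows;
#'   errors if any probe midpoint falls beyond the declared chromosome
#'   extent.
#' @export
assign_windows <- function(probes, windows) {
  out <- rep(NA_character_, nrow(probes))
  mid <- (probes$start + probes$end) / 2
  for (chrom in unique(probes$chrom)) {
    w <- windows[windows$chrom == chrom, ]
    if (nrow(w) == 0L)
      stop(sprintf("chromosome %s absent from window grid", chrom),
           call. = FALSE)
    p <- which(probes$chrom == chrom)
    idx <- findInterval(mid[p], w$start)  # starts are sorted per chromosome
    beyond <- mid[p] >= w$end[nrow(w)] | idx < 1L
    if (any(beyond))
      stop(sprintf("%d probe(s) on %s lie beyond the chromosome length",
                   sum(beyond), chrom), call. = FALSE)
    out[p] <- w$window_id[idx]
  }
  out
}

#' Build analysis windows from a probe set
#'
#' Tiles each chromosome with consecutive windows and characterizes each
#' window by its probe composition (midpoint containment). Typically
#' applied to the 80% analysis subset left after reference-mean
#' estimation.
#'
#' @param probes probe table (`probe_id`, `chrom`, `start`, `end`).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window_size window size in bp (default 50000).
#' @return data frame (window_id, chrom, start, end, n_probes) with a
#'   list-column `probe_ids` naming the member probes.
#' @export
build_windows <- function(probes, chrom_lengths, window_size = 50000) {
  wins <- window_grid(names(chrom_lengths), as.numeric(chrom_lengths),
                      window_size)
  wid <- assign_windows(probes, wins)
  by_win <- split(probes$probe_id, factor(wid, levels = wins$window_id))
  wins$n_probes <- lengths(by_win)[wins$window_id]
  wins$probe_ids <- I(unname(by_win[wins$window_id]))
  wins
}

#' Per-probe condition means
#'
#' Averages each probe's signal across the replicate samples of one
#' condition, ignoring missing values. The method tests one pooled
#' signal per probe per condition.
#'
#' @param signal probe x sample numeric matrix (rownames = probe ids).
#' @param samples sample metadata (`sample_id`, `condition`).
#' @param condition condition label to average over.
#' @return named numeric vector of per-probe means (NaN when all
#'   replicates are missing).
#' @export
condition_means <- function(signal, samples, condition) {
  cols <- samples$sample_id[samples$condition == condition]
  missing_cols <- setdiff(cols, colnames(signal))
  if (length(missing_cols))
    stop(sprintf("sample(s) %s not present in signal matrix",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  rowMeans(signal[, cols, drop = FALSE], na.rm = TRUE)
}

#' Test windows against a reference mean
#'
#' Runs the one-sample Wilcoxon signed-rank test of every window's probe
#' signals against the per-chromosome reference mean (null: signals
#' symmetric around the reference mean), then adjusts the p-values for
#' multiple testing across all testable windows.
#'
#' @param windows window table from [build_windows()].
#' @param probe_values named numeric vector of per-probe (condition
#'   mean) signals for the analysis subset.
#' @param mu_ref named numeric vector of reference means, one per
#'   chromosome.
#' @param min_probes windows with fewer finite values are marked
#'   untestable (`testable = FALSE`, p/q/score `NA`).
#' @param fdr_method,alpha passed to [adjust_fdr()].
#' @return data frame (window_id, chrom, start, end, n_probes,
#'   mean_signal, p_value, q_value, testable).
#' @export
test_windows <- function(windows, probe_values, mu_ref,
                         min_probes = 3L, fdr_method = "bh",
                         alpha = 0.05) {
  missing_ref <- setdiff(unique(windows$chrom), names(mu_ref))
  if (length(missing_ref))
    stop(sprintf("no reference mean for chromosome(s): %s",
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  n <- nrow(windows)
  mean_signal <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  n_used <- integer(n)
  for (i in seq_len(n)) {
    x <- probe_values[intersect(windows$probe_ids[[i]],
                                names(probe_values))]
    x <- x[is.finite(x)]
    n_used[i] <- length(x)
    if (length(x) >= min_probes) {
      mean_signal[i] <- mean(x)
      p[i] <- suppressWarnings(
        wilcoxon_signed_rank(x, mu_ref[[windows$chrom[i]]])$p_value)
    }
  }
  testable <- !is.na(p)
  q <- rep(NA_real_, n)
  q[testable] <- adjust_fdr(p[testable], method = fdr_method, alpha = alpha)
  data.frame(window_id = windows$window_id, chrom = windows$chrom,
             start = windows$start, end = windows$end,
             n_probes = n_used, mean_signal = mean_signal,
             p_value = p, q_value = q, testable = testable,
             stringsAsFactors = FALSE)
}

#' Ternary methylation scores
#'
#' Assigns each testable window a decision score: `0` when the adjusted
#' value exceeds `alpha` (not significantly different from the reference
#' mean), `-1` when significantly below it, `+1` when significantly
#' above it. A significant window whose mean equals the reference mean
#' exactly scores 0 (tie rule). Untestable windows keep `NA`.
#'
#' @param results data frame from [test_windows()].
#' @param mu_ref named numeric vector of per-chromosome reference means.
#' @param alpha FDR level gating nonzero scores.
#' @return `results` with an integer `score` column.
#' @export
score_windows <- function(results, mu_ref, alpha = 0.05) {
  score <- rep(NA_integer_, nrow(results))
  t <- results$testable
  ref <- unname(unlist(mu_ref)[results$chrom])
  score[t] <- ifelse(results$q_value[t] > alpha, 0L,
                     sign(results$mean_signal[t] - ref[t]))
  results$score <- as.integer(score)
  results
}
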