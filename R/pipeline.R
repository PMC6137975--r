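#' Run the full windowed DMR-calling pipeline
#'
#' Chains the method end to end for one experiment: (1) split the probes
#' per chromosome into a random reference fraction and an analysis
#' remainder; (2) per condition, average each probe across replicates
#' and estimate the per-chromosome reference mean (base level of
#' methylation) from the reference subset; (3) tile the genome with
#' consecutive windows, characterize each by its analysis-subset probe
#' composition, and test every window's signals against the reference
#' mean with the one-sample Wilcoxon signed-rank test; (4) adjust for
#' multiple testing at `config$alpha` and assign ternary scores; (5)
#' call DMRs as windows whose scores differ between conditions.
#'
#' @param probes probe table (`probe_id`, `chrom`, `start`, `end`).
#' @param signals named list of probe x sample matrices keyed by
#'   condition label, or a single matrix holding both conditions'
#'   samples.
#' @param samples sample metadata (`sample_id`, `condition`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param config a [run_config()].
#' @param fit_mixture fit the diagnostic mixture models during reference
#'   estimation (default FALSE; see [reference_models()]).
#' @return list of class `dmr_run`: `split`, `reference` (per-condition
#'   data frames), `mu_ref` (per-condition named vectors), `windows`
#'   (per-condition scored tables), `dmrs`, `n_tested` (windows testable
#'   in both conditions), `config`.
#' @export
run_dmr_pipeline <- function(probes, signals, samples, chrom_lengths,
                             config = run_config(),
                             fit_mixture = FALSE) {
  conds <- config$conditions
  if (is.matrix(signals)) signals <- list(all = signals)
  get_matrix <- function(cond) {
    for (m in signals)
      if (all(samples$sample_id[samples$condition == cond]
              %in% colnames(m))) return(m)
    stop(sprintf("no signal matrix holds all samples of condition '%s'",
                 cond), call. = FALSE)
  }
  sp <- split_probes(probes, config$ref_fraction, config$seed)
  reference <- list(); mu_ref <- list(); scored <- list()
  wins <- build_windows(sp$analysis, chrom_lengths, config$window_size)
  for (cond in conds) {
    m <- get_matrix(cond)
    ref <- reference_models(sp$reference, m, samples, cond,
                            fit_mixture = fit_mixture)
    reference[[cond]] <- ref
    mu <- stats::setNames(ref$mu_ref, ref$chrom)
    mu_ref[[cond]] <- mu
    vals <- condition_means(m, samples, cond)
    vals <- vals[sp$analysis$probe_id]
    res <- test_windows(wins, vals, mu,
                        min_probes = config$min_probes_per_window,
                        fdr_method = config$fdr_method,
                        alpha = config$alpha)
    scored[[cond]] <- score_windows(res, mu, config$alpha)
  }
  names(scored) <- c("favorable", "unfavorable")
  dmrs <- call_dmrs(scored$favorable, scored$unfavorable)
  n_tested <- sum(scored$favorable$testable & scored$unfavorable$testable)
  structure(list(split = sp, reference = reference, mu_ref = mu_ref,
                 windows = scored, dmrs = dmrs, n_tested = n_tested,
                 config = config),
            class = "dmr_run")
}

#' @export
print.dmr_run <- function(x, ...) {
  s <- summarize_dmrs(x$dmrs, max(x$n_tested, 1L))
  cat("Windowed DMR analysis\n")
  cat(sprintf("  windows tested in both conditions: %d\n", x$n_tested))
  cat(sprintf("  DMRs: %d (%.1f%%), %d hyper / %d hypo, %d mild / %d strong\n",
              s$n_dmrs, s$pct_dmrs, s$n_hyper, s$n_hypo,
              s$n_mild, s$n_strong))
  invisible(x)
}
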