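# All tabular artifacts are TSV with a header row, UTF-8, 0-based
# half-open coordinates; BED output is native BED6.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# significant-digit formatting so write/read round-trips to 12 digits
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

#' Read a probe annotation table
#'
#' Expects a TSV with header columns `probe_id`, `chrom`, `start`,
#' `end`, `category`, `gene_id` (empty/NA gene_id for background
#' probes). Validates the closed category vocabulary, non-negative
#' half-open coordinates and probe_id uniqueness, naming offending lines.
#'
#' @param path TSV path.
#' @return validated probe data frame.
#' @export
read_probes <- function(path) {
  d <- read_tsv(path)
  required <- c("probe_id", "chrom", "start", "end", "category", "gene_id")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(sprintf("probe file lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad_cat <- which(!(d$category %in% PROBE_CATEGORIES))
  if (length(bad_cat))
    stop(sprintf("unknown probe category '%s' at line %d",
                 d$category[bad_cat[1]], bad_cat[1] + 1L), call. = FALSE)
  if (!is.numeric(d$start) || !is.numeric(d$end) ||
      any(is.na(d$start)) || any(is.na(d$end)))
    stop("malformed probe coordinates: start/end must be numeric",
         call. = FALSE)
  bad_coord <- which(d$start < 0 | d$start >= d$end)
  if (length(bad_coord))
    stop(sprintf("invalid interval at line %d: start=%s end=%s",
                 bad_coord[1] + 1L, d$start[bad_coord[1]],
                 d$end[bad_coord[1]]), call. = FALSE)
  dup <- which(duplicated(d$probe_id))
  if (length(dup))
    stop(sprintf("duplicate probe_id '%s' at line %d",
                 d$probe_id[dup[1]], dup[1] + 1L), call. = FALSE)
  d
}

#' Read a signal matrix with its sample sheet
#'
#' The signal TSV carries `probe_id` plus one numeric column per sample;
#' the sample sheet declares `sample_id`, `condition`, `replicate`.
#' Every signal column must be declared in the sample sheet. Missing
#' values are permitted and counted.
#'
#' @param path signal TSV path.
#' @param samples_path sample sheet TSV path.
#' @param probes optional probe table; when given, every probe_id in the
#'   signal file must appear in it.
#' @return list of class `signal_matrix`: `values` (probe x sample
#'   matrix), `samples` (metadata), `n_missing`.
#' @export
read_signals <- function(path, samples_path, probes = NULL) {
  d <- read_tsv(path, check.names = FALSE)
  if (names(d)[1] != "probe_id")
    stop("first column of a signal file must be probe_id", call. = FALSE)
  samples <- read_tsv(samples_path)
  required <- c("sample_id", "condition", "replicate")
  if (length(setdiff(required, names(samples))))
    stop("sample sheet needs sample_id, condition, replicate columns",
         call. = FALSE)
  undeclared <- setdiff(names(d)[-1], samples$sample_id)
  if (length(undeclared))
    stop(sprintf("signal column(s) not declared in the sample sheet: %s",
                 paste(undeclared, collapse = ", ")), call. = FALSE)
  if (!is.null(probes)) {
    unknown <- setdiff(d$probe_id, probes$probe_id)
    if (length(unknown))
      stop(sprintf("%d probe id(s) absent from the probe table (e.g. %s)",
                   length(unknown), unknown[1]), call. = FALSE)
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric signal cell encountered", call. = FALSE)
  rownames(m) <- d$probe_id
  samples <- samples[samples$sample_id %in% colnames(m), , drop = FALSE]
  structure(list(values = m, samples = samples,
                 n_missing = sum(is.na(m))),
            class = "signal_matrix")
}

#' Write scored window results
#'
#' One row per window with, per condition, the probe count, mean signal,
#' raw and adjusted p, ternary score and `-log10(p)` (the Manhattan-plot
#' export). Numbers are written with 12 significant digits so a
#' write-then-read round trip preserves them.
#'
#' @param scored named list of scored window tables (one per condition,
#'   from [score_windows()]), all on the same window grid.
#' @param path output TSV path.
#' @return the written data frame, invisibly.
#' @export
write_windows <- function(scored, path) {
  stopifnot(length(scored) >= 1L)
  base <- scored[[1]][, c("window_id", "chrom", "start", "end")]
  for (cond in names(scored)) {
    s <- scored[[cond]]
    stopifnot(identical(s$window_id, base$window_id))
    base[[paste0("n_probes_", cond)]] <- s$n_probes
    base[[paste0("mean_", cond)]] <- fmt_num(s$mean_signal)
    base[[paste0("p_", cond)]] <- fmt_num(s$p_value)
    base[[paste0("q_", cond)]] <- fmt_num(s$q_value)
    base[[paste0("score_", cond)]] <- s$score
    base[[paste0("neglog10p_", cond)]] <- fmt_num(-log10(s$p_value))
  }
  write_tsv(base, path)
  invisible(base)
}

#' Read a scored window table written by [write_windows()]
#'
#' @param path TSV path.
#' @return data frame with numeric columns restored.
#' @export
read_windows <- function(path) {
  d <- read_tsv(path)
  for (col in grep("^(mean|p|q|neglog10p)_", names(d), value = TRUE))
    d[[col]] <- as.numeric(d[[col]])
  d
}

#' Write DMR calls as TSV and BED6
#'
#' The BED name is `direction_intensity` (e.g. `hyper_mild`) and the BED
#' score encodes direction: 1000 hyper, 0 hypo. An empty DMR set yields
#' a valid BED containing only a header comment. The TSV keeps all
#' fields (gene lists comma-joined).
#'
#' @param dmrs DMR table (optionally annotated).
#' @param tsv_path,bed_path output paths (either may be NULL to skip).
#' @return invisibly, the DMR table.
#' @export
write_dmrs <- function(dmrs, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    d <- dmrs
    if (!is.null(d$gene_ids))
      d$gene_ids <- vapply(d$gene_ids, paste, character(1), collapse = ",")
    write_tsv(d, tsv_path)
  }
  if (!is.null(bed_path)) {
    con <- file(bed_path, "w")
    writeLines("# BED6: chrom start end direction_intensity score strand",
               con)
    if (nrow(dmrs) > 0) {
      bed <- sprintf("%s\t%.0f\t%.0f\t%s_%s\t%d\t.",
                     dmrs$chrom, dmrs$start, dmrs$end,
                     dmrs$direction, dmrs$intensity,
                     ifelse(dmrs$direction == "hyper", 1000L, 0L))
      writeLines(bed, con)
    }
    close(con)
  }
  invisible(dmrs)
}

#' Write simulation artifacts to a directory
#'
#' Emits `probes.tsv`, `genes.bed` (BED6), `signals_<condition>.tsv`,
#' `samples.tsv` and `truth.tsv`.
#'
#' @param design output of [simulate_probe_design()].
#' @param sim output of [simulate_signals()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(design, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "probes.tsv")
  write_tsv(design$probes, p); paths <- c(paths, p)
  p <- file.path(dir, "genes.bed")
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t0\t%s",
                     design$genes$chrom, design$genes$start,
                     design$genes$end, design$genes$gene_id,
                     design$genes$strand), p)
  paths <- c(paths, p)
  for (cond in names(sim$signals)) {
    m <- sim$signals[[cond]]
    d <- data.frame(probe_id = rownames(m), stringsAsFactors = FALSE)
    for (cn in colnames(m)) d[[cn]] <- fmt_num(m[, cn])
    p <- file.path(dir, sprintf("signals_%s.tsv", cond))
    write_tsv(d, p); paths <- c(paths, p)
  }
  p <- file.path(dir, "samples.tsv")
  write_tsv(sim$samples, p); paths <- c(paths, p)
  p <- file.path(dir, "truth.tsv")
  write_tsv(sim$truth, p); paths <- c(paths, p)
  invisible(paths)
}

#' Read and write run configurations (YAML)
#'
#' Every analysis run writes a resolved copy of its configuration next
#' to its outputs for provenance.
#'
#' @param path YAML path.
#' @return [run_config()] for `read_run_config`; invisible path for
#'   `write_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("window_size", "ref_fraction", "alpha", "fdr_method",
             "min_probes_per_window", "conditions", "seed")
  cfg <- do.call(run_config, y[intersect(names(y), known)])
  attr(cfg, "extra") <- y[setdiff(names(y), known)]
  cfg
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
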