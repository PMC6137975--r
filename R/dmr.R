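#' Call differentially methylated regions from ternary scores
#'
#' A DMR is a window whose decision scores differ between the favorable
#' and unfavorable condition (score pairs 0/+1, 0/-1 or +1/-1). The
#' change is read along the favorable-to-unfavorable axis: `hyper` when
#' the unfavorable score exceeds the favorable one (methylation gained
#' under unfavorable growth), `hypo` otherwise. Intensity is `strong`
#' for a full -1 to +1 (or +1 to -1) swing, `mild` for a one-step
#' change. Windows untestable in either condition are excluded.
#'
#' @param scored_favorable,scored_unfavorable scored window tables from
#'   [score_windows()], covering the same windows.
#' @return data frame (window_id, chrom, start, end, score_favorable,
#'   score_unfavorable, direction, intensity).
#' @export
call_dmrs <- function(scored_favorable, scored_unfavorable) {
  a <- scored_favorable; b <- scored_unfavorable
  only_a <- setdiff(a$window_id, b$window_id)
  only_b <- setdiff(b$window_id, a$window_id)
  if (length(only_a) || length(only_b))
    stop(sprintf("window sets differ: %s",
                 paste(c(only_a, only_b), collapse = ", ")), call. = FALSE)
  b <- b[match(a$window_id, b$window_id), ]
  keep <- a$testable & b$testable
  a <- a[keep, ]; b <- b[keep, ]
  is_dmr <- a$score != b$score
  d <- a[is_dmr, c("window_id", "chrom", "start", "end")]
  d$score_favorable <- a$score[is_dmr]
  d$score_unfavorable <- b$score[is_dmr]
  d$direction <- ifelse(d$score_unfavorable > d$score_favorable,
                        "hyper", "hypo")
  d$intensity <- ifelse(abs(d$score_unfavorable - d$score_favorable) == 2L,
                        "strong", "mild")
  rownames(d) <- NULL
  d
}

#' Annotate DMRs with probe categories and overlapped genes
#'
#' Per DMR, counts the member probes of each design category and lists
#' the distinct genes whose intervals overlap the whole window (any
#' overlap, 0-based half-open arithmetic). A gene spanning a window
#' boundary is listed in both windows.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param probes probe table with `chrom`, `start`, `end`, `category`.
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end`.
#' @return `dmrs` with one count column per category and a list-column
#'   `gene_ids`.
#' @export
annotate_dmrs <- function(dmrs, probes, genes) {
  mid <- (probes$start + probes$end) / 2
  cat_cols <- gsub("[+]", "_", paste0("n_", PROBE_CATEGORIES))
  for (col in cat_cols) dmrs[[col]] <- 0L
  gene_ids <- vector("list", nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    inwin <- probes$chrom == dmrs$chrom[i] &
      mid >= dmrs$start[i] & mid < dmrs$end[i]
    tab <- table(factor(probes$category[inwin], levels = PROBE_CATEGORIES))
    for (j in seq_along(PROBE_CATEGORIES))
      dmrs[[cat_cols[j]]][i] <- as.integer(tab[j])
    ov <- genes$chrom == dmrs$chrom[i] &
      genes$start < dmrs$end[i] & genes$end > dmrs$start[i]
    gene_ids[[i]] <- sort(unique(genes$gene_id[ov]))
  }
  dmrs$gene_ids <- I(gene_ids)
  dmrs
}

# Display convention for proportions: truncation (floor) at one decimal,
# matching printed ratios such as 255/871 -> 29.2.
floor_pct <- function(count, total) {
  if (total < 1) stop("denominator must be >= 1", call. = FALSE)
  floor(1000 * count / total + 1e-9) / 10
}

#' Summarize a DMR set
#'
#' DMR count, percentage of tested windows (display convention:
#' truncated, not rounded, at one decimal), hyper/hypo and mild/strong
#' splits, and the per-category probe totals when the DMRs are
#' annotated.
#'
#' @param dmrs DMR table.
#' @param n_windows_tested denominator: windows tested in both
#'   conditions (or an explicit published denominator when reproducing
#'   printed ratios).
#' @return list with `n_dmrs`, `pct_dmrs`, `n_hyper`, `n_hypo`,
#'   `pct_hyper`, `n_mild`, `n_strong`, and `category_counts` (NULL if
#'   unannotated).
#' @export
summarize_dmrs <- function(dmrs, n_windows_tested) {
  n <- nrow(dmrs)
  n_hyper <- sum(dmrs$direction == "hyper")
  cat_cols <- grep("^n_", names(dmrs), value = TRUE)
  list(
    n_dmrs = n,
    n_windows_tested = n_windows_tested,
    pct_dmrs = floor_pct(n, n_windows_tested),
    n_hyper = n_hyper,
    n_hypo = n - n_hyper,
    pct_hyper = if (n > 0) floor_pct(n_hyper, n) else 0,
    n_mild = sum(dmrs$intensity == "mild"),
    n_strong = sum(dmrs$intensity == "strong"),
    category_counts = if (length(cat_cols))
      vapply(dmrs[cat_cols], sum, numeric(1)) else NULL
  )
}

#' Chi-squared test of DMR distribution across probe categories
#'
#' Pearson chi-squared test of independence on the category-by-direction
#' (hyper/hypo) contingency table of annotated DMR probe counts.
#'
#' @param dmrs annotated DMR table ([annotate_dmrs()]), or a numeric
#'   contingency matrix (rows = categories, columns = directions).
#' @return list with `statistic`, `df`, `p_value`, the `table` tested,
#'   `expected` counts, and `low_expected` (TRUE if any expected count
#'   is below 5).
#' @export
chi_squared_categories <- function(dmrs) {
  if (is.matrix(dmrs)) {
    tab <- dmrs
  } else {
    cat_cols <- grep("^n_", names(dmrs), value = TRUE)
    if (!length(cat_cols))
      stop("DMRs must be annotated first (see annotate_dmrs)", call. = FALSE)
    tab <- rbind(
      hyper = vapply(dmrs[dmrs$direction == "hyper", cat_cols],
                     sum, numeric(1)),
      hypo = vapply(dmrs[dmrs$direction == "hypo", cat_cols],
                    sum, numeric(1)))
    tab <- t(tab)  # categories x direction
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table needs at least two rows and two columns",
         call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate contingency table: zero margin", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab, expected = expected,
       low_expected = any(expected < 5))
}
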