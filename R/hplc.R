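#' Global DNA methylation percentage from nucleoside amounts
#'
#' `%mC = (mC / (C + mC)) * 100`, where C is the 2'-deoxycytidine amount
#' and mC the 5-methyl-2'-deoxycytidine amount of an HPLC run.
#' Vectorized.
#'
#' @param C_amount,mC_amount non-negative nucleoside amounts (any common
#'   unit).
#' @return percentage in `[0, 100]`.
#' @export
percent_mC <- function(C_amount, mC_amount) {
  if (any(C_amount < 0 | mC_amount < 0))
    stop("nucleoside amounts must be non-negative", call. = FALSE)
  tot <- C_amount + mC_amount
  if (any(tot <= 0))
    stop("%mC undefined: C + mC must be positive", call. = FALSE)
  100 * mC_amount / tot
}

#' Aggregate technical replicates to individual and genotype means
#'
#' Computes %mC per measurement, averages the technical replicates
#' (hydrolysis x run, unweighted) within each individual, then
#' summarizes each genotype x condition cell by the mean and standard
#' error over its individuals (n = individual count; SE is `NA` for a
#' single individual).
#'
#' @param records data frame with `genotype`, `condition`, `individual`,
#'   `C_amount`, `mC_amount` (one row per HPLC measurement).
#' @return list with `individuals` (genotype, condition, individual,
#'   n_measurements, pct_mC) and `summary` (genotype, condition, n,
#'   mean_pct_mC, se).
#' @export
aggregate_replicates <- function(records) {
  records$pct <- percent_mC(records$C_amount, records$mC_amount)
  key <- interaction(records$genotype, records$condition,
                     records$individual, drop = TRUE)
  ind <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(genotype = d$genotype[1], condition = d$condition[1],
               individual = d$individual[1],
               n_measurements = nrow(d), pct_mC = mean(d$pct),
               stringsAsFactors = FALSE)
  }))
  rownames(ind) <- NULL
  cell <- interaction(ind$genotype, ind$condition, drop = TRUE)
  summ <- do.call(rbind, lapply(split(ind, cell), function(d) {
    data.frame(genotype = d$genotype[1], condition = d$condition[1],
               n = nrow(d), mean_pct_mC = mean(d$pct_mC),
               se = if (nrow(d) > 1)
                 stats::sd(d$pct_mC) / sqrt(nrow(d)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(individuals = ind, summary = summ)
}

#' Genotype x environment two-way ANOVA on per-individual %mC
#'
#' Two-way ANOVA with interaction (type-II sums of squares, robust to
#' unbalanced field designs) of per-individual %mC on genotype and
#' treatment, Tukey HSD contrasts among genotypes within each condition,
#' and a Shapiro-Wilk normality check of the full-model residuals.
#'
#' @param individuals per-individual table from [aggregate_replicates()]
#'   (`genotype`, `condition`, `pct_mC`).
#' @return list of class `gxe_result`: `anova` (data frame with df, SS,
#'   F and p for genotype, treatment and interaction), `tukey` (named
#'   list per condition: TukeyHSD table plus compact letter groups),
#'   `shapiro_p`, `zero_variance` flag.
#' @export
anova_gxe <- function(individuals) {
  d <- data.frame(y = individuals$pct_mC,
                  G = factor(individuals$genotype),
                  T = factor(individuals$condition))
  if (nlevels(d$G) < 2L || nlevels(d$T) < 2L)
    stop("need at least two genotypes and two conditions", call. = FALSE)
  cell_n <- table(d$G, d$T)
  if (any(cell_n == 0))
    stop(sprintf("empty genotype x condition cell(s): %s",
                 paste(which(cell_n == 0, arr.ind = TRUE)[, 1],
                       collapse = ", ")), call. = FALSE)
  if (any(cell_n < 2L))
    stop("need at least two individuals per genotype x condition cell",
         call. = FALSE)
  zero_var <- stats::var(d$y) < 1e-12

  # type-II: each main effect adjusted for the other, interaction last
  rss <- function(f) sum(stats::resid(stats::lm(f, data = d))^2)
  full <- stats::lm(y ~ G * T, data = d)
  rss_full <- sum(stats::resid(full)^2)
  df_err <- stats::df.residual(full)
  ss <- c(G = rss(y ~ T) - rss(y ~ G + T),
          T = rss(y ~ G) - rss(y ~ G + T),
          `G:T` = rss(y ~ G + T) - rss_full)
  df <- c(G = nlevels(d$G) - 1L, T = nlevels(d$T) - 1L,
          `G:T` = (nlevels(d$G) - 1L) * (nlevels(d$T) - 1L))
  ms_err <- rss_full / df_err
  f_stat <- if (zero_var || ms_err < 1e-12) rep(NA_real_, 3) else
    (ss / df) / ms_err
  p <- stats::pf(f_stat, df, df_err, lower.tail = FALSE)
  an <- data.frame(term = names(ss), df = as.integer(df), sum_sq = ss,
                   f_value = f_stat, p_value = p,
                   stringsAsFactors = FALSE)
  rownames(an) <- NULL

  tukey <- lapply(split(d, d$T), function(dd) {
    dd$G <- droplevels(dd$G)
    if (nlevels(dd$G) < 2L || stats::var(dd$y) < 1e-12)
      return(list(contrasts = NULL, groups = NULL))
    fit <- stats::aov(y ~ G, data = dd)
    hsd <- stats::TukeyHSD(fit)$G
    list(contrasts = hsd, groups = letter_groups(hsd, levels(dd$G)))
  })

  shapiro_p <- if (zero_var) NA_real_ else
    stats::shapiro.test(stats::resid(full))$p.value
  structure(list(anova = an, tukey = tukey, shapiro_p = shapiro_p,
                 zero_variance = zero_var), class = "gxe_result")
}

# Compact letter display from a TukeyHSD contrast table: groups sharing a
# letter are not significantly different. Insert-and-absorb algorithm.
letter_groups <- function(hsd, levels, alpha = 0.05) {
  sig <- hsd[, "p adj"] < alpha
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  k <- length(levels)
  differ <- matrix(FALSE, k, k, dimnames = list(levels, levels))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    differ[a, b] <- differ[b, a] <- sig[i]
  }
  groups <- list()
  for (lv in levels) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(differ[lv, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], lv); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- lv
  }
  out <- stats::setNames(rep("", k), levels)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  out
}

#' @export
print.gxe_result <- function(x, ...) {
  cat("Two-way genotype x treatment ANOVA (type II)\n")
  print(x$anova, row.names = FALSE)
  cat(sprintf("Shapiro-Wilk residual normality p = %.4g\n", x$shapiro_p))
  invisible(x)
}

#' Correlation between global methylation and an ecophysiological trait
#'
#' Shapiro-Wilk normality checks on both variables followed by Pearson's
#' r and Spearman's rho with two-sided p-values. Pearson is reported as
#' the headline coefficient only when both normality checks pass
#' (p > 0.05); Spearman is always reported.
#'
#' @param x,y paired numeric vectors, at least 3 finite pairs, each with
#'   positive variance.
#' @return list: `n`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `shapiro_p_x`, `shapiro_p_y`, `pearson_valid`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 paired finite values", call. = FALSE)
  if (stats::var(x) < 1e-12 || stats::var(y) < 1e-12)
    stop("zero variance in one of the variables", call. = FALSE)
  sw_x <- stats::shapiro.test(x)$p.value
  sw_y <- stats::shapiro.test(y)$p.value
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(n = length(x),
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       shapiro_p_x = sw_x, shapiro_p_y = sw_y,
       pearson_valid = sw_x > 0.05 && sw_y > 0.05)
}
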