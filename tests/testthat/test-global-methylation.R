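test_that("%mC follows the printed formula and its bounds", {
  expect_equal(percent_mC(1, 0), 0)
  expect_equal(percent_mC(1, 1), 50)
  expect_equal(percent_mC(65, 35), 35)
  expect_error(percent_mC(0, 0), "undefined")
  expect_error(percent_mC(-1, 2), "non-negative")
  # bounds and monotonicity in mC at fixed C
  mc <- seq(0, 10, by = 0.5)
  v <- percent_mC(rep(5, length(mc)), mc)
  expect_true(all(v >= 0 & v <= 100))
  expect_true(all(diff(v) > 0))
})

test_that("replicate aggregation averages technical then biological", {
  rec <- data.frame(
    genotype = "G1", condition = "fav",
    individual = rep(c("i1", "i2"), each = 4),
    hydrolysis = rep(1:2, 4), run = rep(1:2, each = 2),
    C_amount = 70, mC_amount = rep(c(30, 34), each = 4) / 70 * 70)
  rec$mC_amount <- rep(c(30, 34), each = 4)
  rec$C_amount <- 100 - rec$mC_amount
  agg <- aggregate_replicates(rec)
  expect_equal(agg$individuals$pct_mC, c(30, 34))
  expect_equal(agg$summary$mean_pct_mC, 32)
  expect_equal(agg$summary$se, 2)
  # single individual: SE is missing; identical technicals collapse
  one <- rec[rec$individual == "i1", ]
  agg1 <- aggregate_replicates(one)
  expect_equal(agg1$individuals$pct_mC, 30)
  expect_true(is.na(agg1$summary$se))
  # unbalanced technical replicates: unweighted per-individual means
  unb <- rbind(rec, rec[8, ])
  expect_equal(aggregate_replicates(unb)$individuals$pct_mC[2], 34)
})

test_that("pure additive effects give a null interaction", {
  g_eff <- c(G1 = 0, G2 = 5)
  t_eff <- c(fav = 0, unf = 2)
  d <- expand.grid(genotype = names(g_eff), condition = names(t_eff),
                   rep = 1:2, stringsAsFactors = FALSE)
  d$individual <- paste(d$genotype, d$condition, d$rep, sep = "_")
  d$pct_mC <- g_eff[d$genotype] + t_eff[d$condition] +
    ifelse(d$rep == 1, -0.5, 0.5)
  r <- anova_gxe(d)
  inter <- r$anova[r$anova$term == "G:T", ]
  expect_equal(inter$f_value, 0, tolerance = 1e-6)
  expect_equal(inter$p_value, 1, tolerance = 1e-6)
  expect_gt(r$anova$f_value[r$anova$term == "G"], 1)
})

test_that("type-II sums of squares match sequential ANOVA when balanced", {
  set.seed(15)
  d <- expand.grid(genotype = paste0("G", 1:4),
                   condition = c("fav", "unf"), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$individual <- paste(d$genotype, d$condition, d$rep, sep = "_")
  d$pct_mC <- rnorm(nrow(d), 35, 2)
  r <- anova_gxe(d)
  ref <- stats::anova(stats::lm(pct_mC ~ factor(genotype) * factor(condition),
                                data = d))
  expect_equal(r$anova$sum_sq, ref$`Sum Sq`[1:3], tolerance = 1e-9)
  expect_equal(r$anova$f_value, ref$`F value`[1:3], tolerance = 1e-9)
  expect_true(r$shapiro_p > 0 && r$shapiro_p <= 1)
  expect_true(all(c("fav", "unf") %in% names(r$tukey)))
})

test_that("anova_gxe validates design shape", {
  d <- data.frame(genotype = c("G1", "G1", "G2", "G2"),
                  condition = "fav",
                  individual = paste0("i", 1:4), pct_mC = rnorm(4))
  expect_error(anova_gxe(d), "two genotypes and two conditions")
  d2 <- expand.grid(genotype = c("G1", "G2"), condition = c("a", "b"),
                    stringsAsFactors = FALSE)
  d2$individual <- paste0("i", 1:4); d2$pct_mC <- rnorm(4)
  expect_error(anova_gxe(d2), "two individuals per")
})

test_that("strong interaction is detected with high power", {
  hit <- vapply(1:10, function(seed) {
    cfg <- hplc_sim_config(n_genotypes = 8L, gxe_sd = 3, noise_sd = 0.8,
                           seed = seed)
    agg <- aggregate_replicates(simulate_hplc(cfg)$nucleosides)
    r <- anova_gxe(agg$individuals)
    r$anova$p_value[r$anova$term == "G:T"] < 0.05
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("treatment p-values are uniform under permuted labels", {
  cfg <- hplc_sim_config(n_genotypes = 6L, env_effect = 0, gxe_sd = 0,
                         noise_sd = 1, seed = 44)
  agg <- aggregate_replicates(simulate_hplc(cfg)$nucleosides)
  ind <- agg$individuals
  set.seed(45)
  ps <- replicate(200, {
    # permute labels within genotype so every cell keeps its size
    ind$condition <- unlist(lapply(split(ind$condition, ind$genotype),
                                   sample), use.names = FALSE)[
      order(order(ind$genotype))]
    r <- anova_gxe(ind)
    r$anova$p_value[r$anova$term == "T"]
  })
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_lte(mean(ps < 0.05), 0.1)
})

test_that("correlate reports both coefficients with normality checks", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  r <- correlate(x, 2 * x + 1)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  r2 <- correlate(x, -x)
  expect_equal(r2$pearson_r, -1)
  expect_equal(r2$spearman_rho, -1)
  expect_error(correlate(x, rep(3, 8)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("opposite-sign biomass correlations are recovered per condition", {
  signs_ok <- vapply(1:10, function(seed) {
    cfg <- hplc_sim_config(n_genotypes = 30L,
                           biomass_r_favorable = 0.8,
                           biomass_r_unfavorable = -0.8, seed = seed)
    sim <- simulate_hplc(cfg)
    agg <- aggregate_replicates(sim$nucleosides)
    r <- vapply(c("favorable", "unfavorable"), function(cond) {
      s <- agg$summary[agg$summary$condition == cond, ]
      b <- sim$biomass[sim$biomass$condition == cond, ]
      b <- b[match(s$genotype, b$genotype), ]
      correlate(s$mean_pct_mC, b$biomass)$pearson_r
    }, numeric(1))
    r["favorable"] > 0 && r["unfavorable"] < 0
  }, logical(1))
  expect_gte(mean(signs_ok), 0.9)
})
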