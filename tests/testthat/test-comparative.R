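dmr_stub <- function(ids, dirs) {
  data.frame(window_id = ids, direction = dirs, stringsAsFactors = FALSE)
}

test_that("common DMRs are classified conserved or inversed", {
  a <- dmr_stub(c("w1", "w2", "w3"), c("hyper", "hyper", "hypo"))
  b <- dmr_stub(c("w2", "w3", "w4"), c("hyper", "hyper", "hypo"))
  ix <- intersect_dmrs(list(A = a, B = b))
  expect_equal(ix$common$window_id, c("w2", "w3"))
  expect_equal(ix$common$status, c("conserved", "inversed"))
  expect_equal(ix$exclusive$A, "w1")
  expect_equal(ix$exclusive$B, "w4")
  # symmetry in argument order
  ix2 <- intersect_dmrs(list(B = b, A = a))
  expect_setequal(ix2$common$window_id, ix$common$window_id)
  expect_equal(
    ix2$common$status[match(ix$common$window_id, ix2$common$window_id)],
    ix$common$status)
  # partition: conserved + inversed = common
  expect_equal(sum(ix$common$status == "conserved") +
                 sum(ix$common$status == "inversed"),
               nrow(ix$common))
})

test_that("disjoint sets, triples and grid mismatches behave", {
  a <- dmr_stub("w1", "hyper"); b <- dmr_stub("w2", "hypo")
  expect_equal(nrow(intersect_dmrs(list(a, b))$common), 0L)
  tri <- intersect_dmrs(list(
    dmr_stub(c("w1", "w2"), c("hyper", "hyper")),
    dmr_stub(c("w1", "w2"), c("hyper", "hypo")),
    dmr_stub(c("w1", "w2"), c("hyper", "hyper"))))
  expect_equal(tri$common$status, c("conserved", "inversed"))
  expect_error(intersect_dmrs(list(a, b), universe = "w1"),
               "outside the shared grid")
})

test_that("hypergeometric upper tail equals enumeration for N <= 25", {
  expect_equal(hypergeometric_upper_tail(4, 2, 2, 2), 1 / 6,
               tolerance = 1e-12)
  expect_equal(hypergeometric_upper_tail(10, 5, 5, 5), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_upper_tail(100, 10, 10, 0), 1)
  set.seed(6)
  for (i in 1:20) {
    N <- sample(4:25, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)
    expect_equal(hypergeometric_upper_tail(N, K, n, k),
                 oracle_hyper(N, K, n, k), tolerance = 1e-10)
  }
  # large-N log-space path agrees with the reference distribution
  expect_equal(hypergeometric_upper_tail(7550, 871, 1391, 255),
               stats::phyper(254, 871, 7550 - 871, 1391,
                             lower.tail = FALSE), tolerance = 1e-12)
  expect_error(hypergeometric_upper_tail(10, 3, 3, 4), "impossible")
})

test_that("overlap enrichment uses the shared tested-window universe", {
  u <- sprintf("w%d", 1:50)
  e <- test_overlap_enrichment(u[1:10], u[1:10], u)
  expect_equal(e$k, 10L)
  expect_equal(e$p_value, 1 / choose(50, 10) * 1, tolerance = 1e-12)
  # saturation: both sets equal the universe
  e2 <- test_overlap_enrichment(u, u, u)
  expect_equal(e2$k, e2$n)
  expect_equal(e2$p_value, 1)
  expect_error(test_overlap_enrichment(u[1:5], u[1:5], character(0)),
               "empty")
  expect_error(test_overlap_enrichment(c(u[1:5], "zz"), u[1:5], u),
               "subsets")
  # null calibration: independent random sets give roughly uniform p
  set.seed(9)
  ps <- replicate(60, {
    a <- sample(u, 12); b <- sample(u, 12)
    test_overlap_enrichment(a, b, u)$p_value
  })
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.35)
})

test_that("direction enrichment among conserved DMRs is exact", {
  common <- data.frame(
    window_id = sprintf("w%d", 1:20),
    direction_A = rep(c("hyper", "hypo"), each = 10),
    status = c(rep("conserved", 10), rep("inversed", 10)),
    stringsAsFactors = FALSE)
  e <- test_direction_enrichment(common)  # all conserved are hyper
  expect_equal(c(e$N, e$K, e$n, e$k), c(20L, 10L, 10L, 10L))
  expect_equal(e$p_value, oracle_hyper(20, 10, 10, 10), tolerance = 1e-10)
  # K = N (everything hyper) is certain
  common$direction_A <- "hyper"
  expect_equal(test_direction_enrichment(common)$p_value, 1)
  expect_error(test_direction_enrichment(common[0, ]), "no common")
})

test_that("DEG overlap crosses methylation and expression direction", {
  empty <- overlap_with_degs(
    data.frame(gene_id = "g1", direction = "hyper"),
    data.frame(gene_id = character(0), direction = character(0)),
    paste0("g", 1:10))
  expect_equal(sum(empty$table), 0L)
  expect_length(empty$tests, 0)

  universe <- paste0("g", 1:20)
  dmr_genes <- data.frame(gene_id = paste0("g", 1:8),
                          direction = rep(c("hyper", "hypo"), each = 4),
                          stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = paste0("g", 1:4),
                     direction = rep(c("up", "down"), 2),
                     stringsAsFactors = FALSE)
  ov <- overlap_with_degs(dmr_genes, degs, universe)
  expect_equal(ov$table["hyper", "up"], 2L)
  expect_equal(ov$table["hypo", "up"], 0L)
  # all DEGs inside hypermethylated genes: p equals brute-force tail
  expect_equal(ov$tests$hyper$p_value, oracle_hyper(20, 4, 4, 4),
               tolerance = 1e-10)
  expect_warning(
    ov2 <- overlap_with_degs(dmr_genes,
                             rbind(degs, data.frame(gene_id = "zz",
                                                    direction = "up")),
                             universe),
    "absent from the gene universe")
  expect_equal(ov2$n_dropped, 1L)

  # null: DEGs scattered over a large universe are rarely "enriched"
  set.seed(12)
  big_u <- paste0("g", 1:500)
  frac_sig <- mean(replicate(30, {
    dg <- data.frame(gene_id = sample(big_u, 60),
                     direction = sample(c("hyper", "hypo"), 60, TRUE))
    de <- data.frame(gene_id = sample(big_u, 40),
                     direction = sample(c("up", "down"), 40, TRUE))
    min(vapply(overlap_with_degs(dg, de, big_u)$tests,
               function(t) t$p_value, numeric(1))) < 0.05
  }))
  expect_lte(frac_sig, 0.2)
})

test_that("two experiments planting the same DMRs yield conserved overlap", {
  runs <- lapply(c(1, 2), function(rep_seed) {
    cfg <- sim_config(seed = 55)          # same planted windows/directions
    d <- simulate_probe_design(cfg)
    sim <- simulate_signals(d$probes, cfg)
    # different measurement noise per "experiment" via the analysis seed
    run <- run_dmr_pipeline(d$probes, sim$signals, sim$samples,
                            chrom_lengths_of(cfg),
                            run_config(seed = rep_seed))
    run
  })
  ix <- intersect_dmrs(list(e1 = runs[[1]]$dmrs, e2 = runs[[2]]$dmrs))
  expect_gt(nrow(ix$common), 0)
  truth_dirs <- ix$common$direction_e1 == ix$common$direction_e2
  expect_true(all(ix$common$status[truth_dirs] == "conserved"))
  u <- intersect(
    runs[[1]]$windows$favorable$window_id[
      runs[[1]]$windows$favorable$testable &
        runs[[1]]$windows$unfavorable$testable],
    runs[[2]]$windows$favorable$window_id[
      runs[[2]]$windows$favorable$testable &
        runs[[2]]$windows$unfavorable$testable])
  e <- test_overlap_enrichment(runs[[1]]$dmrs, runs[[2]]$dmrs, u)
  expect_lt(e$p_value, 0.001)
})
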