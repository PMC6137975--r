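# Independent brute-force oracles, kept free of the implementation paths
# they check.

# Exact two-sided one-sample Wilcoxon signed-rank p by enumeration of all
# 2^n sign assignments (no ties among |differences| assumed).
oracle_wilcoxon <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Upper-tail hypergeometric by enumeration of all C(N, n) draws.
oracle_hyper <- function(N, K, n, k) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= k)
}

# Small fast simulation world shared across tests.
tiny_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2L, chromosome_length = 5e5, n_genes = 100L,
         n_background = 100L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

chrom_lengths_of <- function(cfg) {
  stats::setNames(rep(cfg$chromosome_length, cfg$n_chromosomes),
                  paste0("chr", seq_len(cfg$n_chromosomes)))
}

run_tiny_pipeline <- function(cfg, rc = NULL) {
  d <- simulate_probe_design(cfg)
  sim <- simulate_signals(d$probes, cfg)
  if (is.null(rc)) rc <- run_config(seed = cfg$seed)
  run <- run_dmr_pipeline(d$probes, sim$signals, sim$samples,
                          chrom_lengths_of(cfg), rc)
  list(design = d, sim = sim, run = run)
}
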