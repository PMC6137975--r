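#' Simulation configuration for the synthetic MeDIP-chip world
#'
#' Bundles and validates every knob of the toy-genome generator: genome
#' geometry, probe design density, the two-component signal mixture, and
#' the planted-DMR scheme. Defaults describe a 3 chromosome x 2 Mb genome
#' (120 windows of 50 kb) with ~30 probes per window, a bimodal signal
#' whose high (methylated) component carries 65% of the probes, and
#' condition-induced shifts of 4.2 signal units confined to 10% of
#' windows.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of every chromosome, bp.
#' @param window_size analysis window size, bp (default 50000).
#' @param n_genes genes placed across the genome (5 probes each).
#' @param n_background non-genic background probes across the genome,
#'   always labelled INTERGENIC (or TE when overlapping a transposable
#'   element).
#' @param te_fraction approximate fraction of each chromosome covered by
#'   transposable-element intervals, in `[0, 1]`.
#' @param mu_low,sigma_low mean and sd of the low (unmethylated) mixture
#'   component, dimensionless normalized intensity.
#' @param mu_high,sigma_high mean and sd of the high (methylated)
#'   component; `mu_low < mu_high` required.
#' @param p_high per-probe probability of the high component.
#' @param dmr_fraction fraction of windows planted as true DMRs.
#' @param delta signal shift added (hyper) or subtracted (hypo) in the
#'   unfavorable condition inside planted windows.
#' @param p_hyper probability that a planted DMR is hypermethylated
#'   (shifted up) rather than hypomethylated.
#' @param n_replicates replicate samples per condition (default 5;
#'   the emulated design used four to six individuals per condition).
#' @param sigma_rep sd of per-replicate Gaussian noise.
#' @param gene_length gene body length, bp.
#' @param te_length transposable-element interval length, bp.
#' @param seed integer seed; every generator draw flows from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 3L,
                       chromosome_length = 2e6,
                       window_size = 50000L,
                       n_genes = 600L,
                       n_background = 600L,
                       te_fraction = 0.15,
                       mu_low = -1, sigma_low = 0.4,
                       mu_high = 1, sigma_high = 0.4,
                       p_high = 0.65,
                       dmr_fraction = 0.1,
                       delta = 4.2,
                       p_hyper = 0.7,
                       n_replicates = 5L,
                       sigma_rep = 0.3,
                       gene_length = 2000L,
                       te_length = 500L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.numeric(chromosome_length),
    window_size = as.numeric(window_size),
    n_genes = as.integer(n_genes),
    n_background = as.integer(n_background),
    te_fraction = te_fraction,
    mu_low = mu_low, sigma_low = sigma_low,
    mu_high = mu_high, sigma_high = sigma_high,
    p_high = p_high,
    dmr_fraction = dmr_fraction,
    delta = delta,
    p_hyper = p_hyper,
    n_replicates = as.integer(n_replicates),
    sigma_rep = sigma_rep,
    gene_length = as.numeric(gene_length),
    te_length = as.numeric(te_length),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1L,
    cfg$chromosome_length > 0,
    cfg$window_size > 0,
    cfg$n_genes >= 0L,
    cfg$n_background >= 0L,
    cfg$gene_length > 0,
    cfg$te_length > 0,
    cfg$n_replicates >= 1L,
    cfg$sigma_low > 0, cfg$sigma_high > 0, cfg$sigma_rep >= 0
  )
  if (cfg$te_fraction < 0 || cfg$te_fraction > 1)
    stop("te_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$p_high < 0 || cfg$p_high > 1)
    stop("p_high must lie in [0, 1]", call. = FALSE)
  if (cfg$dmr_fraction < 0 || cfg$dmr_fraction > 1)
    stop("dmr_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$p_hyper < 0 || cfg$p_hyper > 1)
    stop("p_hyper must lie in [0, 1]", call. = FALSE)
  if (!(cfg$mu_low < cfg$mu_high))
    stop("mu_low must be strictly below mu_high", call. = FALSE)
  invisible(cfg)
}

#' Simulation configuration for HPLC global-methylation tables
#'
#' Describes a genotype x environment world for global DNA methylation
#' percentage (%mC): a base level plus genotype, environment and
#' interaction effects, a nested replicate scheme (individuals x
#' hydrolysis replicates x HPLC runs), and genotype-level biomass whose
#' correlation with mean %mC has a configured sign in each condition
#' (positive under favorable, negative under unfavorable growth).
#'
#' @param n_genotypes number of genotypes.
#' @param conditions character vector of condition labels; the first is
#'   treated as favorable, the second as unfavorable.
#' @param base_mC baseline global methylation, percent.
#' @param genotype_sd sd of genotype main effects, percentage points.
#' @param env_effect additive shift of the unfavorable condition,
#'   percentage points.
#' @param gxe_sd sd of genotype-by-environment interaction effects.
#' @param noise_sd sd of per-individual biological noise.
#' @param tech_sd sd of per-measurement technical noise (hydrolysis/run).
#' @param biomass_r_favorable target genotype-level Pearson correlation
#'   between mean %mC and biomass under the favorable condition, in
#'   `(0, 1]`.
#' @param biomass_r_unfavorable same under the unfavorable condition, in
#'   `[-1, 0)`.
#' @param n_individuals individuals per genotype x condition.
#' @param n_hydrolysis hydrolysis replicates per individual (default 2).
#' @param n_runs HPLC runs per hydrolysis replicate (default 2).
#' @param seed integer seed.
#' @return an object of class `hplc_sim_config`.
#' @export
hplc_sim_config <- function(n_genotypes = 8L,
                            conditions = c("favorable", "unfavorable"),
                            base_mC = 36,
                            genotype_sd = 2,
                            env_effect = -1,
                            gxe_sd = 1.5,
                            noise_sd = 1,
                            tech_sd = 0.3,
                            biomass_r_favorable = 0.8,
                            biomass_r_unfavorable = -0.8,
                            n_individuals = 4L,
                            n_hydrolysis = 2L,
                            n_runs = 2L,
                            seed = 1L) {
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    conditions = as.character(conditions),
    base_mC = base_mC,
    genotype_sd = genotype_sd,
    env_effect = env_effect,
    gxe_sd = gxe_sd,
    noise_sd = noise_sd,
    tech_sd = tech_sd,
    biomass_r_favorable = biomass_r_favorable,
    biomass_r_unfavorable = biomass_r_unfavorable,
    n_individuals = as.integer(n_individuals),
    n_hydrolysis = as.integer(n_hydrolysis),
    n_runs = as.integer(n_runs),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genotypes >= 1L,
    length(cfg$conditions) >= 2L,
    cfg$genotype_sd >= 0, cfg$gxe_sd >= 0, cfg$noise_sd >= 0,
    cfg$tech_sd >= 0,
    cfg$n_individuals >= 1L, cfg$n_hydrolysis >= 1L, cfg$n_runs >= 1L
  )
  if (!(cfg$biomass_r_favorable > 0 && cfg$biomass_r_favorable <= 1))
    stop("biomass_r_favorable must lie in (0, 1]", call. = FALSE)
  if (!(cfg$biomass_r_unfavorable < 0 && cfg$biomass_r_unfavorable >= -1))
    stop("biomass_r_unfavorable must lie in [-1, 0)", call. = FALSE)
  class(cfg) <- "hplc_sim_config"
  cfg
}

#' Analysis run configuration
#'
#' Parameters of the DMR-calling pipeline: window size, the random
#' fraction of probes reserved for reference-mean estimation, the FDR
#' level and method, and the minimum probe count below which a window is
#' untestable.
#'
#' @param window_size analysis window, bp (default 50000, the 50 kb
#'   window the method is built around); must be at least 1000.
#' @param ref_fraction fraction of probes (per chromosome) used for the
#'   reference mean, in `(0, 1)`; default 0.2.
#' @param alpha FDR level gating nonzero scores, in `(0, 1)`; default
#'   0.05.
#' @param fdr_method `"bh"` (Benjamini-Hochberg step-up, default) or
#'   `"local"` (tail-area two-group estimator, see [adjust_fdr()]).
#' @param min_probes_per_window windows with fewer finite probe values
#'   are marked untestable; default 3.
#' @param conditions labels of the two compared conditions,
#'   `c(favorable, unfavorable)`.
#' @param seed integer seed for the reference-subset draw.
#' @return an object of class `run_config`.
#' @export
run_config <- function(window_size = 50000,
                       ref_fraction = 0.2,
                       alpha = 0.05,
                       fdr_method = c("bh", "local"),
                       min_probes_per_window = 3L,
                       conditions = c("favorable", "unfavorable"),
                       seed = 1L) {
  fdr_method <- match.arg(fdr_method)
  if (!(ref_fraction > 0 && ref_fraction < 1))
    stop("ref_fraction must lie strictly in (0, 1)", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  if (window_size < 1000)
    stop("window_size must be >= 1000 bp", call. = FALSE)
  stopifnot(min_probes_per_window >= 1L, length(conditions) == 2L)
  structure(list(
    window_size = as.numeric(window_size),
    ref_fraction = ref_fraction,
    alpha = alpha,
    fdr_method = fdr_method,
    min_probes_per_window = as.integer(min_probes_per_window),
    conditions = as.character(conditions),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("DMR run configuration\n")
  cat(sprintf("  window size      : %g bp\n", x$window_size))
  cat(sprintf("  reference subset : %g%% of probes per chromosome\n",
              100 * x$ref_fraction))
  cat(sprintf("  FDR              : %s at alpha = %g\n",
              x$fdr_method, x$alpha))
  cat(sprintf("  min probes/window: %d\n", x$min_probes_per_window))
  cat(sprintf("  conditions       : %s (favorable) vs %s (unfavorable)\n",
              x$conditions[1], x$conditions[2]))
  invisible(x)
}
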