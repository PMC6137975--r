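PROBE_CATEGORIES <- c("BODY", "PROMOTER", "TE", "BODY+TE", "PROM+TE",
                      "INTERGENIC")

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Place k non-overlapping intervals of length len uniformly on [0, total).
# Classical spacing construction: sorted uniforms on the free space plus
# cumulative interval offsets; exact and rejection-free.
place_nonoverlapping <- function(k, len, total) {
  if (k == 0L) return(numeric(0))
  free <- total - k * len
  if (free < 0)
    stop(sprintf(
      "cannot place %d features of %g bp on a %g bp chromosome: density too high",
      k, len, total), call. = FALSE)
  sort(runif(k, 0, free)) + (seq_len(k) - 1L) * len
}

# Uniform positions on the complement of occupied [start,end) intervals.
sample_in_gaps <- function(n, occupied_start, occupied_end, total, len) {
  if (n == 0L) return(numeric(0))
  o <- order(occupied_start)
  s <- occupied_start[o]; e <- occupied_end[o]
  gaps_start <- c(0, e)
  gaps_end <- c(s, total)
  w <- pmax(0, gaps_end - gaps_start - len)  # room for a probe of length len
  if (sum(w) <= 0)
    stop("no intergenic room left for background probes", call. = FALSE)
  g <- sample.int(length(w), n, replace = TRUE, prob = w)
  gaps_start[g] + runif(n) * w[g]
}

#' Simulate a probe design on a toy genome
#'
#' Places `n_genes` genes (with 0.5 kb promoter and downstream flanks)
#' without overlap on each chromosome and designs five probes per gene:
#' one in the upstream promoter (PROMOTER), three in the gene body
#' (BODY), and one in the 0.5 kb downstream flank (INTERGENIC, but still
#' linked to its gene). `n_background` additional probes fall in the
#' space between gene footprints (INTERGENIC). Transposable-element
#' intervals covering roughly `te_fraction` of each chromosome re-label
#' overlapped probes: BODY to BODY+TE, PROMOTER to PROM+TE, INTERGENIC
#' to TE. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `probes` (probe_id, chrom, start, end, category,
#'   gene_id), `genes` (gene_id, chrom, start, end, strand) and `tes`
#'   data frames; coordinates 0-based half-open.
#' @export
simulate_probe_design <- function(config) {
  validate_sim_config(config)
  probe_len <- 60
  with_local_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    genes_per_chrom <- diff(round(seq(0, config$n_genes,
                                      length.out = config$n_chromosomes + 1L)))
    gene_rows <- list(); probe_rows <- list(); te_rows <- list()
    gid <- 0L
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      clen <- config$chromosome_length
      k <- genes_per_chrom[ci]
      footprint <- config$gene_length + 1000  # body + both 0.5 kb flanks
      fstart <- place_nonoverlapping(k, footprint, clen)
      gstart <- fstart + 500
      gend <- gstart + config$gene_length
      ids <- if (k > 0L) sprintf("gene%05d", gid + seq_len(k)) else character(0)
      gid <- gid + k
      gene_rows[[ci]] <- data.frame(
        gene_id = ids, chrom = rep(chrom, k),
        start = gstart, end = gend, strand = rep("+", k),
        stringsAsFactors = FALSE)

      if (k > 0L) {
        prom <- gstart - 500 + runif(k) * (500 - probe_len)
        body1 <- gstart + runif(k) * (config$gene_length / 3 - probe_len)
        body2 <- gstart + config$gene_length / 3 +
          runif(k) * (config$gene_length / 3 - probe_len)
        body3 <- gstart + 2 * config$gene_length / 3 +
          runif(k) * (config$gene_length / 3 - probe_len)
        down <- gend + runif(k) * (500 - probe_len)
        probe_rows[[length(probe_rows) + 1L]] <- data.frame(
          chrom = rep(chrom, 5L * k),
          start = c(prom, body1, body2, body3, down),
          category = rep(c("PROMOTER", "BODY", "BODY", "BODY", "INTERGENIC"),
                         each = k),
          gene_id = rep(ids, 5L),
          stringsAsFactors = FALSE)
      }

      # background probes in the gaps between gene footprints
      nb <- diff(round(seq(0, config$n_background,
                           length.out = config$n_chromosomes + 1L)))[ci]
      if (nb > 0L) {
        bg <- sample_in_gaps(nb, fstart, fstart + footprint, clen, probe_len)
        probe_rows[[length(probe_rows) + 1L]] <- data.frame(
          chrom = rep(chrom, nb), start = bg,
          category = rep("INTERGENIC", nb),
          gene_id = rep(NA_character_, nb),
          stringsAsFactors = FALSE)
      }

      n_te <- round(config$te_fraction * clen / config$te_length)
      if (n_te > 0L) {
        ts <- runif(n_te, 0, clen - config$te_length)
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          chrom = rep(chrom, n_te), start = ts,
          end = ts + config$te_length, stringsAsFactors = FALSE)
      }
    }

    genes <- do.call(rbind, gene_rows)
    tes <- if (length(te_rows)) do.call(rbind, te_rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    probes <- if (length(probe_rows)) do.call(rbind, probe_rows) else
      data.frame(chrom = character(0), start = numeric(0),
                 category = character(0), gene_id = character(0))
    if (nrow(probes)) {
      probes$start <- floor(probes$start)
      probes$end <- probes$start + probe_len
      # TE relabelling by probe midpoint containment
      if (nrow(tes)) {
        mid <- (probes$start + probes$end) / 2
        in_te <- rep(FALSE, nrow(probes))
        for (chrom in unique(tes$chrom)) {
          p <- which(probes$chrom == chrom)
          te <- tes[tes$chrom == chrom, ]
          o <- order(te$start)
          idx <- findInterval(mid[p], te$start[o])
          hit <- idx >= 1L & mid[p] < te$end[o][pmax(idx, 1L)]
          in_te[p[hit]] <- TRUE
        }
        probes$category[in_te & probes$category == "BODY"] <- "BODY+TE"
        probes$category[in_te & probes$category == "PROMOTER"] <- "PROM+TE"
        probes$category[in_te & probes$category == "INTERGENIC"] <- "TE"
      }
      probes <- probes[order(probes$chrom, probes$start), ]
      probes$probe_id <- sprintf("probe%06d", seq_len(nrow(probes)))
      probes <- probes[, c("probe_id", "chrom", "start", "end",
                           "category", "gene_id")]
      rownames(probes) <- NULL
      stopifnot(all(probes$start >= 0),
                all(probes$end <= config$chromosome_length))
    }
    rownames(genes) <- NULL
    list(probes = probes, genes = genes, tes = tes)
  })
}

#' Window grid of a simulated genome
#'
#' @param config a [sim_config()].
#' @return data frame of consecutive windows (window_id, chrom, start,
#'   end), the last window of each chromosome truncated at the
#'   chromosome end.
#' @export
sim_windows <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  lens <- rep(config$chromosome_length, config$n_chromosomes)
  window_grid(chroms, lens, config$window_size)
}

#' Simulate bimodal MeDIP-chip signals with planted DMRs
#'
#' Each probe receives one base signal from the two-component Gaussian
#' mixture, shared between conditions (methylation is a property of the
#' locus). Probes whose midpoint lies inside a planted DMR window are
#' shifted by `+delta` (hyper) or `-delta` (hypo) in the unfavorable
#' condition only. Independent `N(0, sigma_rep)` noise is added per
#' replicate sample. The returned truth table covers every window of the
#' genome exactly once.
#'
#' @param probes probe table from [simulate_probe_design()].
#' @param config the same [sim_config()].
#' @return list with `signals` (named list of probe x replicate
#'   matrices, one per condition), `samples` (sample metadata data
#'   frame) and `truth` (window_id, chrom, start, end, is_dmr,
#'   planted_direction).
#' @export
simulate_signals <- function(probes, config) {
  validate_sim_config(config)
  if (nrow(probes) == 0L) stop("probe table is empty", call. = FALSE)
  wins <- sim_windows(config)
  with_local_seed(config$seed + 1L, {
    n_plant <- floor(config$dmr_fraction * nrow(wins))
    if (config$dmr_fraction > 0 && n_plant < 1L)
      warning("dmr_fraction times window count is below 1; no DMRs planted")
    planted <- if (n_plant > 0L) sort(sample.int(nrow(wins), n_plant)) else
      integer(0)
    direction <- rep("none", nrow(wins))
    if (n_plant > 0L)
      direction[planted] <- ifelse(runif(n_plant) < config$p_hyper,
                                   "hyper", "hypo")
    truth <- data.frame(
      window_id = wins$window_id, chrom = wins$chrom,
      start = wins$start, end = wins$end,
      is_dmr = direction != "none",
      planted_direction = direction,
      stringsAsFactors = FALSE)

    n <- nrow(probes)
    comp_high <- runif(n) < config$p_high
    base <- ifelse(comp_high,
                   rnorm(n, config$mu_high, config$sigma_high),
                   rnorm(n, config$mu_low, config$sigma_low))

    probe_win <- assign_windows(probes, wins)
    shift <- numeric(n)
    dir_by_win <- stats::setNames(direction, wins$window_id)
    pd <- dir_by_win[probe_win]
    shift[!is.na(pd) & pd == "hyper"] <- config$delta
    shift[!is.na(pd) & pd == "hypo"] <- -config$delta

    r <- config$n_replicates
    mk <- function(mu) {
      m <- matrix(mu, nrow = n, ncol = r) +
        matrix(rnorm(n * r, 0, config$sigma_rep), nrow = n, ncol = r)
      rownames(m) <- probes$probe_id
      m
    }
    fav <- mk(base)
    unf <- mk(base + shift)
    colnames(fav) <- sprintf("fav_rep%d", seq_len(r))
    colnames(unf) <- sprintf("unf_rep%d", seq_len(r))
    samples <- data.frame(
      sample_id = c(colnames(fav), colnames(unf)),
      condition = rep(c("favorable", "unfavorable"), each = r),
      replicate = rep(seq_len(r), 2L),
      stringsAsFactors = FALSE)
    list(signals = list(favorable = fav, unfavorable = unf),
         samples = samples, truth = truth)
  })
}

#' Simulate HPLC nucleoside tables with genotype x environment structure
#'
#' Per-individual true %mC is `base + genotype + environment + GxE +
#' noise`; each individual yields `n_hydrolysis x n_runs` (C, mC)
#' measurement pairs whose implied percentage adds technical noise.
#' Values outside `[0, 100]` are clipped and flagged. Genotype-level
#' biomass is constructed so that the expected Pearson correlation
#' between genotype-mean %mC and biomass equals the configured target in
#' each condition (positive under favorable, negative under unfavorable
#' growth).
#'
#' @param config an [hplc_sim_config()].
#' @return list with `nucleosides` (genotype, condition, individual,
#'   hydrolysis, run, C_amount, mC_amount, clipped) and `biomass`
#'   (genotype, condition, biomass) data frames.
#' @export
simulate_hplc <- function(config) {
  with_local_seed(config$seed + 2L, {
    g <- config$n_genotypes
    conds <- config$conditions
    genos <- sprintf("G%02d", seq_len(g))
    g_eff <- rnorm(g, 0, config$genotype_sd)
    env <- stats::setNames(
      c(0, rep(config$env_effect, length(conds) - 1L)), conds)
    gxe <- matrix(rnorm(g * length(conds), 0, config$gxe_sd),
                  nrow = g, dimnames = list(genos, conds))

    rows <- list(); cell_mean <- matrix(NA_real_, g, length(conds),
                                        dimnames = list(genos, conds))
    for (ci in seq_along(conds)) for (gi in seq_len(g)) {
      mu_cell <- config$base_mC + g_eff[gi] + env[ci] + gxe[gi, ci]
      ind_mc <- mu_cell + rnorm(config$n_individuals, 0, config$noise_sd)
      cell_mean[gi, ci] <- mean(pmin(pmax(ind_mc, 0), 100))
      for (ii in seq_len(config$n_individuals)) {
        total <- exp(rnorm(1, log(100), 0.1))  # arbitrary nucleoside units
        for (hi in seq_len(config$n_hydrolysis))
          for (ri in seq_len(config$n_runs)) {
            pct <- ind_mc[ii] + rnorm(1, 0, config$tech_sd)
            clipped <- pct < 0 || pct > 100
            pct <- min(max(pct, 0), 100)
            rows[[length(rows) + 1L]] <- data.frame(
              genotype = genos[gi], condition = conds[ci],
              individual = sprintf("%s_%s_i%d", genos[gi], conds[ci], ii),
              hydrolysis = hi, run = ri,
              C_amount = total * (1 - pct / 100),
              mC_amount = total * pct / 100,
              clipped = clipped, stringsAsFactors = FALSE)
          }
      }
    }
    nucleosides <- do.call(rbind, rows)

    # biomass with the configured correlation sign per condition:
    # r * standardized genotype-mean %mC + sqrt(1 - r^2) * independent noise
    bio <- list()
    for (ci in seq_along(conds)) {
      r_target <- if (ci == 1L) config$biomass_r_favorable else
        config$biomass_r_unfavorable
      zm <- as.numeric(scale(cell_mean[, ci]))
      if (any(!is.finite(zm))) zm <- rep(0, g)  # degenerate: zero variance
      b <- r_target * zm + sqrt(1 - r_target^2) * rnorm(g)
      bio[[ci]] <- data.frame(
        genotype = genos, condition = conds[ci],
        biomass = 100 + 20 * b, stringsAsFactors = FALSE)
    }
    list(nucleosides = nucleosides, biomass = do.call(rbind, bio))
  })
}
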