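#' Intersect DMR sets across experiments
#'
#' Windows called as DMRs in two or more experiments form the common
#' set; a common DMR is `conserved` when the direction of methylation
#' change (hyper/hypo, favorable to unfavorable) agrees in every
#' experiment it appears in, `inversed` otherwise. For three or more
#' experiments the status refers to the windows present in all sets.
#' Symmetric in argument order.
#'
#' @param dmr_sets named list of DMR tables (from [call_dmrs()]) indexed
#'   on one shared window grid.
#' @param universe optional character vector of window ids tested in all
#'   experiments; DMR window ids outside it raise an error.
#' @return list with `common` (window_id, one direction column per
#'   experiment, status), and `exclusive` (named list of window ids
#'   unique to each experiment).
#' @export
intersect_dmrs <- function(dmr_sets, universe = NULL) {
  stopifnot(length(dmr_sets) >= 2L)
  if (is.null(names(dmr_sets)))
    names(dmr_sets) <- paste0("exp", seq_along(dmr_sets))
  if (!is.null(universe)) {
    for (nm in names(dmr_sets)) {
      bad <- setdiff(dmr_sets[[nm]]$window_id, universe)
      if (length(bad))
        stop(sprintf("DMR windows of %s outside the shared grid: %s",
                     nm, paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
    }
  }
  ids <- lapply(dmr_sets, function(d) d$window_id)
  common_ids <- Reduce(intersect, ids)
  dirs <- lapply(dmr_sets, function(d)
    stats::setNames(d$direction, d$window_id)[common_ids])
  common <- data.frame(window_id = common_ids, stringsAsFactors = FALSE)
  for (nm in names(dmr_sets))
    common[[paste0("direction_", nm)]] <- unname(dirs[[nm]])
  if (length(common_ids)) {
    dm <- do.call(cbind, dirs)
    common$status <- ifelse(apply(dm, 1, function(r) length(unique(r))) == 1L,
                            "conserved", "inversed")
  } else common$status <- character(0)
  exclusive <- lapply(names(dmr_sets), function(nm)
    setdiff(ids[[nm]], unlist(ids[setdiff(names(dmr_sets), nm)])))
  names(exclusive) <- names(dmr_sets)
  list(common = common, exclusive = exclusive)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` successes when drawing `n` objects without
#' replacement from a population of `N` containing `K` successes.
#' Computed exactly by summing the point masses in log space
#' (log-sum-exp over `lchoose` terms).
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @param k observed successes.
#' @return the upper-tail probability, in `(0, 1]`.
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N)
  if (k > min(K, n))
    stop(sprintf("impossible overlap: k = %d exceeds min(K, n) = %d",
                 k, min(K, n)), call. = FALSE)
  if (k <= max(0L, n + K - N)) return(1)
  i <- seq.int(k, min(K, n))
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

#' Over-representation of common DMRs between two experiments
#'
#' Tests, with the upper-tail hypergeometric distribution, whether more
#' DMRs are shared between two experiments than expected when drawing
#' without replacement from the shared universe of tested windows:
#' `N = |universe|`, `K = |DMRs A|`, `n = |DMRs B|`, `k = |common|`.
#'
#' @param dmrs_A,dmrs_B DMR tables or character vectors of window ids.
#' @param universe_windows character vector of window ids tested in both
#'   experiments.
#' @return list of class `enrichment_result`: `N`, `K`, `n`, `k`,
#'   `p_value`.
#' @export
test_overlap_enrichment <- function(dmrs_A, dmrs_B, universe_windows) {
  ids_A <- if (is.data.frame(dmrs_A)) dmrs_A$window_id else dmrs_A
  ids_B <- if (is.data.frame(dmrs_B)) dmrs_B$window_id else dmrs_B
  if (length(universe_windows) == 0L)
    stop("empty window universe", call. = FALSE)
  if (length(setdiff(ids_A, universe_windows)) ||
      length(setdiff(ids_B, universe_windows)))
    stop("DMR sets must be subsets of the universe", call. = FALSE)
  N <- length(unique(universe_windows))
  K <- length(unique(ids_A))
  n <- length(unique(ids_B))
  k <- length(intersect(ids_A, ids_B))
  structure(list(N = N, K = K, n = n, k = k,
                 p_value = hypergeometric_upper_tail(N, K, n, k)),
            class = "enrichment_result")
}

#' Over-representation of hypermethylation among conserved DMRs
#'
#' Tests whether hypermethylated DMRs are over-represented among the
#' conserved common DMRs relative to a random draw from all common
#' DMRs: `N = |common|`, `K` = hypermethylated among common,
#' `n = |conserved|`, `k` = hypermethylated among conserved.
#' Direction of a common DMR is taken from the first experiment's
#' direction column.
#'
#' @param common_dmrs `common` table from [intersect_dmrs()].
#' @return an `enrichment_result`.
#' @export
test_direction_enrichment <- function(common_dmrs) {
  if (nrow(common_dmrs) == 0L)
    stop("no common DMRs to test", call. = FALSE)
  dir_col <- grep("^direction_", names(common_dmrs), value = TRUE)[1]
  N <- nrow(common_dmrs)
  K <- sum(common_dmrs[[dir_col]] == "hyper")
  conserved <- common_dmrs$status == "conserved"
  n <- sum(conserved)
  k <- sum(conserved & common_dmrs[[dir_col]] == "hyper")
  structure(list(N = N, K = K, n = n, k = k,
                 p_value = hypergeometric_upper_tail(N, K, n, k)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric over-representation: k = %d of n = %d draws (K = %d of N = %d), upper-tail P = %.4g\n",
    x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Overlap of DMR genes with differentially expressed genes
#'
#' Crosses the genes covered by hyper- and hypomethylated DMRs with an
#' external up/down-regulated DEG list and tests, per methylation
#' direction, whether DEGs are over-represented among that direction's
#' genes: `N = |gene universe|`, `K` = genes of the methylation class,
#' `n` = DEGs (in the universe), `k` = their overlap. DEG ids absent
#' from the universe are dropped with a warning.
#'
#' @param dmr_genes data frame (`gene_id`, `direction` hyper/hypo) of
#'   genes covered by DMRs, e.g. unnested from [annotate_dmrs()].
#' @param deg_list data frame (`gene_id`, `direction` up/down).
#' @param gene_universe character vector: genes overlapped by any tested
#'   window.
#' @return list with `table` (methylation x expression counts of
#'   overlapping genes), `tests` (named list of `enrichment_result`, one
#'   per methylation direction), and `n_dropped` DEG ids outside the
#'   universe.
#' @export
overlap_with_degs <- function(dmr_genes, deg_list, gene_universe) {
  gene_universe <- unique(gene_universe)
  if (nrow(deg_list) == 0L)
    return(list(table = matrix(0L, 2, 2,
                               dimnames = list(c("hyper", "hypo"),
                                               c("up", "down"))),
                tests = list(), n_dropped = 0L))
  dropped <- !(deg_list$gene_id %in% gene_universe)
  if (any(dropped))
    warning(sprintf("%d DEG id(s) absent from the gene universe; excluded",
                    sum(dropped)))
  deg <- deg_list[!dropped, , drop = FALSE]
  dmr_genes <- dmr_genes[dmr_genes$gene_id %in% gene_universe, ,
                         drop = FALSE]
  tab <- matrix(0L, 2, 2, dimnames = list(c("hyper", "hypo"),
                                          c("up", "down")))
  for (md in rownames(tab)) for (ed in colnames(tab)) {
    tab[md, ed] <- length(intersect(
      unique(dmr_genes$gene_id[dmr_genes$direction == md]),
      unique(deg$gene_id[deg$direction == ed])))
  }
  tests <- list()
  n_deg <- length(unique(deg$gene_id))
  for (md in c("hyper", "hypo")) {
    class_genes <- unique(dmr_genes$gene_id[dmr_genes$direction == md])
    k <- length(intersect(class_genes, unique(deg$gene_id)))
    tests[[md]] <- structure(
      list(N = length(gene_universe), K = length(class_genes),
           n = n_deg, k = k,
           p_value = hypergeometric_upper_tail(
             length(gene_universe), length(class_genes), n_deg, k)),
      class = "enrichment_result")
  }
  list(table = tab, tests = tests, n_dropped = sum(dropped))
}
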