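#' Degree-preserving randomization of a functional network
#'
#' Shuffles the connections of a network by repeated double-edge swaps
#' (replace edges (a,b) and (c,d) by (a,d) and (c,b) when that creates no
#' self-loop or duplicate edge), which preserves every node's degree — and
#' hence the active-node set, edge count, and degree distribution — exactly.
#' Swap attempts that would violate simplicity are skipped, so graphs with
#' no valid swap (e.g. a triangle) come back unchanged.
#'
#' @param net A \code{functional_network} with at least 2 edges.
#' @param swaps_per_edge Attempted swaps per edge (Maslov-Sneppen
#'   convention; default 10).
#' @param seed Optional seed; fixed seed gives a bit-identical rewiring.
#' @return A rewired \code{functional_network} with identical degree
#'   sequence.
#' @export
rewire_preserving_degree <- function(net, swaps_per_edge = 10, seed = NULL) {
  stopifnot(inherits(net, "functional_network"))
  m <- n_edges(net)
  assert_that(m >= 2, "rewiring needs at least 2 edges")
  g <- as_igraph(net)
  g2 <- with_seed_opt(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = swaps_per_edge * m)))
  adj <- as.matrix(igraph::as_adjacency_matrix(g2))
  adj <- adj[net$region_order, net$region_order]
  functional_network(adj, threshold_p = net$threshold_p, group = net$group,
                     region_order = net$region_order)
}

#' Null ensemble of degree-preserving rewired networks
#'
#' Generates \code{n} independent rewirings of the data network and computes
#' graph measures on each, so the data network's structure can be compared
#' with what identical degree sequences produce by chance. Reports the data
#' value of each measure and its empirical quantile within the ensemble
#' (midpoint convention: (#less + 0.5 #equal) / n). Undefined measures on a
#' replicate are recorded as NA, not fatal.
#'
#' @param net A \code{functional_network}.
#' @param n Number of replicates (the full analysis uses 1000).
#' @param seed Seed for the whole ensemble.
#' @param measures Which measures to compute per replicate.
#' @param swaps_per_edge Swaps per edge for each rewiring.
#' @param n_random ER ensemble size inside each small-worldness evaluation.
#' @return An object of class \code{null_ensemble}: per-replicate measure
#'   matrix, data values, and empirical quantiles.
#' @export
build_null_ensemble <- function(net, n = 1000, seed = NULL,
                                measures = c("transitivity", "assortativity",
                                             "small_worldness"),
                                swaps_per_edge = 10, n_random = 100) {
  stopifnot(inherits(net, "functional_network"))
  measures <- match.arg(measures, several.ok = TRUE)
  measure_fun <- list(
    transitivity = net_transitivity,
    assortativity = net_assortativity,
    small_worldness = function(x) small_worldness(x, n_random = n_random))

  data_values <- vapply(measures, function(msr) measure_fun[[msr]](net),
                        numeric(1))
  replicate_values <- with_seed_opt(seed, {
    vals <- matrix(NA_real_, nrow = n, ncol = length(measures),
                   dimnames = list(NULL, measures))
    for (i in seq_len(n)) {
      null_net <- rewire_preserving_degree(net, swaps_per_edge)
      for (msr in measures) {
        vals[i, msr] <- measure_fun[[msr]](null_net)
      }
    }
    vals
  })
  quantiles <- vapply(measures, function(msr) {
    x <- replicate_values[, msr]
    d <- data_values[[msr]]
    if (is.na(d)) return(NA_real_)
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    (sum(x < d) + 0.5 * sum(x == d)) / length(x)
  }, numeric(1))
  structure(
    list(n_replicates = n, measures = measures,
         replicate_values = replicate_values,
         data_values = data_values, quantiles = quantiles,
         swaps_per_edge = swaps_per_edge, seed = seed),
    class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> ", x$n_replicates, " degree-preserving replicates\n",
      sep = "")
  for (msr in x$measures) {
    cat(sprintf("  %-16s data = %.4f, null mean = %.4f, quantile = %.3f\n",
                msr, x$data_values[[msr]],
                mean(x$replicate_values[, msr], na.rm = TRUE),
                x$quantiles[[msr]]))
  }
  invisible(x)
}

#' Network structure across a grid of p-value thresholds
#'
#' Rebuilds the functional network at each threshold of a p-value grid
#' (default: 20 thresholds, p < 0.005 to p < 0.1 in steps of 0.005),
#' computes the global graph measures, and compares each against a
#' degree-preserving null ensemble at that threshold. Thresholds yielding an
#' empty network are recorded as undefined rows rather than dropped.
#'
#' @param corr A \code{group_correlation_matrix}.
#' @param p_grid Thresholds to sweep.
#' @param n_null Null replicates per threshold (the full analysis uses
#'   1000).
#' @param seed Master seed; per-threshold seeds derive from it.
#' @param measures Measures to track.
#' @param n_random ER ensemble size for small-worldness.
#' @param swaps_per_edge Swaps per edge in the null rewiring.
#' @return A data frame (class \code{threshold_sweep}) with one row per
#'   threshold: edge/node counts, data measures, null mean/sd and the data
#'   value's ensemble quantile per measure.
#' @export
threshold_sweep <- function(corr, p_grid = seq(0.005, 0.1, by = 0.005),
                            n_null = 1000, seed = NULL,
                            measures = c("transitivity", "assortativity",
                                         "small_worldness"),
                            n_random = 100, swaps_per_edge = 10) {
  stopifnot(inherits(corr, "group_correlation_matrix"))
  assert_that(length(p_grid) > 0, "threshold grid is empty")
  sub_seeds <- if (is.null(seed)) rep(list(NULL), length(p_grid)) else
    as.list(seed + seq_along(p_grid))
  rows <- lapply(seq_along(p_grid), function(i) {
    p_thresh <- p_grid[i]
    net <- threshold_network(corr, p_thresh)
    base <- data.frame(group = corr$group, threshold_p = p_thresh,
                       n_active_nodes = length(active_nodes(net)),
                       n_edges = n_edges(net), stringsAsFactors = FALSE)
    for (msr in measures) {
      base[[paste0(msr, "_data")]] <- NA_real_
      base[[paste0(msr, "_null_mean")]] <- NA_real_
      base[[paste0(msr, "_null_sd")]] <- NA_real_
      base[[paste0(msr, "_quantile")]] <- NA_real_
    }
    if (base$n_edges >= 2) {
      ens <- build_null_ensemble(net, n = n_null, seed = sub_seeds[[i]],
                                 measures = measures,
                                 swaps_per_edge = swaps_per_edge,
                                 n_random = n_random)
      for (msr in measures) {
        base[[paste0(msr, "_data")]] <- ens$data_values[[msr]]
        base[[paste0(msr, "_null_mean")]] <-
          mean(ens$replicate_values[, msr], na.rm = TRUE)
        base[[paste0(msr, "_null_sd")]] <-
          stats::sd(ens$replicate_values[, msr], na.rm = TRUE)
        base[[paste0(msr, "_quantile")]] <- ens$quantiles[[msr]]
      }
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("threshold_sweep", "data.frame")
  out
}
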