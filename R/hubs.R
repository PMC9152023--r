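#' Identify hub regions of a network
#'
#' A hub is an active node ranking in the top \code{top_fraction} (default
#' 20\%) for both degree and betweenness. Ranking is over active nodes,
#' descending; the cutoff index is \code{ceiling(top_fraction * N_active)}
#' and nodes tied with the value at the cutoff index qualify, so the result
#' does not depend on node order. A qualifying value must additionally be
#' positive: a node that lies on no shortest path (betweenness 0) is never a
#' hub, even when zeros tie with the cutoff value.
#'
#' @param centrality A \code{\link{centrality_table}}.
#' @param top_fraction Fraction of active nodes forming the top set.
#' @return An object of class \code{hub_set}: the hub region set, the
#'   per-measure cutoff values and ranks, and the active-node count. Empty
#'   networks give an empty hub set.
#' @export
identify_hubs <- function(centrality, top_fraction = 0.2) {
  stopifnot(inherits(centrality, "centrality_table"))
  act <- centrality[centrality$active, , drop = FALSE]
  n_active <- nrow(act)
  if (n_active == 0) {
    return(structure(list(hubs = character(0), top_fraction = top_fraction,
                          n_active = 0L, cutoff_index = 0L,
                          degree_cutoff = NA_real_,
                          betweenness_cutoff = NA_real_),
                     class = "hub_set"))
  }
  k <- ceiling(top_fraction * n_active)
  cutoff_value <- function(x) sort(x, decreasing = TRUE)[k]
  deg_cut <- cutoff_value(act$degree)
  btw_cut <- cutoff_value(act$betweenness)
  qualifies <- function(x, cut) x >= cut & x > 0
  hubs <- act$region[qualifies(act$degree, deg_cut) &
                     qualifies(act$betweenness, btw_cut)]
  structure(
    list(hubs = hubs, top_fraction = top_fraction,
         n_active = n_active, cutoff_index = k,
         degree_cutoff = deg_cut, betweenness_cutoff = btw_cut),
    class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat("<hub_set> top ", 100 * x$top_fraction, "% of ", x$n_active,
      " active nodes (cutoff index ", x$cutoff_index, ")\n  hubs: ",
      if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Hub robustness across pruning thresholds
#'
#' Recomputes the hub set on the base network (p < \code{base_p}) and on 9
#' progressively pruned networks built at stricter p-value thresholds
#' (default 0.005 to 0.045 in steps of 0.005), then counts, per region, at
#' how many of the 10 thresholds it qualified as a hub. Regions that stay
#' hubs as unreliable connections are pruned away are robust hubs.
#'
#' @param corr A \code{group_correlation_matrix}.
#' @param base_p The primary network threshold.
#' @param prune_grid Additional (stricter) thresholds.
#' @param top_fraction Passed to \code{\link{identify_hubs}}.
#' @return An object of class \code{robust_hub_ranking}: a ranking data
#'   frame (region, hub count, rank; ties share a rank), the per-threshold
#'   hub sets, and the thresholds used.
#' @export
hub_robustness <- function(corr, base_p = 0.05,
                           prune_grid = seq(0.005, 0.045, by = 0.005),
                           top_fraction = 0.2) {
  stopifnot(inherits(corr, "group_correlation_matrix"))
  thresholds <- c(base_p, prune_grid)
  hub_sets <- lapply(thresholds, function(p) {
    net <- threshold_network(corr, p)
    identify_hubs(centrality_table(net), top_fraction)
  })
  names(hub_sets) <- sprintf("p<%g", thresholds)
  counts <- stats::setNames(integer(length(corr$region_order)),
                            corr$region_order)
  for (hs in hub_sets) counts[hs$hubs] <- counts[hs$hubs] + 1L
  if (all(counts == 0)) {
    warning("no region qualified as hub at any threshold", call. = FALSE)
  }
  ranking <- data.frame(region = names(counts),
                        hub_count = as.integer(counts),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$hub_count, ranking$region), ]
  ranking$rank <- rank_desc(ranking$hub_count)
  rownames(ranking) <- NULL
  structure(
    list(ranking = ranking, hub_sets = hub_sets, thresholds = thresholds,
         group = corr$group, top_fraction = top_fraction),
    class = "robust_hub_ranking")
}

#' @export
print.robust_hub_ranking <- function(x, ...) {
  cat("<robust_hub_ranking> ", x$group, ", ", length(x$thresholds),
      " thresholds\n", sep = "")
  top <- x$ranking[x$ranking$hub_count > 0, , drop = FALSE]
  print(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}

#' Most robust hub(s) of a ranking
#'
#' Regions attaining the maximum hub count; possibly plural when tied.
#'
#' @param ranking A \code{robust_hub_ranking}.
#' @return Character vector of region acronyms (empty if no hubs at all).
#' @export
top_robust_hubs <- function(ranking) {
  stopifnot(inherits(ranking, "robust_hub_ranking"))
  r <- ranking$ranking
  if (max(r$hub_count) == 0) return(character(0))
  r$region[r$hub_count == max(r$hub_count)]
}

#' Compare hub sets across groups
#'
#' Pairwise intersections and Jaccard indices between the hub sets of
#' different experimental groups.
#'
#' @param hub_sets Named list of \code{hub_set} objects (or character
#'   vectors of hub regions), one per group.
#' @return Data frame with one row per group pair: set sizes, shared hubs,
#'   and Jaccard index.
#' @export
compare_hub_sets <- function(hub_sets) {
  sets <- lapply(hub_sets, function(h) {
    if (inherits(h, "hub_set")) h$hubs else as.character(h)
  })
  groups <- names(sets) %||% paste0("group", seq_along(sets))
  pairs <- utils::combn(seq_along(sets), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    shared <- intersect(a, b)
    uni <- union(a, b)
    data.frame(group_a = groups[ij[1]], group_b = groups[ij[2]],
               n_a = length(a), n_b = length(b), n_shared = length(shared),
               shared = paste(shared, collapse = ";"),
               jaccard = if (length(uni) == 0) NA_real_ else
                 length(shared) / length(uni),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
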