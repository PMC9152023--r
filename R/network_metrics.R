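#' Threshold a correlation matrix into a binary functional network
#'
#' An (undirected, self-loop-free) edge joins two regions iff their Pearson
#' r is positive and its two-tailed p-value is strictly below
#' \code{p_thresh}. Negative and undefined correlations never form edges.
#'
#' @param corr A \code{\link{correlation_matrix}} result.
#' @param p_thresh Significance threshold in (0, 1).
#' @return An object of class \code{functional_network}: binary symmetric
#'   adjacency matrix plus the threshold and group tag that produced it.
#' @export
threshold_network <- function(corr, p_thresh = 0.05) {
  stopifnot(inherits(corr, "group_correlation_matrix"))
  assert_that(is.numeric(p_thresh) && p_thresh > 0 && p_thresh < 1,
              "p_thresh must be in (0, 1)")
  adj <- (corr$r > 0 & corr$p < p_thresh)
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  functional_network(adj * 1L, threshold_p = p_thresh, group = corr$group,
                     region_order = corr$region_order)
}

#' Construct a functional network from an adjacency matrix
#'
#' @param adjacency Binary symmetric matrix with zero diagonal.
#' @param threshold_p The p-value threshold that produced it (or \code{NA}).
#' @param group Group tag.
#' @param region_order Region acronyms (defaults to matrix dimnames).
#' @return A \code{functional_network}.
#' @export
functional_network <- function(adjacency, threshold_p = NA_real_,
                               group = NA_character_,
                               region_order = colnames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  assert_that(nrow(adjacency) == ncol(adjacency), "adjacency must be square")
  assert_that(all(adjacency %in% c(0, 1)), "adjacency must be binary")
  assert_that(all(adjacency == t(adjacency)), "adjacency must be symmetric")
  assert_that(all(diag(adjacency) == 0), "self-loops are not allowed")
  if (is.null(region_order)) {
    region_order <- sprintf("R%03d", seq_len(nrow(adjacency)))
  }
  dimnames(adjacency) <- list(region_order, region_order)
  structure(list(adjacency = adjacency, threshold_p = threshold_p,
                 group = group, region_order = region_order),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat("<functional_network> ", x$group, " p < ", x$threshold_p, ": ",
      length(active_nodes(x)), "/", nrow(x$adjacency), " active nodes, ",
      n_edges(x), " edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(net, active_only = FALSE) {
  stopifnot(inherits(net, "functional_network"))
  adj <- net$adjacency
  if (active_only) {
    keep <- rowSums(adj) > 0
    adj <- adj[keep, keep, drop = FALSE]
  }
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Active nodes and edge count of a network
#'
#' A region is active when it has at least one edge; isolated regions are
#' excluded from centrality normalization and from null-model matching.
#'
#' @param net A \code{functional_network}.
#' @return \code{active_nodes}: character vector of active region acronyms;
#'   \code{n_edges}: integer edge count.
#' @export
active_nodes <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  net$region_order[rowSums(net$adjacency) > 0]
}

#' @rdname active_nodes
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  as.integer(sum(net$adjacency) / 2)
}

#' Node degree
#'
#' @param net A \code{functional_network}.
#' @return Named integer vector over all regions.
#' @export
net_degree <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  stats::setNames(as.integer(rowSums(net$adjacency)), net$region_order)
}

#' Normalized betweenness centrality
#'
#' Fraction of all-pairs shortest paths through each node, computed on the
#' subgraph of active nodes and normalized by \eqn{(N-1)(N-2)/2} with
#' \eqn{N} the number of active nodes. Isolated regions get betweenness 0.
#'
#' @param net A \code{functional_network}.
#' @return Named numeric vector over all regions.
#' @export
net_betweenness <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  out <- stats::setNames(numeric(length(net$region_order)), net$region_order)
  g <- as_igraph(net, active_only = TRUE)
  if (igraph::vcount(g) >= 3) {
    b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    out[names(b)] <- b
  }
  out
}

#' Per-node centrality table with ranks
#'
#' @param net A \code{functional_network}.
#' @return Data frame (class \code{centrality_table}) with degree,
#'   betweenness, descending ranks over active nodes, and an \code{active}
#'   flag.
#' @export
centrality_table <- function(net) {
  deg <- net_degree(net)
  btw <- net_betweenness(net)
  active <- deg > 0
  degree_rank <- rep(NA_integer_, length(deg))
  betweenness_rank <- rep(NA_integer_, length(btw))
  degree_rank[active] <- rank_desc(deg[active])
  betweenness_rank[active] <- rank_desc(btw[active])
  structure(
    data.frame(region = net$region_order, degree = as.integer(deg),
               betweenness = btw, degree_rank = degree_rank,
               betweenness_rank = betweenness_rank, active = active,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("centrality_table", "data.frame"))
}

#' Global graph measures
#'
#' \code{net_transitivity}: global clustering coefficient, 3 x triangles /
#' connected triples (NA when no connected triples exist).
#' \code{net_assortativity}: Pearson correlation of degrees across edge
#' endpoints (NA on degree-regular graphs, where it is undefined).
#' \code{char_path_length}: mean shortest-path length over reachable pairs
#' of active nodes (NA when no pair is reachable); disconnected pairs are
#' excluded rather than counted as infinite.
#'
#' @param net A \code{functional_network}.
#' @return A single numeric value (NA when undefined).
#' @export
net_transitivity <- function(net) {
  g <- as_igraph(net)
  val <- igraph::transitivity(g, type = "global")
  if (is.nan(val)) NA_real_ else val
}

#' @rdname net_transitivity
#' @export
net_assortativity <- function(net) {
  g <- as_igraph(net, active_only = TRUE)
  if (igraph::ecount(g) == 0) return(NA_real_)
  val <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (is.nan(val)) NA_real_ else val
}

#' @rdname net_transitivity
#' @export
char_path_length <- function(net) {
  g <- as_igraph(net, active_only = TRUE)
  if (igraph::vcount(g) < 2) return(NA_real_)
  val <- suppressWarnings(igraph::mean_distance(g, unconnected = TRUE))
  if (is.nan(val) || !is.finite(val)) NA_real_ else val
}

#' Small-worldness against an Erdos-Renyi ensemble
#'
#' \eqn{S = (T / <T_{ER}>) / (L / <L_{ER}>)}: transitivity and
#' characteristic path length, each normalized by its mean over
#' \code{n_random} Erdos-Renyi G(n, m) graphs matched on the data network's
#' active-node and edge counts. Values above 1 indicate clustered yet
#' short-path (small-world) structure. Ensemble means average over the
#' replicates where the measure is defined.
#'
#' @param net A \code{functional_network}.
#' @param n_random Number of random graphs in the normalizing ensemble.
#' @param seed Optional seed for the ensemble draws.
#' @return Small-worldness S (NA if any component is undefined).
#' @export
small_worldness <- function(net, n_random = 100, seed = NULL) {
  stopifnot(inherits(net, "functional_network"))
  t_data <- net_transitivity(net)
  l_data <- char_path_length(net)
  n_act <- length(active_nodes(net))
  m <- n_edges(net)
  if (is.na(t_data) || is.na(l_data) || n_act < 3 || m < 2) return(NA_real_)
  with_seed_opt(seed, {
    t_er <- numeric(n_random)
    l_er <- numeric(n_random)
    for (i in seq_len(n_random)) {
      g <- igraph::sample_gnm(n_act, m)
      tv <- igraph::transitivity(g, type = "global")
      t_er[i] <- if (is.nan(tv)) NA_real_ else tv
      lv <- suppressWarnings(igraph::mean_distance(g, unconnected = TRUE))
      l_er[i] <- if (is.nan(lv) || !is.finite(lv)) NA_real_ else lv
    }
    t_bar <- mean(t_er, na.rm = TRUE)
    l_bar <- mean(l_er, na.rm = TRUE)
    if (!is.finite(t_bar) || !is.finite(l_bar) || t_bar == 0 || l_bar == 0) {
      NA_real_
    } else {
      (t_data / t_bar) / (l_data / l_bar)
    }
  })
}

#' Summary of global network structure
#'
#' @param net A \code{functional_network}.
#' @param n_random Ensemble size for small-worldness.
#' @param seed Optional seed for the small-world ensemble.
#' @return A one-row data frame (class \code{graph_summary}) with
#'   transitivity, assortativity, characteristic path length,
#'   small-worldness, and active-node / edge counts.
#' @export
graph_summary <- function(net, n_random = 100, seed = NULL) {
  structure(
    data.frame(group = net$group, threshold_p = net$threshold_p,
               n_active_nodes = length(active_nodes(net)),
               n_edges = n_edges(net),
               transitivity = net_transitivity(net),
               assortativity = net_assortativity(net),
               char_path_length = char_path_length(net),
               small_worldness = small_worldness(net, n_random, seed),
               stringsAsFactors = FALSE),
    class = c("graph_summary", "data.frame"))
}

#' Export a network
#'
#' @param net A \code{functional_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(as_igraph(net))
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
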