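# Markov clustering (MCL) on the binary adjacency matrix, plus
# Newman-Girvan modularity and modularity-based inflation selection.

#' Markov clustering of a functional network
#'
#' Runs the MCL algorithm on the network's adjacency matrix with unit
#' self-loops: column-normalize the matrix to a random-walk transition
#' matrix, then alternate expansion (matrix squaring) and inflation
#' (elementwise power \code{inflation}, then column renormalization) until
#' the matrix stops changing. Clusters are read from the attractor rows of
#' the limit matrix; a node supported by several attractor systems is
#' assigned to the largest cluster (ties to the lowest cluster index), so
#' the partition is deterministic. Isolated regions come out as singleton
#' clusters.
#'
#' @param net A \code{functional_network}.
#' @param inflation Inflation exponent (> 1). Larger values give finer
#'   clusters.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   iteration count.
#' @param tol Convergence tolerance on the max elementwise change.
#' @param prune Entries below this are zeroed each iteration for stability.
#' @return An object of class \code{cluster_assignment}: named integer
#'   membership over all regions, the inflation used, the Newman-Girvan
#'   modularity of the partition, and the iteration count.
#' @export
markov_cluster <- function(net, inflation = 2, max_iter = 200,
                           tol = 1e-8, prune = 1e-10) {
  stopifnot(inherits(net, "functional_network"))
  assert_that(inflation > 1, "inflation must be > 1")
  n <- nrow(net$adjacency)
  M <- net$adjacency + diag(n)
  M <- sweep(M, 2, colSums(M), "/")

  normalize_cols <- function(A) {
    cs <- colSums(A)
    cs[cs == 0] <- 1
    sweep(A, 2, cs, "/")
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M_new <- M %*% M               # expansion
    M_new <- M_new^inflation       # inflation
    M_new <- normalize_cols(M_new)
    M_new[M_new < prune] <- 0
    M_new <- normalize_cols(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_fosnet("MCL did not converge in ", iter, " iterations",
                " (inflation = ", inflation, ")")
  }

  # Attractors: rows with mass on their own diagonal. Each attractor row's
  # support is a candidate cluster; attractors sharing support belong to one
  # attractor system and are merged.
  thr <- sqrt(prune)
  attractors <- which(diag(M) > thr)
  if (length(attractors) == 0) attractors <- seq_len(n)
  support <- M[attractors, , drop = FALSE] > thr
  # Attractor systems: merge attractor rows that contain each other's
  # attractor node (e.g. periodic attractor pairs). Non-attractor nodes
  # supported by several systems stay contested and are resolved below.
  sys_id <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (i in seq_along(attractors)) {
      for (j in seq_along(attractors)) {
        if (sys_id[i] != sys_id[j] &&
            (support[i, attractors[j]] || support[j, attractors[i]])) {
          sys_id[sys_id == max(sys_id[i], sys_id[j])] <-
            min(sys_id[i], sys_id[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  systems <- unique(sys_id)
  clusters <- lapply(systems, function(s) {
    which(colSums(support[sys_id == s, , drop = FALSE]) > 0)
  })
  sizes <- lengths(clusters)

  membership <- integer(n)
  for (v in seq_len(n)) {
    holding <- which(vapply(clusters, function(cl) v %in% cl, logical(1)))
    if (length(holding) == 0) {
      clusters[[length(clusters) + 1]] <- v
      sizes <- c(sizes, 1L)
      holding <- length(clusters)
    }
    # overlap: largest cluster wins, ties to lowest index
    membership[v] <- holding[order(-sizes[holding], holding)][1]
  }
  membership <- as.integer(factor(membership, levels = unique(membership)))
  names(membership) <- net$region_order
  structure(
    list(membership = membership, inflation = inflation,
         modularity_Q = modularity_q(net, membership),
         n_clusters = length(unique(membership)), iterations = iter),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", x$n_clusters, " clusters, inflation = ",
      x$inflation, ", Q = ", round(x$modularity_Q, 4), "\n", sep = "")
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' \eqn{Q = \sum_c (e_{cc} - a_c^2)} where \eqn{e_{cc}} is the fraction of
#' edges inside community c and \eqn{a_c} the fraction of edge endpoints in
#' c. Lies in [-0.5, 1]; 0 for the one-community partition.
#'
#' @param net A \code{functional_network}.
#' @param membership Integer cluster label per region (named vector or in
#'   region order).
#' @return Modularity Q (NA on an edgeless network).
#' @export
modularity_q <- function(net, membership) {
  stopifnot(inherits(net, "functional_network"))
  adj <- net$adjacency
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  if (!is.null(names(membership))) {
    membership <- membership[net$region_order]
  }
  labels <- unique(membership)
  q <- 0
  deg <- rowSums(adj)
  for (lab in labels) {
    in_c <- membership == lab
    e_cc <- sum(adj[in_c, in_c, drop = FALSE]) / 2 / m
    a_c <- sum(deg[in_c]) / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

#' Select the MCL inflation by maximizing modularity
#'
#' Runs \code{\link{markov_cluster}} at every inflation in \code{grid} and
#' returns the clustering with the highest Newman-Girvan modularity (ties
#' resolved toward the smallest inflation, so selection is deterministic).
#'
#' @param net A \code{functional_network}.
#' @param grid Inflation values to evaluate.
#' @param ... Passed to \code{\link{markov_cluster}}.
#' @return A list with \code{inflation}, \code{assignment} (the winning
#'   \code{cluster_assignment}), and \code{search} (data frame of inflation,
#'   Q, cluster count).
#' @export
select_inflation <- function(net, grid = seq(1.1, 3.0, by = 0.1), ...) {
  assert_that(length(grid) > 0, "inflation grid is empty")
  assert_that(all(grid > 1), "all inflation values must be > 1")
  runs <- lapply(grid, function(infl) markov_cluster(net, infl, ...))
  qs <- vapply(runs, function(x) x$modularity_Q, numeric(1))
  search <- data.frame(
    inflation = grid, modularity_Q = qs,
    n_clusters = vapply(runs, function(x) x$n_clusters, integer(1)))
  if (all(is.na(qs))) {
    best <- 1L
  } else {
    best <- which(qs == max(qs, na.rm = TRUE))[1]
  }
  list(inflation = grid[best], assignment = runs[[best]], search = search)
}

#' Write a cluster assignment as CSV
#'
#' @param assignment A \code{cluster_assignment}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  utils::write.csv(
    data.frame(region = names(assignment$membership),
               cluster = as.integer(assignment$membership),
               inflation = assignment$inflation,
               modularity_Q = assignment$modularity_Q,
               row.names = NULL),
    path, row.names = FALSE)
  invisible(path)
}
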