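# Independent brute-force oracles, kept deliberately separate from (and
# dumber than) the package implementations they check.

# Two-stage aggregation by explicit nested loops over animals, regions and
# sections: hemisphere mean per section, then mean over sections.
oracle_aggregate <- function(records) {
  animals <- sort(unique(records$animal_id))
  regions <- sort(unique(records$region))
  out <- matrix(NA_real_, length(animals), length(regions),
                dimnames = list(animals, regions))
  for (a in animals) {
    for (r in regions) {
      rows <- records[records$animal_id == a & records$region == r, ]
      section_means <- c()
      for (i in seq_len(nrow(rows))) {
        hemis <- c(rows$left_count[i], rows$right_count[i])
        hemis <- hemis[!is.na(hemis)]
        if (length(hemis) > 0) section_means <- c(section_means, mean(hemis))
      }
      if (length(section_means) > 0) out[a, r] <- mean(section_means)
    }
  }
  out
}

# All-pairs shortest-path enumeration by exhaustive simple-path search.
# Returns sigma_st and sigma_st(v) counts; usable up to ~9 nodes.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ] == 1)) {
        if (!(w %in% path)) walk(c(path, w))
      }
    }
    walk(s)
    paths
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in setdiff(1:n, c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + through / sigma
      }
    }
  }
  btw
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) triangles <- triangles + 1
  }
  deg <- rowSums(adj)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(NA_real_)
  3 * triangles / triples
}

# Degree-pair Pearson correlation over both orientations of every edge.
oracle_assortativity <- function(adj) {
  deg <- rowSums(adj)
  xs <- c(); ys <- c()
  n <- nrow(adj)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && adj[i, j] == 1) {
      xs <- c(xs, deg[i]); ys <- c(ys, deg[j])
    }
  }
  if (length(xs) == 0 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(NA_real_)
  }
  stats::cor(xs, ys)
}

# Floyd-Warshall mean shortest path over reachable active-node pairs.
oracle_cpl <- function(adj) {
  active <- which(rowSums(adj) > 0)
  if (length(active) < 2) return(NA_real_)
  a <- adj[active, active, drop = FALSE]
  n <- nrow(a)
  d <- ifelse(a == 1, 1, Inf)
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Newman-Girvan modularity via the per-pair formulation
# Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j).
oracle_modularity <- function(adj, membership) {
  m2 <- sum(adj)
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in 1:n) for (j in 1:n) {
    if (membership[i] == membership[j]) {
      q <- q + adj[i, j] - deg[i] * deg[j] / m2
    }
  }
  unname(q / m2)
}

# Type III two-way ANOVA via explicit design-matrix least squares and
# extra-sum-of-squares F tests under sum-to-zero coding.
oracle_anova_type3 <- function(y, sex, condition) {
  s <- ifelse(sex == "male", 1, -1)
  c_ <- ifelse(condition == "naive", 1, -1)
  X <- cbind(1, s, c_, s * c_)
  fit_ss <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    beta <- solve(crossprod(Xs), crossprod(Xs, y))
    sum((y - Xs %*% beta)^2)
  }
  sse_full <- fit_ss(1:4)
  df_error <- length(y) - 4
  mse <- sse_full / df_error
  f_p <- function(drop_col) {
    ss <- fit_ss(setdiff(1:4, drop_col)) - sse_full
    f <- (ss / 1) / mse
    c(F = f, p = stats::pf(f, 1, df_error, lower.tail = FALSE))
  }
  list(sex = f_p(2), training = f_p(3), interaction = f_p(4),
       mse = mse, df_error = df_error)
}

# Pooled-MSE two-group t (Fisher's LSD) from the raw formula.
oracle_lsd <- function(ya, yb, mse, df_error) {
  t_stat <- (mean(ya) - mean(yb)) /
    sqrt(mse * (1 / length(ya) + 1 / length(yb)))
  c(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df_error))
}

# Greedy matched-representation filter, reimplemented independently.
oracle_filter <- function(values, cutoff = 0.5) {
  while (anyNA(values) && nrow(values) > 0 && ncol(values) > 0) {
    col_frac <- colMeans(is.na(values))
    if (max(col_frac) > cutoff) {
      values <- values[, -which.max(col_frac), drop = FALSE]
    } else {
      values <- values[-which.max(rowSums(is.na(values))), , drop = FALSE]
    }
  }
  values
}
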