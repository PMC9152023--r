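# Small graph and cohort fixtures built in code.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}

net_star <- function(n_leaves = 4) {
  functional_network(
    adj_from_edges(n_leaves + 1, lapply(2:(n_leaves + 1), function(i) c(1, i))))
}

net_cycle <- function(n = 5) {
  functional_network(
    adj_from_edges(n, lapply(1:n, function(i) c(i, i %% n + 1))))
}

net_path <- function(n = 4) {
  functional_network(
    adj_from_edges(n, lapply(1:(n - 1), function(i) c(i, i + 1))))
}

net_complete <- function(n = 5) {
  a <- matrix(1L, n, n); diag(a) <- 0L
  functional_network(a)
}

net_barbell <- function(k = 5) {
  a <- matrix(0L, 2 * k, 2 * k)
  a[1:k, 1:k] <- 1L
  a[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1L
  diag(a) <- 0L
  a[k, k + 1] <- a[k + 1, k] <- 1L
  functional_network(a)
}

# Seeded Erdos-Renyi G(n, p) network as a functional_network.
net_random <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) a[i, j] <- a[j, i] <- 1L
    }
    functional_network(a)
  })
}

# Tiny balanced 2x2 cohort table from explicit per-cell values.
table_2x2 <- function(cells, n_per_cell = 3, region = "RGN") {
  # cells: named list male.naive, female.naive, male.trained, female.trained,
  # each a numeric vector of length n_per_cell
  fac <- do.call(rbind, lapply(names(cells), function(g) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(animal_id = paste0(g, "_", seq_along(cells[[g]])),
               sex = parts[1], condition = parts[2],
               stringsAsFactors = FALSE)
  }))
  values <- matrix(unlist(cells), ncol = 1,
                   dimnames = list(fac$animal_id, region))
  region_count_table(values, fac)
}

# Cohort spec used by recovery tests: large groups, strong clean blocks.
recovery_spec <- function(seed, n_per_group = 50, n_regions = 112) {
  cohort_spec(
    n_per_group = c(male.naive = n_per_group, female.naive = n_per_group,
                    male.trained = n_per_group, female.trained = n_per_group),
    n_regions = n_regions,
    seed = seed)
}

# All-null spec: no effects, no factor structure, independent regions.
null_spec <- function(seed, n_regions = 500) {
  cohort_spec(
    n_regions = n_regions,
    baseline_log_mean = log(50),
    training_effect = 0, sex_effect = 0, interaction_effect = 0,
    factor_loadings = matrix(0, n_regions, 1),
    planted_hubs = integer(0),
    noise_sd = 0.3,
    seed = seed)
}
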