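#' Specify a synthetic c-fos cohort
#'
#' Defines a seeded generative model for animal-by-region c-fos count tables
#' with the structure the downstream analysis assumes: a 2 x 2 design
#' (sex x training), multiplicative regional effects, and group-specific
#' interregional covariance induced by latent per-animal factors. Counts are
#' lognormal: for animal \eqn{a} in group \eqn{g} and region \eqn{r},
#' \deqn{count = exp(mu_r + beta_r I[trained] + s_r I[female] +
#'   gamma_r I[female x trained] + sum_k L^g_{rk} f_{ka} + eps_{ar})}
#' with \eqn{f ~ N(0, 1)} per animal and \eqn{eps ~ N(0, noise_sd^2)}.
#'
#' Defaults mirror a brain-wide threat-conditioning study: four groups with
#' n = 4 (naive) / n = 3 (trained) animals, 112 regions, a training effect in
#' 93 regions, a sex main effect in 5 regions, sex-by-training interactions
#' in 8 regions, five covariance blocks of co-active regions, and two
#' designated hub regions that bridge pairs of blocks by loading on two
#' latent factors each.
#'
#' @param n_per_group Named integer vector of animals per group; names are
#'   \code{"male.naive"}, \code{"female.naive"}, \code{"male.trained"},
#'   \code{"female.trained"}.
#' @param n_regions Number of regions.
#' @param baseline_log_mean Per-region baseline log mean count (recycled).
#' @param training_effect,sex_effect,interaction_effect Per-region log-scale
#'   shifts (recycled to \code{n_regions}).
#' @param factor_loadings Either a regions x K loadings matrix shared by all
#'   groups, or a named list of such matrices, one per group.
#' @param noise_sd Residual log-scale noise standard deviation (> 0).
#' @param planted_hubs Integer indices (or a per-group named list of indices)
#'   of regions planted as bridging hubs; each must load on at least two
#'   factors.
#' @param seed Master seed; all randomness in \code{\link{generate_cohort}}
#'   derives from it.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = c(male.naive = 4, female.naive = 4,
                                        male.trained = 3, female.trained = 3),
                        n_regions = 112,
                        baseline_log_mean = seq(log(20), log(200),
                                                length.out = n_regions),
                        training_effect = default_training_effect(n_regions),
                        sex_effect = default_sex_effect(n_regions),
                        interaction_effect =
                          default_interaction_effect(n_regions),
                        factor_loadings = default_factor_loadings(n_regions),
                        noise_sd = 0.1,
                        planted_hubs = default_planted_hubs(n_regions),
                        seed = 1L) {
  n_per_group <- unlist(n_per_group)
  assert_that(all(group_levels() %in% names(n_per_group)),
              "n_per_group must name all four sex x condition groups")
  assert_that(all(n_per_group >= 2), "all group sizes must be >= 2")
  assert_that(is.numeric(noise_sd) && noise_sd > 0, "noise_sd must be > 0")
  loadings <- if (is.matrix(factor_loadings)) {
    stats::setNames(rep(list(factor_loadings), 4), group_levels())
  } else {
    factor_loadings
  }
  assert_that(all(group_levels() %in% names(loadings)),
              "factor_loadings must cover all four groups")
  for (g in group_levels()) {
    L <- loadings[[g]]
    assert_that(is.matrix(L) && nrow(L) == n_regions && all(is.finite(L)),
                paste0("loadings for ", g,
                       " must be a finite n_regions x K matrix"))
  }
  hubs <- if (is.list(planted_hubs)) planted_hubs else
    stats::setNames(rep(list(planted_hubs), 4), group_levels())
  for (g in group_levels()) {
    for (h in hubs[[g]]) {
      assert_that(sum(abs(loadings[[g]][h, ]) > 0) >= 2,
                  "planted hubs must load on at least two factors")
    }
  }
  spec <- list(
    n_per_group = n_per_group[group_levels()],
    n_regions = n_regions,
    baseline_log_mean = rep_len(baseline_log_mean, n_regions),
    training_effect = rep_len(training_effect, n_regions),
    sex_effect = rep_len(sex_effect, n_regions),
    interaction_effect = rep_len(interaction_effect, n_regions),
    factor_loadings = loadings,
    noise_sd = noise_sd,
    planted_hubs = hubs,
    seed = as.integer(seed),
    region_names = sprintf("R%03d", seq_len(n_regions)))
  structure(spec, class = "cohort_spec")
}

# Default effect layouts: a twofold training increase in 93 of 112 regions
# (scaled proportionally for other region counts), a sex main effect in 5
# regions and a sex-by-training interaction in 8 regions, all placed at fixed
# low indices so planted_truth() is a deterministic readout.
default_training_effect <- function(n_regions) {
  n_hit <- min(n_regions, max(1L, round(n_regions * 93 / 112)))
  eff <- numeric(n_regions)
  eff[seq_len(n_hit)] <- log(2)
  eff
}

default_sex_effect <- function(n_regions) {
  eff <- numeric(n_regions)
  idx <- seq_len(min(5L, n_regions))
  eff[idx] <- log(1.5)
  eff
}

default_interaction_effect <- function(n_regions) {
  eff <- numeric(n_regions)
  idx <- seq_len(min(8L, n_regions))
  eff[idx] <- log(1.5)
  eff
}

# Five equal covariance blocks over the leading regions plus, per hub, a
# smaller satellite block, with the hub regions placed at the end. Each hub
# loads on its home (main-block) factor and on a bridge factor it shares
# with part of its satellite block, so the hub belongs to the large cluster
# while acting as the sole connector to a bordering smaller cluster. The
# hub's edges into both blocks are strong enough to survive strict
# thresholds, giving it top degree and betweenness at every pruning level;
# because the hub reaches only part of the satellite, the satellite remains
# a distinct community and cluster recovery is untouched. When there is no
# room for satellites the hubs fall back to weak loadings on a second main
# factor.
default_factor_loadings <- function(n_regions, n_factors = 5,
                                    block_loading = 0.3,
                                    hub_loading = c(0.4, 0.35),
                                    satellite_size = 12,
                                    bridge_size = 7,
                                    n_hubs = 2) {
  n_satellite <- n_hubs * satellite_size
  if (n_regions >= n_hubs + n_satellite + n_factors) {
    n_block_regions <- n_regions - n_hubs - n_satellite
    K <- n_factors + 2 * n_hubs
    L <- matrix(0, nrow = n_regions, ncol = K)
    block <- sort(rep(seq_len(n_factors), length.out = n_block_regions))
    L[cbind(seq_len(n_block_regions), block)] <- block_loading
    for (h in seq_len(n_hubs)) {
      sat_factor <- n_factors + h
      bridge_factor <- n_factors + n_hubs + h
      sat_idx <- n_block_regions + (h - 1) * satellite_size +
        seq_len(satellite_size)
      L[sat_idx, sat_factor] <- block_loading
      L[sat_idx[seq_len(bridge_size)], bridge_factor] <- block_loading
      home_factor <- ((h - 1) %% n_factors) + 1
      L[n_regions - n_hubs + h, home_factor] <- hub_loading[1]
      L[n_regions - n_hubs + h, bridge_factor] <- hub_loading[2]
    }
    return(L)
  }
  # compact fallback: no satellites, hubs load weakly on a second factor
  if (n_regions < n_factors + n_hubs) {
    n_factors <- max(1L, n_regions - n_hubs)
  }
  n_block_regions <- n_regions - n_hubs
  L <- matrix(0, nrow = n_regions, ncol = n_factors)
  block <- sort(rep(seq_len(n_factors), length.out = n_block_regions))
  L[cbind(seq_len(n_block_regions), block)] <- block_loading
  for (h in seq_len(n_hubs)) {
    f1 <- ((h - 1) %% n_factors) + 1
    f2 <- (h %% n_factors) + 1
    L[n_block_regions + h, f1] <- hub_loading[1]
    L[n_block_regions + h, f2] <- hub_loading[2] * 0.4
  }
  L
}

default_planted_hubs <- function(n_regions, n_hubs = 2) {
  seq.int(n_regions - n_hubs + 1L, n_regions)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_regions, " regions, groups: ",
      paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = ", "),
      "\n  noise_sd = ", x$noise_sd, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort count table
#'
#' Draws a complete animal-by-region count table from a
#' \code{\link{cohort_spec}}. The same spec and seed always produce the
#' identical table.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A \code{\link{region_count_table}} with strictly positive counts.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    rows <- list()
    fac <- list()
    for (g in group_levels()) {
      parts <- strsplit(g, ".", fixed = TRUE)[[1]]
      sex <- parts[1]; condition <- parts[2]
      n <- spec$n_per_group[[g]]
      L <- spec$factor_loadings[[g]]
      K <- ncol(L)
      trained <- as.numeric(condition == "trained")
      female <- as.numeric(sex == "female")
      log_mu <- spec$baseline_log_mean +
        spec$training_effect * trained +
        spec$sex_effect * female +
        spec$interaction_effect * female * trained
      # Per-animal latent factor scores. When the group is large enough the
      # planted identity covariance is realized empirically (exact sample
      # covariance), so recovery tests probe the planted structure rather
      # than chance covariance between nominally independent factors; tiny
      # groups fall back to plain iid draws.
      F_scores <- if (n > K + 1) {
        MASS::mvrnorm(n, mu = rep(0, K), Sigma = diag(K), empirical = TRUE)
      } else {
        matrix(stats::rnorm(n * K), n, K)
      }
      for (a in seq_len(n)) {
        eps <- stats::rnorm(spec$n_regions, sd = spec$noise_sd)
        rows[[length(rows) + 1]] <- exp(log_mu + drop(L %*% F_scores[a, ]) +
                                          eps)
        fac[[length(fac) + 1]] <- data.frame(
          animal_id = sprintf("%s_%s_%d", substr(sex, 1, 1),
                              substr(condition, 1, 1), a),
          sex = sex, condition = condition, stringsAsFactors = FALSE)
      }
    }
    values <- do.call(rbind, rows)
    colnames(values) <- spec$region_names
    region_count_table(values, do.call(rbind, fac))
  })
}

#' Ground truth planted in a cohort spec
#'
#' Deterministic readout of the structure a \code{\link{cohort_spec}} plants:
#' per-region cluster labels (the latent factor with the largest absolute
#' loading; 0 for regions loading on nothing), the hub region set, and
#' per-region flags for training, sex, and interaction effects. Used as
#' ground truth in recovery tests.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param group Group whose loadings define the cluster labels (default
#'   trained males).
#' @return A list with \code{cluster_labels}, \code{hub_regions},
#'   \code{training_regions}, \code{sex_regions}, \code{interaction_regions}.
#' @export
planted_truth <- function(spec, group = "male.trained") {
  stopifnot(inherits(spec, "cohort_spec"))
  L <- spec$factor_loadings[[group]]
  labels <- apply(L, 1, function(row) {
    if (all(row == 0)) 0L else which.max(abs(row))
  })
  names(labels) <- spec$region_names
  list(
    cluster_labels = labels,
    hub_regions = spec$region_names[spec$planted_hubs[[group]]],
    training_regions = spec$region_names[spec$training_effect != 0],
    sex_regions = spec$region_names[spec$sex_effect != 0],
    interaction_regions = spec$region_names[spec$interaction_effect != 0])
}

#' Synthetic region metadata
#'
#' Builds an acronym/name/division table for synthetic regions, cycling
#' through major brain divisions; useful for exercising the ingest
#' validation and division-ordered matrix export on generated data.
#'
#' @param n_regions Number of regions.
#' @return Data frame with columns \code{acronym}, \code{name},
#'   \code{division}.
#' @export
synthetic_region_metadata <- function(n_regions = 112) {
  divisions <- c("isocortex", "olfactory areas", "hippocampal formation",
                 "cortical subplate", "striatum", "pallidum", "thalamus",
                 "hypothalamus", "midbrain", "amygdala")
  acronyms <- sprintf("R%03d", seq_len(n_regions))
  data.frame(
    acronym = acronyms,
    name = paste("synthetic region", seq_len(n_regions)),
    division = rep_len(divisions, n_regions),
    stringsAsFactors = FALSE)
}
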