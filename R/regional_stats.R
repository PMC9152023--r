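#' Two-way (sex x training) ANOVA for one region
#'
#' Between-subjects 2 x 2 ANOVA of per-animal mean counts for a single
#' region, with Type III sums of squares under sum-to-zero factor coding
#' (well-defined for the unbalanced group sizes typical of these cohorts;
#' identical to Type I/II on balanced designs).
#'
#' @param table A complete \code{\link{region_count_table}}.
#' @param region Region acronym (a column of \code{table}).
#' @param ss_type Sum-of-squares type passed to \code{car::Anova}
#'   (\code{3}, the default, or \code{2}).
#' @return An object of class \code{anova_result}: a one-row data frame with
#'   F statistics, p-values, degrees of freedom, the error mean square, and
#'   a \code{degenerate} flag (zero error variance; p-values undefined).
#' @export
two_way_anova <- function(table, region, ss_type = 3) {
  stopifnot(inherits(table, "region_count_table"))
  assert_that(region %in% table$region_order,
              paste0("unknown region: ", region))
  y <- table$values[, region]
  assert_that(!anyNA(y), "region has missing values; run filter_matched first")
  sex <- factor(table$animal_factors$sex, levels = SEXES)
  condition <- factor(table$animal_factors$condition, levels = CONDITIONS)
  cell_n <- table(sex, condition)
  if (any(cell_n == 0)) {
    stop_fosnet("empty design cell for region ", region)
  }
  n <- length(y)
  df_error <- n - 4L

  fit <- stats::lm(y ~ sex * condition,
                   contrasts = list(sex = "contr.sum",
                                    condition = "contr.sum"))
  mse <- sum(stats::residuals(fit)^2) / df_error
  scale_ss <- sum((y - mean(y))^2)
  degenerate <- !is.finite(mse) || mse <= .Machine$double.eps *
    max(scale_ss, 1)

  if (degenerate) {
    Fs <- c(NA_real_, NA_real_, NA_real_)
    ps <- c(NA_real_, NA_real_, NA_real_)
  } else {
    aov_tab <- car::Anova(fit, type = ss_type)
    rn <- rownames(aov_tab)
    pick <- function(term) {
      i <- match(term, rn)
      c(aov_tab[i, "F value"], aov_tab[i, "Pr(>F)"])
    }
    tr <- pick("condition"); sx <- pick("sex"); ix <- pick("sex:condition")
    Fs <- c(tr[1], sx[1], ix[1])
    ps <- c(tr[2], sx[2], ix[2])
  }
  structure(
    data.frame(region = region,
               F_training = Fs[1], F_sex = Fs[2], F_interaction = Fs[3],
               p_training = ps[1], p_sex = ps[2], p_interaction = ps[3],
               df_effect = 1L, df_error = df_error, mse = mse,
               degenerate = degenerate, stringsAsFactors = FALSE),
    class = c("anova_result", "data.frame"))
}

#' Fisher's LSD planned contrast between two groups of one region
#'
#' Unadjusted pairwise t-test using the pooled error mean square and error
#' degrees of freedom from the region's two-way ANOVA:
#' \eqn{t = (m_a - m_b) / sqrt(MSE (1/n_a + 1/n_b))}, two-tailed p on
#' \code{df_error}.
#'
#' @param anova An \code{\link{two_way_anova}} result for the same region.
#' @param table The count table the ANOVA was fit on.
#' @param region Region acronym.
#' @param group_a,group_b Length-2 character vectors \code{c(sex, condition)}.
#' @return A one-row data frame (class \code{planned_contrast}) with the mean
#'   difference, t, and p.
#' @export
fishers_lsd <- function(anova, table, region,
                        group_a = c("male", "trained"),
                        group_b = c("female", "trained")) {
  stopifnot(inherits(table, "region_count_table"))
  assert_that(!anova$degenerate,
              "ANOVA is degenerate (zero error variance); LSD undefined")
  fac <- table$animal_factors
  in_group <- function(g) fac$sex == g[1] & fac$condition == g[2]
  ya <- table$values[in_group(group_a), region]
  yb <- table$values[in_group(group_b), region]
  if (length(ya) == 0 || length(yb) == 0) {
    stop_fosnet("empty group in planned contrast for region ", region)
  }
  mean_diff <- mean(ya) - mean(yb)
  se <- sqrt(anova$mse * (1 / length(ya) + 1 / length(yb)))
  t_stat <- mean_diff / se
  p <- 2 * stats::pt(-abs(t_stat), df = anova$df_error)
  structure(
    data.frame(region = region,
               group_a = group_label(group_a[1], group_a[2]),
               group_b = group_label(group_b[1], group_b[2]),
               mean_diff = mean_diff, t = t_stat, p = p,
               df = anova$df_error, stringsAsFactors = FALSE),
    class = c("planned_contrast", "data.frame"))
}

#' Region-wise activation screen
#'
#' Runs the two-way ANOVA over every region and, where requested, the
#' planned trained-male vs trained-female contrast (by default only in
#' regions whose interaction term is significant at \code{alpha}, which is
#' how such contrasts are usually motivated; set
#' \code{gate_contrast_on_interaction = FALSE} to test everywhere).
#'
#' @param table A complete \code{\link{region_count_table}}.
#' @param alpha Region-wise significance level.
#' @param contrast_groups List of two \code{c(sex, condition)} vectors for
#'   the planned comparison.
#' @param gate_contrast_on_interaction Compute the contrast only where
#'   \code{p_interaction < alpha}.
#' @param fdr Add Benjamini-Hochberg adjusted p-value columns
#'   (\code{q_training}, \code{q_sex}, \code{q_interaction}); off by default
#'   since the screen is reported region-wise.
#' @param ss_type Sum-of-squares type (see \code{\link{two_way_anova}}).
#' @return A list (class \code{region_screen}) with \code{anova} (one row
#'   per region), \code{contrasts}, and \code{summary} counts of regions
#'   significant for each effect at \code{alpha}.
#' @export
screen_all_regions <- function(table, alpha = 0.05,
                               contrast_groups = list(c("male", "trained"),
                                                      c("female", "trained")),
                               gate_contrast_on_interaction = TRUE,
                               fdr = FALSE, ss_type = 3) {
  stopifnot(inherits(table, "region_count_table"))
  res <- lapply(table$region_order, function(r)
    two_way_anova(table, r, ss_type = ss_type))
  anova_tab <- do.call(rbind, res)
  rownames(anova_tab) <- NULL
  if (fdr) {
    anova_tab$q_training <- stats::p.adjust(anova_tab$p_training, "BH")
    anova_tab$q_sex <- stats::p.adjust(anova_tab$p_sex, "BH")
    anova_tab$q_interaction <- stats::p.adjust(anova_tab$p_interaction, "BH")
  }
  do_contrast <- !anova_tab$degenerate
  if (gate_contrast_on_interaction) {
    do_contrast <- do_contrast & !is.na(anova_tab$p_interaction) &
      anova_tab$p_interaction < alpha
  }
  contrasts <- lapply(which(do_contrast), function(i) {
    fishers_lsd(res[[i]], table, anova_tab$region[i],
                contrast_groups[[1]], contrast_groups[[2]])
  })
  contrast_tab <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame(region = character(), group_a = character(),
               group_b = character(), mean_diff = numeric(), t = numeric(),
               p = numeric(), df = integer())
  summary <- list(
    n_regions = nrow(anova_tab),
    n_training = sum(anova_tab$p_training < alpha, na.rm = TRUE),
    n_sex = sum(anova_tab$p_sex < alpha, na.rm = TRUE),
    n_interaction = sum(anova_tab$p_interaction < alpha, na.rm = TRUE),
    n_contrast = sum(contrast_tab$p < alpha, na.rm = TRUE),
    alpha = alpha)
  structure(list(anova = anova_tab, contrasts = contrast_tab,
                 summary = summary),
            class = "region_screen")
}

#' @export
print.region_screen <- function(x, ...) {
  s <- x$summary
  cat("<region_screen> ", s$n_regions, " regions at alpha = ", s$alpha,
      "\n  training effect: ", s$n_training,
      "\n  sex effect: ", s$n_sex,
      "\n  sex x training interaction: ", s$n_interaction,
      "\n  planned contrasts significant: ", s$n_contrast, "\n", sep = "")
  invisible(x)
}
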