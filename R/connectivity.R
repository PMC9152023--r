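#' Interregional Pearson correlation matrix for one experimental group
#'
#' Computes the region-by-region Pearson correlation of per-animal mean
#' counts across the animals of one sex x condition group, together with
#' two-tailed p-values from \eqn{t = r sqrt((n-2)/(1-r^2))} on \eqn{n-2}
#' degrees of freedom. Regions with zero variance within the group produce
#' flagged-undefined (\code{NA}) rows/columns, which downstream thresholding
#' treats as non-edges.
#'
#' @param table A complete \code{\link{region_count_table}}.
#' @param group Length-2 character vector \code{c(sex, condition)} or a
#'   \code{"sex.condition"} label.
#' @return An object of class \code{group_correlation_matrix} with elements
#'   \code{group}, \code{n_animals}, \code{r}, \code{p},
#'   \code{region_order}, and \code{undefined_regions}.
#' @export
correlation_matrix <- function(table, group) {
  stopifnot(inherits(table, "region_count_table"))
  if (length(group) == 1) group <- strsplit(group, ".", fixed = TRUE)[[1]]
  fac <- table$animal_factors
  idx <- fac$sex == group[1] & fac$condition == group[2]
  n <- sum(idx)
  if (n < 3) {
    stop_fosnet("group ", group_label(group[1], group[2]), " has n = ", n,
                " < 3 animals; correlation p-values undefined")
  }
  x <- table$values[idx, , drop = FALSE]
  assert_that(!anyNA(x), "table has missing cells; run filter_matched first")
  sds <- apply(x, 2, stats::sd)
  undefined <- colnames(x)[sds == 0]

  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1

  # two-tailed p from the exact t transform; clamp r^2 just under 1 so
  # perfect correlations get p = 0 rather than NaN
  r2 <- pmin(r^2, 1)
  t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, 0))
  p <- 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  p[is.na(r)] <- NA_real_
  diag(p) <- 0
  if (length(undefined)) {
    r[undefined, ] <- NA_real_; r[, undefined] <- NA_real_
    p[undefined, ] <- NA_real_; p[, undefined] <- NA_real_
  }
  structure(
    list(group = group_label(group[1], group[2]),
         n_animals = n, r = r, p = p,
         region_order = colnames(x),
         undefined_regions = undefined),
    class = "group_correlation_matrix")
}

#' @export
print.group_correlation_matrix <- function(x, ...) {
  cat("<group_correlation_matrix> ", x$group, " (n = ", x$n_animals, "), ",
      length(x$region_order), " regions\n", sep = "")
  if (length(x$undefined_regions)) {
    cat("  undefined (zero variance):",
        paste(x$undefined_regions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Critical Pearson r for a two-tailed test
#'
#' Smallest correlation magnitude that is significant at level \code{alpha}
#' with \code{n} paired observations:
#' \eqn{r^* = t^* / sqrt(t^{*2} + n - 2)} with \eqn{t^*} the
#' \eqn{1 - alpha/2} quantile of the t distribution on \eqn{n - 2} df. At
#' the cohort sizes typical of matched c-fos datasets this is steep: about
#' 0.95 for n = 4 and 0.997 for n = 3 at alpha = 0.05.
#'
#' @param n Number of animals (>= 3).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return The critical r in (0, 1).
#' @export
critical_r <- function(n, alpha = 0.05) {
  assert_that(is.numeric(n) && n >= 3, "critical_r requires n >= 3")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  t_star <- stats::qt(1 - alpha / 2, df = n - 2)
  t_star / sqrt(t_star^2 + n - 2)
}

#' Order a correlation matrix by major brain division
#'
#' Reorders the rows/columns of a \code{group_correlation_matrix} so regions
#' from the same major division are adjacent (stable within division),
#' matching the conventional presentation of brain-wide matrices.
#'
#' @param corr A \code{group_correlation_matrix}.
#' @param metadata Region metadata with \code{acronym} and \code{division}.
#' @return The reordered \code{group_correlation_matrix}.
#' @export
order_by_division <- function(corr, metadata) {
  stopifnot(inherits(corr, "group_correlation_matrix"))
  div <- metadata$division[match(corr$region_order, metadata$acronym)]
  assert_that(!anyNA(div), "metadata does not cover all regions")
  ord <- order(factor(div, levels = unique(metadata$division)))
  corr$r <- corr$r[ord, ord]
  corr$p <- corr$p[ord, ord]
  corr$region_order <- corr$region_order[ord]
  corr
}

#' Write correlation matrices as square CSV
#'
#' @param corr A \code{group_correlation_matrix}.
#' @param r_path,p_path Output CSV paths for the r and p matrices.
#' @return Invisibly, the paths written.
#' @export
write_correlation_matrix <- function(corr, r_path, p_path) {
  stopifnot(inherits(corr, "group_correlation_matrix"))
  utils::write.csv(as.data.frame(corr$r), r_path)
  utils::write.csv(as.data.frame(corr$p), p_path)
  invisible(c(r_path, p_path))
}
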