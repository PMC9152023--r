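#' Read long-format raw c-fos count records
#'
#' Reads a long-format CSV of per-section, per-hemisphere c-fos counts. The
#' file must have columns \code{animal_id}, \code{sex}, \code{condition},
#' \code{region}, \code{bregma_mm}, \code{left_count}, \code{right_count}.
#' Either hemisphere count may be empty (missing section on that side).
#'
#' @param path Path to the CSV file.
#' @return A data frame of raw count records, one row per animal x region x
#'   section.
#' @export
read_count_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("animal_id", "sex", "condition", "region", "bregma_mm",
              "left_count", "right_count")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    stop_fosnet("raw count file is missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  rec
}

#' Read a region metadata table
#'
#' @param path CSV with columns \code{acronym}, \code{name}, \code{division}.
#' @return A data frame with unique region acronyms.
#' @export
read_region_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("acronym", "name", "division")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    stop_fosnet("region metadata is missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$acronym)) {
    stop_fosnet("region metadata has duplicated acronyms: ",
                paste(unique(meta$acronym[duplicated(meta$acronym)]),
                      collapse = ", "))
  }
  meta
}

#' Construct an animals-by-regions count table
#'
#' Low-level constructor used by \code{\link{aggregate_counts}} and
#' \code{\link{generate_cohort}}.
#'
#' @param values Numeric matrix, animals in rows, regions in columns. Row
#'   names are animal ids, column names region acronyms.
#' @param animal_factors Data frame with columns \code{animal_id},
#'   \code{sex}, \code{condition}, one row per row of \code{values}.
#' @return An object of class \code{region_count_table}.
#' @export
region_count_table <- function(values, animal_factors) {
  values <- as.matrix(values)
  assert_that(nrow(values) == nrow(animal_factors),
              "values and animal_factors disagree on the number of animals")
  assert_that(!is.null(colnames(values)), "values must have region names")
  assert_that(!anyDuplicated(colnames(values)),
              "region_order has duplicated acronyms")
  assert_that(all(animal_factors$sex %in% SEXES),
              "sex must be 'male' or 'female'")
  assert_that(all(animal_factors$condition %in% CONDITIONS),
              "condition must be 'naive' or 'trained'")
  rownames(values) <- animal_factors$animal_id
  structure(
    list(values = values,
         animal_factors = data.frame(
           animal_id = as.character(animal_factors$animal_id),
           sex = as.character(animal_factors$sex),
           condition = as.character(animal_factors$condition),
           stringsAsFactors = FALSE),
         region_order = colnames(values)),
    class = "region_count_table")
}

#' @export
print.region_count_table <- function(x, ...) {
  grp <- table(group_label(x$animal_factors$sex, x$animal_factors$condition))
  cat("<region_count_table> ", nrow(x$values), " animals x ",
      ncol(x$values), " regions\n", sep = "")
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' Aggregate per-section bilateral counts into per-region animal means
#'
#' For every section (one bregma level of one region in one animal), left and
#' right hemisphere counts are averaged into one section value; when only one
#' hemisphere is available, that side is used. Section values are then
#' averaged into a single value per animal x region. Sections missing both
#' hemispheres contribute nothing.
#'
#' @param records Data frame of raw count records
#'   (see \code{\link{read_count_records}}).
#' @param metadata Optional region metadata; when given, every region acronym
#'   in \code{records} must be present in it.
#' @param bregma_range Allowed anterior-posterior range (mm from bregma) for
#'   section coordinates; records outside it are a validation error.
#' @return A \code{\link{region_count_table}}; cells with no usable sections
#'   are \code{NA} (resolve with \code{\link{filter_matched}}).
#' @export
aggregate_counts <- function(records, metadata = NULL,
                             bregma_range = c(-3.52, 2.80)) {
  if (is.null(records) || nrow(records) == 0) {
    stop_fosnet("no raw count records supplied")
  }
  if (!is.null(metadata)) {
    unknown <- setdiff(unique(records$region), metadata$acronym)
    if (length(unknown) > 0) {
      stop_fosnet("unknown region acronym(s): ",
                  paste(unknown, collapse = ", "))
    }
  }
  bad_bregma <- !is.na(records$bregma_mm) &
    (records$bregma_mm < bregma_range[1] | records$bregma_mm > bregma_range[2])
  if (any(bad_bregma)) {
    stop_fosnet(sum(bad_bregma), " record(s) outside bregma range [",
                bregma_range[1], ", ", bregma_range[2], "] mm")
  }
  counts <- c(records$left_count, records$right_count)
  if (any(counts < 0, na.rm = TRUE)) {
    stop_fosnet("negative c-fos counts in input")
  }

  # Stage 1: hemisphere mean per section.
  section_value <- rowMeans(
    cbind(records$left_count, records$right_count), na.rm = TRUE)
  section_value[is.nan(section_value)] <- NA_real_

  # Stage 2: mean over sections per animal x region.
  keep <- !is.na(section_value)
  agg <- stats::aggregate(
    section_value[keep],
    by = list(animal_id = as.character(records$animal_id[keep]),
              region = as.character(records$region[keep])),
    FUN = mean)

  animals <- sort(unique(as.character(records$animal_id)))
  regions <- if (!is.null(metadata)) {
    intersect(metadata$acronym, unique(records$region))
  } else {
    sort(unique(as.character(records$region)))
  }
  values <- matrix(NA_real_, nrow = length(animals), ncol = length(regions),
                   dimnames = list(animals, regions))
  values[cbind(match(agg$animal_id, animals), match(agg$region, regions))] <-
    agg$x

  fac <- unique(data.frame(animal_id = as.character(records$animal_id),
                           sex = as.character(records$sex),
                           condition = as.character(records$condition),
                           stringsAsFactors = FALSE))
  if (anyDuplicated(fac$animal_id)) {
    stop_fosnet("inconsistent sex/condition labels within an animal")
  }
  fac <- fac[match(animals, fac$animal_id), ]
  region_count_table(values, fac)
}

#' Reduce a count table to a fully matched animals-by-regions subset
#'
#' Regions without matched representation across animals (and animals with
#' missing regions) are removed by greedy deletion until no missing cells
#' remain: at each step, if the most-missing region is absent from more than
#' \code{max_region_missing_frac} of the remaining animals, that region is
#' dropped; otherwise the animal with the most missing regions is dropped.
#' Ties go to the first animal/region in table order, so the result is
#' deterministic.
#'
#' @param table A \code{\link{region_count_table}}, possibly with \code{NA}
#'   cells.
#' @param max_region_missing_frac Fraction of animals that may lack a region
#'   before the region (rather than an animal) is deleted. The default 0.5
#'   drops animals first and sacrifices a region only when it is missing from
#'   most of the cohort.
#' @return A list with elements \code{table} (complete
#'   \code{region_count_table}) and \code{report} (dropped animals/regions
#'   with reasons; serializable as JSON).
#' @export
filter_matched <- function(table, max_region_missing_frac = 0.5) {
  stopifnot(inherits(table, "region_count_table"))
  values <- table$values
  fac <- table$animal_factors
  dropped_animals <- list()
  dropped_regions <- list()

  while (anyNA(values)) {
    if (nrow(values) == 0 || ncol(values) == 0) break
    region_missing <- colMeans(is.na(values))
    worst_region <- which.max(region_missing)
    if (region_missing[worst_region] > max_region_missing_frac) {
      dropped_regions[[length(dropped_regions) + 1]] <- data.frame(
        region = colnames(values)[worst_region],
        n_missing = sum(is.na(values[, worst_region])),
        reason = "lack of matched representation across animals",
        stringsAsFactors = FALSE)
      values <- values[, -worst_region, drop = FALSE]
    } else {
      animal_missing <- rowSums(is.na(values))
      worst_animal <- which.max(animal_missing)
      dropped_animals[[length(dropped_animals) + 1]] <- data.frame(
        animal_id = rownames(values)[worst_animal],
        n_missing = animal_missing[[worst_animal]],
        reason = "missing regions",
        stringsAsFactors = FALSE)
      values <- values[-worst_animal, , drop = FALSE]
      fac <- fac[fac$animal_id %in% rownames(values), , drop = FALSE]
    }
  }
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop_fosnet("no matched subset: filtering removed all animals or regions")
  }
  report <- list(
    dropped_animals = if (length(dropped_animals))
      do.call(rbind, dropped_animals) else
      data.frame(animal_id = character(), n_missing = integer(),
                 reason = character()),
    dropped_regions = if (length(dropped_regions))
      do.call(rbind, dropped_regions) else
      data.frame(region = character(), n_missing = integer(),
                 reason = character()),
    n_animals_kept = nrow(values),
    n_regions_kept = ncol(values))
  list(table = region_count_table(values, fac), report = report)
}

#' Write / read the wide-format analysis table
#'
#' The wide format has one row per animal with \code{animal_id}, \code{sex},
#' \code{condition} columns followed by one column per region.
#'
#' @param table A \code{\link{region_count_table}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "region_count_table"))
  out <- cbind(table$animal_factors,
               as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fac_cols <- c("animal_id", "sex", "condition")
  assert_that(all(fac_cols %in% names(x)),
              "wide table must have animal_id, sex, condition columns")
  values <- as.matrix(x[, setdiff(names(x), fac_cols), drop = FALSE])
  region_count_table(values, x[, fac_cols])
}
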