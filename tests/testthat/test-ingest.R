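make_records <- function(animal_id, region, bregma_mm, left, right,
                         sex = "male", condition = "naive") {
  data.frame(animal_id = animal_id, sex = sex, condition = condition,
             region = region, bregma_mm = bregma_mm,
             left_count = left, right_count = right,
             stringsAsFactors = FALSE)
}

test_that("bilateral counts average within section, then across sections", {
  rec <- make_records("a1", "PL", c(-1.0, -1.3), left = c(4, 10),
                      right = c(6, 10))
  tab <- aggregate_counts(rec)
  expect_equal(unname(tab$values["a1", "PL"]), 7.5)

  # a single hemisphere stands alone when the other is missing
  rec1 <- make_records("a1", "PL", -1.0, left = 8, right = NA)
  expect_equal(unname(aggregate_counts(rec1)$values["a1", "PL"]), 8)

  # both hemispheres missing contributes nothing
  rec2 <- rbind(rec, make_records("a1", "PL", -1.6, left = NA, right = NA))
  expect_equal(unname(aggregate_counts(rec2)$values["a1", "PL"]), 7.5)
})

test_that("aggregation matches the nested-loop two-stage oracle", {
  withr::with_seed(101, {
    rec <- do.call(rbind, lapply(paste0("a", 1:3), function(a) {
      do.call(rbind, lapply(c("PL", "LA"), function(r) {
        make_records(a, r, c(-0.5, -0.8),
                     left = round(runif(2, 0, 40)),
                     right = ifelse(runif(2) < 0.3, NA,
                                    round(runif(2, 0, 40))))
      }))
    }))
  })
  tab <- aggregate_counts(rec)
  expected <- oracle_aggregate(rec)
  expect_equal(tab$values[rownames(expected), colnames(expected)], expected)

  # invariant to record order
  shuffled <- aggregate_counts(rec[rev(seq_len(nrow(rec))), ])
  expect_equal(shuffled$values, tab$values)

  # aggregated values bounded by contributing raw counts
  raw <- c(rec$left_count, rec$right_count)
  expect_true(all(tab$values >= min(raw, na.rm = TRUE), na.rm = TRUE))
  expect_true(all(tab$values <= max(raw, na.rm = TRUE), na.rm = TRUE))
})

test_that("aggregation validates regions, bregma range and counts", {
  rec <- make_records("a1", "XX", -1.0, 4, 6)
  meta <- data.frame(acronym = "PL", name = "prelimbic", division = "iso")
  expect_error(aggregate_counts(rec, meta), "XX")
  expect_error(aggregate_counts(rec[0, ]), "no raw count records")
  expect_error(aggregate_counts(make_records("a1", "PL", -9, 4, 6)),
               "bregma")
  expect_error(aggregate_counts(make_records("a1", "PL", -1, -4, 6)),
               "negative")
})

test_that("matched filtering removes missingness deterministically", {
  # complete table passes through untouched
  spec <- cohort_spec(n_regions = 6, seed = 3,
                      factor_loadings = matrix(0, 6, 2),
                      planted_hubs = integer(0))
  tab <- generate_cohort(spec)
  res <- filter_matched(tab)
  expect_equal(res$table$values, tab$values)
  expect_equal(nrow(res$report$dropped_animals), 0)

  # one animal missing one region, animals-first policy -> 4 x 4
  vals <- matrix(1, 5, 4, dimnames = list(NULL, paste0("R", 1:4)))
  vals[2, 3] <- NA
  fac <- data.frame(animal_id = paste0("a", 1:5),
                    sex = c("male", "male", "male", "female", "female"),
                    condition = c("naive", "naive", "trained", "naive",
                                  "trained"))
  res2 <- filter_matched(region_count_table(vals, fac))
  expect_equal(dim(res2$table$values), c(4, 4))
  expect_equal(res2$report$dropped_animals$animal_id, "a2")

  # random missingness: result complete and equal to independent greedy
  withr::with_seed(7, {
    v <- matrix(rlnorm(8 * 20), 8, 20,
                dimnames = list(paste0("a", 1:8), sprintf("R%02d", 1:20)))
    v[sample(length(v), round(0.1 * length(v)))] <- NA
  })
  fac8 <- data.frame(animal_id = paste0("a", 1:8),
                     sex = rep(c("male", "female"), 4),
                     condition = rep(c("naive", "trained"), each = 4))
  res3 <- filter_matched(region_count_table(v, fac8))
  expect_false(anyNA(res3$table$values))
  expected <- oracle_filter(v)
  expect_equal(res3$table$values, expected)

  # nothing left -> explicit error
  v_all_na <- matrix(NA_real_, 2, 2, dimnames = list(NULL, c("A", "B")))
  fac2 <- data.frame(animal_id = c("x", "y"), sex = c("male", "female"),
                     condition = c("naive", "naive"))
  expect_error(filter_matched(region_count_table(v_all_na, fac2)),
               "no matched subset")
})

test_that("wide-format CSV round-trips a count table", {
  tab <- generate_cohort(cohort_spec(n_regions = 10, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_equal(back$values, tab$values)
  expect_equal(back$animal_factors, tab$animal_factors)
})
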