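test_that("zero-variance regions are flagged degenerate, not errors", {
  tab <- table_2x2(list(male.naive = c(5, 5, 5), female.naive = c(5, 5, 5),
                        male.trained = c(5, 5, 5),
                        female.trained = c(5, 5, 5)))
  res <- two_way_anova(tab, "RGN")
  expect_true(res$degenerate)
  expect_true(is.na(res$p_training))
  expect_error(fishers_lsd(res, tab, "RGN"), "degenerate")
})

test_that("a pure training shift loads on the training term only", {
  base <- c(10, 11, 9)
  tab <- table_2x2(list(male.naive = base, female.naive = base + 0.1,
                        male.trained = base + 20,
                        female.trained = base + 20.1))
  res <- two_way_anova(tab, "RGN")
  expect_gt(res$F_training, 100)
  expect_lt(res$p_training, 0.001)
  expect_lt(res$F_interaction, 1e-6)
})

test_that("Type III ANOVA matches the design-matrix extra-SS oracle", {
  # balanced printed toy table
  cells <- list(male.naive = c(12, 15, 11), female.naive = c(14, 18, 13),
                male.trained = c(25, 28, 31), female.trained = c(36, 42, 39))
  tab <- table_2x2(cells)
  res <- two_way_anova(tab, "RGN")
  orc <- oracle_anova_type3(unlist(cells),
                            tab$animal_factors$sex,
                            tab$animal_factors$condition)
  expect_equal(res$F_training, unname(orc$training["F"]))
  expect_equal(res$p_training, unname(orc$training["p"]))
  expect_equal(res$F_sex, unname(orc$sex["F"]))
  expect_equal(res$F_interaction, unname(orc$interaction["F"]))
  expect_equal(res$p_interaction, unname(orc$interaction["p"]))
  expect_equal(res$mse, orc$mse)
  expect_equal(res$df_error, orc$df_error)

  # unbalanced cells (the paper's regime: n = 3-5) against the same oracle
  cells_u <- list(male.naive = c(12, 15, 11, 13, 16),
                  female.naive = c(14, 18, 13, 15),
                  male.trained = c(25, 28, 31, 27),
                  female.trained = c(36, 42, 39))
  tab_u <- table_2x2(cells_u)
  res_u <- two_way_anova(tab_u, "RGN")
  orc_u <- oracle_anova_type3(unlist(cells_u),
                              tab_u$animal_factors$sex,
                              tab_u$animal_factors$condition)
  expect_equal(res_u$F_training, unname(orc_u$training["F"]))
  expect_equal(res_u$p_sex, unname(orc_u$sex["p"]))
  expect_equal(res_u$F_interaction, unname(orc_u$interaction["F"]))
})

test_that("sum-of-squares types agree on balanced designs", {
  cells <- list(male.naive = c(12, 15, 11), female.naive = c(14, 18, 13),
                male.trained = c(25, 28, 31), female.trained = c(36, 42, 39))
  tab <- table_2x2(cells)
  t3 <- two_way_anova(tab, "RGN", ss_type = 3)
  t2 <- two_way_anova(tab, "RGN", ss_type = 2)
  expect_equal(t3$F_training, t2$F_training)
  expect_equal(t3$F_sex, t2$F_sex)
  expect_equal(t3$F_interaction, t2$F_interaction)
})

test_that("Fisher's LSD reproduces the pooled-MSE t construction", {
  cells <- list(male.naive = c(12, 15, 11), female.naive = c(14, 18, 13),
                male.trained = c(25, 28, 31), female.trained = c(36, 42, 39))
  tab <- table_2x2(cells)
  res <- two_way_anova(tab, "RGN")
  lsd <- fishers_lsd(res, tab, "RGN")
  orc <- oracle_lsd(cells$male.trained, cells$female.trained,
                    res$mse, res$df_error)
  expect_equal(lsd$t, unname(orc["t"]))
  expect_equal(lsd$p, unname(orc["p"]))

  # identical group means: t = 0, p = 1
  lsd0 <- fishers_lsd(res, tab, "RGN",
                      group_a = c("male", "naive"),
                      group_b = c("male", "naive"))
  expect_equal(lsd0$t, 0)
  expect_equal(lsd0$p, 1)

  # unit construction: difference equal to its standard error gives t = 1
  se <- sqrt(res$mse * (1 / 3 + 1 / 3))
  cells1 <- cells
  cells1$male.trained <- cells$female.trained + se
  tab1 <- table_2x2(cells1)
  res1 <- two_way_anova(tab1, "RGN")
  lsd1 <- fishers_lsd(res1, tab1, "RGN")
  expect_equal(lsd1$t, se / sqrt(res1$mse * (2 / 3)))
})

test_that("the region screen is order-invariant and gates contrasts", {
  spec <- cohort_spec(n_regions = 12, seed = 41,
                      factor_loadings = matrix(0, 12, 1),
                      planted_hubs = integer(0))
  tab <- generate_cohort(spec)
  scr <- screen_all_regions(tab)
  expect_equal(nrow(scr$anova), 12)
  expect_true(all(scr$contrasts$region %in%
                    scr$anova$region[scr$anova$p_interaction < 0.05]))

  # permute animals and regions: identical statistics
  perm_a <- rev(seq_len(nrow(tab$values)))
  perm_r <- c(5:12, 1:4)
  tab_p <- region_count_table(tab$values[perm_a, perm_r],
                              tab$animal_factors[perm_a, ])
  scr_p <- screen_all_regions(tab_p)
  reord <- match(scr$anova$region, scr_p$anova$region)
  expect_equal(scr_p$anova$F_training[reord], scr$anova$F_training)
  expect_equal(scr_p$anova$p_interaction[reord], scr$anova$p_interaction)

  # ungated screen tests the contrast everywhere; FDR columns on request
  scr_all <- screen_all_regions(tab, gate_contrast_on_interaction = FALSE,
                                fdr = TRUE)
  expect_equal(nrow(scr_all$contrasts), 12)
  expect_true(all(c("q_training", "q_sex", "q_interaction") %in%
                    names(scr_all$anova)))
  expect_true(all(scr_all$anova$q_training >= scr_all$anova$p_training))
})

test_that("a planted training effect is recovered region-wise", {
  # raw-scale ANOVA on lognormal counts with shared animal factors: the
  # twofold planted effect is detectable in most but not all regions
  spec <- recovery_spec(seed = 51, n_regions = 30)
  tab <- generate_cohort(spec)
  truth <- planted_truth(spec)
  scr <- screen_all_regions(tab)
  hit <- scr$anova$region %in% truth$training_regions
  expect_gte(mean(scr$anova$p_training[hit] < 0.05), 0.6)
  # and planted-null regions stay mostly null
  expect_lte(mean(scr$anova$p_training[!hit] < 0.05), 0.3)
})
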