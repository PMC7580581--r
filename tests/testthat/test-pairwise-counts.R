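test_that("pairwise PERMANOVAs enumerate pairs and Bonferroni-correct", {
  ds <- generate_dataset(study_preset("six_colony", seed = 4))
  pre <- preprocess_pipeline(ds)
  D <- bray_curtis(pre$abundance)
  pw <- pairwise_permanova(D, pre$metadata, "colony", permutations = 49,
                           seed = 2)
  expect_equal(nrow(pw), choose(6, 2))  # 15 pairs from six colonies
  expect_equal(pw$p_corrected, pmin(1, pw$p * 15))
  expect_true(all(pw$F > 0))
  expect_true(all(pw$R2 > 0 & pw$R2 < 1))
  # each row matches a one-way fit on the subset
  g <- pre$metadata$colony
  idx <- which(g %in% c(pw$group1[1], pw$group2[1]))
  ora <- permanova_oneway(D[idx, idx], g[idx])
  expect_equal(pw$F[1], ora$F, tolerance = 1e-10)
  expect_equal(pw$R2[1], ora$R2, tolerance = 1e-10)
})

test_that("two levels mean the correction is the identity", {
  x <- log_transform(to_relative_abundance(rand_abundance(12, 15, 3)))
  D <- bray_curtis(x)
  g <- rep(c("a", "b"), each = 6)
  pw <- pairwise_permanova(D, grouping = g, permutations = 99, seed = 1)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$p_corrected, pw$p)
})

test_that("composite groupings and undersized levels are handled", {
  ds <- generate_dataset(synthetic_config(families_per_colony = 4, seed = 8))
  pre <- preprocess_pipeline(ds)
  D <- bray_curtis(pre$abundance)
  # colony x age gives the four mother/pup-by-colony strata
  pw <- pairwise_permanova(D, pre$metadata, c("colony", "age_class"),
                           permutations = 49, seed = 5)
  expect_equal(nrow(pw), choose(4, 2))
  # a level with one sample is skipped with a note
  g <- c("solo", rep(c("a", "b"), c(7, 8)))
  expect_message(
    pws <- pairwise_permanova(D, grouping = g, permutations = 49, seed = 1),
    "skipping")
  expect_equal(nrow(pws), 1)
  expect_equal(length(attr(pws, "skipped")), 2)
  # correction count is the number of tests actually emitted
  expect_equal(pws$p_corrected, pws$p)
})

test_that("compound-count comparisons reproduce hand-computed statistics", {
  r <- compare_counts(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                      test = "t_test")
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.021312, tolerance = 1e-4)

  same <- compare_counts(rep(c(3, 4, 5), 2), rep(c("a", "b"), each = 3),
                         test = "t_test")
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # two-group ANOVA F equals t squared
  counts <- c(10, 12, 15, 11, 20, 22, 19, 23)
  g <- rep(c("a", "b"), each = 4)
  tt <- compare_counts(counts, g, "t_test")
  ff <- compare_counts(counts, g, "anova")
  expect_equal(ff$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(ff$df, c(1, 6))

  expect_error(compare_counts(counts, rep(c("a", "b", "c"), c(3, 3, 2)),
                              "t_test"), "exactly two")
  expect_error(compare_counts(c(1, 2, 3), c("a", "a", "b"), "t_test"),
               "at least two samples")
})

test_that("count tests run on generated fingerprints", {
  ds <- generate_dataset(study_preset("replication", seed = 31))
  counts <- compound_counts(ds$abundance)
  r <- compare_counts(counts, ds$metadata$age_class, "t_test")
  expect_true(is.finite(r$statistic))
  six <- generate_dataset(study_preset("six_colony", seed = 32))
  ra <- compare_counts(compound_counts(six$abundance), six$metadata$colony,
                       "anova")
  expect_equal(ra$df[1], 5)
  expect_equal(ra$df[2], 104)
})
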