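make_preprocessed <- function(seed, families = 15) {
  ds <- generate_dataset(study_preset("replication", seed = seed,
                                      families_per_colony = families,
                                      n_twin_families = 0))
  preprocess_pipeline(ds)
}

test_that("bootstrap replicates are reproducible and well-formed", {
  pre <- make_preprocessed(61, families = 6)
  b1 <- bootstrap_effect_sizes(pre, pairs_per_colony = 4, replicates = 5,
                               seed = 7)
  b2 <- bootstrap_effect_sizes(pre, pairs_per_colony = 4, replicates = 5,
                               seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$full, b2$full)
  expect_true(all(b1$replicates >= 0 & b1$replicates <= 1))
  expect_equal(colnames(b1$replicates),
               c("colony", "family_id %in% colony"))
})

test_that("resampling with few families (forced duplicates) stays stable", {
  # two families per colony, 15 draws: heavy duplication guaranteed;
  # duplicated samples sit at distance zero and the family term's df is
  # unchanged because every copy gets a fresh label
  pre <- make_preprocessed(62, families = 2)
  b <- bootstrap_effect_sizes(pre, pairs_per_colony = 15, replicates = 3,
                              seed = 1)
  expect_true(all(is.finite(b$replicates)))
  expect_true(all(b$replicates >= 0 & b$replicates <= 1))
})

test_that("bootstrap validates its inputs", {
  ds <- generate_dataset(study_preset("replication", seed = 63,
                                      families_per_colony = 4,
                                      n_twin_families = 0))
  expect_error(bootstrap_effect_sizes(ds), "log_relative")
  pre <- preprocess_pipeline(ds)
  expect_error(bootstrap_effect_sizes(pre, focal = "nope"), "subset")
  six <- preprocess_pipeline(generate_dataset(study_preset("six_colony",
                                                           seed = 64)))
  expect_error(bootstrap_effect_sizes(six), "exactly 2 colonies")
})

test_that("replicate analyses never mutate the input dataset", {
  pre <- make_preprocessed(65, families = 5)
  before <- unclass(pre$abundance)
  md_before <- pre$metadata
  invisible(bootstrap_effect_sizes(pre, pairs_per_colony = 3,
                                   replicates = 4, seed = 2))
  expect_identical(unclass(pre$abundance), before)
  expect_identical(pre$metadata, md_before)
})

test_that("null colony signal keeps bootstrap R2 near its df-driven floor", {
  ds <- generate_dataset(study_preset("replication", seed = 66,
                                      families_per_colony = 15,
                                      n_twin_families = 0,
                                      sigma_colony = 0))
  pre <- preprocess_pipeline(ds)
  b <- bootstrap_effect_sizes(pre, pairs_per_colony = 15,
                              replicates = 200, seed = 3)
  r2 <- b$replicates[, "colony"]
  expect_true(all(r2 < 0.15))
  # sequential one-df colony term: null expectation ~ df/(n-1) of the
  # post-age remainder; with n = 60 that is about 1/59
  expect_lt(abs(max_density_estimate(r2) - 1 / 59), 0.05)
})

test_that("more pairs per replicate shrink the R2 sampling spread", {
  pre <- make_preprocessed(67, families = 15)
  b8 <- bootstrap_effect_sizes(pre, pairs_per_colony = 8,
                               replicates = 300, seed = 4)
  b15 <- bootstrap_effect_sizes(pre, pairs_per_colony = 15,
                                replicates = 300, seed = 5)
  iqr <- function(x) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  expect_lt(iqr(b15$replicates[, "colony"]), iqr(b8$replicates[, "colony"]))
})

test_that("maximum-density estimate finds the mode", {
  expect_equal(max_density_estimate(rep(0.1, 20)), 0.1)
  set.seed(10)
  x <- rnorm(5000, mean = 0.12, sd = 0.02)
  expect_lt(abs(max_density_estimate(x) - 0.12), 0.005)
  # bimodal: returns the taller mode, not the mean
  y <- c(rnorm(3000, 0.3, 0.01), rnorm(1000, 0.7, 0.01))
  expect_lt(abs(max_density_estimate(y) - 0.3), 0.02)
  expect_error(max_density_estimate(c(1, 2, 3)), "at least 10")
})

test_that("bootstrap summaries are recomputable from the replicates", {
  pre <- make_preprocessed(68, families = 5)
  b <- bootstrap_effect_sizes(pre, pairs_per_colony = 5, replicates = 40,
                              seed = 6)
  s <- summarize_bootstrap(b)
  x <- b$replicates[, "colony"]
  expect_equal(s$median[1], stats::median(x))
  expect_equal(s$q2.5[1],
               stats::quantile(x, 0.025, names = FALSE, type = 7))
  expect_equal(s$max_density[1], max_density_estimate(x))
  expect_gte(s$whisker_low[1], min(x))
  expect_lte(s$whisker_high[1], max(x))
  expect_equal(s$full_R2[1], unname(b$full["colony"]))
})
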