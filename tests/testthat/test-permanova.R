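test_that("Gower centring matches hand computations", {
  D2 <- distance_matrix(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(gower_center(D2),
               matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # trace identity and zero row sums on a random instance
  D <- euclid_D(matrix(rnorm(18), 6, 3))
  G <- gower_center(D)
  d2 <- unclass(D)^2
  expect_equal(sum(diag(G)), sum(d2[lower.tri(d2)]) / 6, tolerance = 1e-10)
  expect_equal(rowSums(G), rep(0, 6), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(G, t(G), tolerance = 1e-12)
  # all-zero distances centre to the zero matrix
  expect_equal(gower_center(distance_matrix(matrix(0, 3, 3))),
               matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("the 4-point instance gives the exact hand-worked decomposition", {
  D <- euclid_D(cbind(c(0, 1, 10, 11)))
  md <- data.frame(group = c("g1", "g1", "g2", "g2"))
  fit <- permanova(D, md, "group", permutations = 0)
  expect_equal(fit$SS[3], 101, tolerance = 1e-10)   # total
  expect_equal(fit$SS[1], 100, tolerance = 1e-10)   # between
  expect_equal(fit$F[1], 200, tolerance = 1e-10)
  expect_equal(fit$R2[1], 100 / 101, tolerance = 1e-12)
})

test_that("projection-based fit equals the direct group-sum identity", {
  set.seed(2024)
  for (i in 1:50) {
    n <- sample(8:16, 1)
    a <- sample(2:4, 1)
    groups <- sample(letters[1:a], n, replace = TRUE)
    while (length(unique(groups)) < a) groups <- sample(letters[1:a], n,
                                                        replace = TRUE)
    D <- if (i %% 2 == 0) euclid_D(matrix(rnorm(n * 3), n, 3))
         else bray_curtis(matrix(runif(n * 6), n, 6,
                                 dimnames = list(sprintf("s%d", 1:n),
                                                 sprintf("c%d", 1:6))),
                          force = TRUE)
    fit <- permanova(D, data.frame(group = groups), "group",
                     permutations = 0)
    ora <- permanova_oneway(D, groups)
    expect_equal(fit$F[1], ora$F, tolerance = 1e-8)
    expect_equal(fit$R2[1], ora$R2, tolerance = 1e-8)
    expect_equal(fit$SS[1], ora$SS_between, tolerance = 1e-8)
  }
  # degenerate cases of the direct route
  D <- euclid_D(matrix(rnorm(12), 6, 2))
  expect_error(permanova_oneway(D, rep("a", 6)), "at least two groups")
  same <- euclid_D(rbind(diag(2), diag(2)))
  ora0 <- permanova_oneway(same, c("a", "a", "b", "b"))
  expect_equal(ora0$SS_between, 0, tolerance = 1e-10)
  expect_equal(ora0$F, 0, tolerance = 1e-10)
})

test_that("sequential SS decomposition is exact for the nested model", {
  ds <- generate_dataset(study_preset("replication", seed = 13))
  pre <- preprocess_pipeline(ds)
  D <- bray_curtis(pre$abundance)
  fit <- permanova(D, pre$metadata,
                   c("age_class", "colony", "family_id %in% colony"),
                   permutations = 0)
  ss_terms <- sum(fit$SS[fit$term != "Total"])
  expect_equal(ss_terms, fit$SS[fit$term == "Total"],
               tolerance = 1e-8 * abs(fit$SS[fit$term == "Total"]))
  expect_equal(sum(fit$R2[fit$term != "Total"]), 1, tolerance = 1e-8)
  expect_equal(sum(fit$df), 2 * (nrow(pre$abundance) - 1))
  # nested df accounting: families minus colonies
  expect_equal(fit$df[fit$term == "family_id %in% colony"],
               length(unique(pre$metadata$family_id)) - 2)
})

test_that("nested sequential fit agrees with the reference implementation", {
  skip_if_not_installed("vegan")
  ds <- generate_dataset(study_preset("original", seed = 5))
  pre <- preprocess_pipeline(ds)
  D <- bray_curtis(pre$abundance)
  fit <- permanova(D, pre$metadata,
                   c("age_class", "colony", "family_id %in% colony"),
                   permutations = 0)
  md <- pre$metadata
  md$age_class <- factor(md$age_class)
  md$colony <- factor(md$colony)
  md$family_id <- factor(md$family_id)
  ref <- vegan::adonis2(stats::as.dist(unclass(D)) ~
                          age_class + colony + colony:family_id,
                        data = md, permutations = 0, by = "terms")
  expect_equal(fit$SS[1:4], ref$SumOfSqs[1:4], tolerance = 1e-9)
  expect_equal(fit$F[1:3], ref$F[1:3], tolerance = 1e-9)
  expect_equal(fit$R2[1:3], ref$R2[1:3], tolerance = 1e-9)
  expect_equal(fit$df[1:4], ref$Df[1:4])
})

test_that("statistics are equivariant under joint sample reordering", {
  ds <- generate_dataset(synthetic_config(families_per_colony = 6, seed = 3))
  pre <- preprocess_pipeline(ds)
  D <- bray_curtis(pre$abundance)
  terms <- c("age_class", "colony", "family_id %in% colony")
  fit <- permanova(D, pre$metadata, terms, permutations = 0)
  set.seed(1)
  perm <- sample(nrow(pre$abundance))
  fitp <- permanova(D[perm, perm], pre$metadata[perm, ], terms,
                    permutations = 0)
  expect_equal(fit$SS, fitp$SS, tolerance = 1e-10)
  expect_equal(fit$F, fitp$F, tolerance = 1e-10)
  # and invariant to order-preserving relabeling of the groups
  md2 <- pre$metadata
  md2$colony <- ifelse(md2$colony == "SSB", "zz_1", "zz_2")
  fit2 <- permanova(D, md2, terms, permutations = 99, seed = 4)
  fit1 <- permanova(D, pre$metadata, terms, permutations = 99, seed = 4)
  expect_equal(fit1$F, fit2$F, tolerance = 1e-12)
  expect_equal(fit1$p, fit2$p)
})

test_that("permutation p-values follow the add-one convention", {
  expect_equal(permutation_pvalue(10, rep(1, 99)), 1 / 100)
  expect_equal(permutation_pvalue(0, 1:99), 1)
  # ties count toward the numerator
  expect_equal(permutation_pvalue(5, c(5, 1, 1, 1)), 2 / 5)
  expect_error(permutation_pvalue(1, numeric(0)), "non-empty")
})

test_that("small samples fall back to exhaustive enumeration", {
  D <- euclid_D(cbind(c(0, 1, 10, 11)))
  md <- data.frame(group = c("g1", "g1", "g2", "g2"))
  expect_message(
    fit <- permanova(D, md, "group", permutations = 9999, seed = 1),
    "exhaustive")
  expect_identical(attr(fit, "permutation_mode"), "exhaustive")
  # independent enumeration over all 4! orderings via the direct oracle
  perms <- scentR:::all_permutations(4)
  Fs <- apply(perms, 1, function(p)
    permanova_oneway(D[p, p], md$group)$F)
  expect_equal(fit$p[1], mean(Fs >= fit$F[1]))
  expect_equal(fit$p[1], 1 / 3)  # 8 of 24 orderings preserve the split
})

test_that("seeded permutation tests are reproducible", {
  ds <- generate_dataset(synthetic_config(families_per_colony = 5, seed = 6))
  pre <- preprocess_pipeline(ds)
  D <- bray_curtis(pre$abundance)
  f1 <- permanova(D, pre$metadata, "colony", permutations = 199, seed = 11)
  f2 <- permanova(D, pre$metadata, "colony", permutations = 199, seed = 11)
  expect_identical(f1$p, f2$p)
})

test_that("inestimable and misaligned models are rejected", {
  D <- euclid_D(matrix(rnorm(12), 6, 2))
  md <- data.frame(g = rep("same", 6), h = c("a", "a", "a", "b", "b", "b"))
  expect_error(permanova(D, md, "g", permutations = 0), "not estimable")
  expect_error(permanova(D, md[1:3, , drop = FALSE], "h",
                         permutations = 0), "not aligned")
  expect_error(permanova(D, md, "nope", permutations = 0), "no column")
})
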