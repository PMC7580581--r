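test_that("PCoA recovers coordinates on a line and conserves the trace", {
  D <- euclid_D(cbind(c(0, 3, 7)))
  p <- pcoa(D)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-9)
  expect_equal(ncol(p$real_axes), 1)
  expect_null(p$imaginary_axes)
  # reconstructed pairwise distances match the input
  rec <- as.matrix(stats::dist(p$real_axes))
  expect_equal(rec, unclass(D), tolerance = 1e-8, ignore_attr = TRUE)
  # axes are centred
  expect_equal(colMeans(p$real_axes), 0, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCoA handles duplicates and k-dimensional data", {
  X <- rbind(c(0, 0), c(1, 1), c(1, 1), c(3, 0))
  p <- pcoa(euclid_D(X))
  expect_equal(max(abs(p$real_axes[2, ] - p$real_axes[3, ])), 0,
               tolerance = 1e-8)
  # points in 2 dimensions give at most 2 positive eigenvalues
  set.seed(9)
  Y <- matrix(rnorm(20), 10, 2)
  py <- pcoa(euclid_D(Y))
  expect_lte(ncol(py$real_axes), 2)
  expect_equal(sum(py$eigenvalues), py$trace, tolerance = 1e-9)
  expect_error(pcoa(distance_matrix(matrix(0, 1, 1))), "at least two")
})

test_that("PCoA reports negative eigenvalues for non-Euclidean input", {
  x <- log_transform(to_relative_abundance(rand_abundance(12, 18, 5,
                                                          sparsity = 0.6)))
  p <- pcoa(bray_curtis(x))
  expect_true(min(p$eigenvalues) < 0)
  expect_gt(ncol(p$imaginary_axes), 0)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-9)
})

test_that("monotone regression pools adjacent violators (primary ties)", {
  # hand-run PAVA: sequence 1, 3, 2 pools the violating pair to 2.5
  fit <- scentR:::monotone_fit(dissim = c(1, 2, 3), confdist = c(1, 3, 2))
  expect_equal(fit, c(1, 2.5, 2.5))
  # tied dissimilarities impose no order constraint: within the tie the
  # fit follows the configuration distances unchanged
  fit2 <- scentR:::monotone_fit(dissim = c(1, 1, 1), confdist = c(3, 1, 2))
  expect_equal(fit2, c(3, 1, 2))
})

test_that("NMDS embeds exactly 2-dimensional distances at ~zero stress", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  D <- euclid_D(square)
  fit <- nmds(D, k = 2, restarts = 5, seed = 1)
  expect_lt(fit$stress, 1e-4)
  expect_true(fit$converged)
  # stress recomputes from the returned coordinates
  expect_equal(nmds_stress(fit$points, D), fit$stress, tolerance = 1e-8)
  # rms inter-point distance normalised to 1
  cd <- as.matrix(stats::dist(fit$points))
  expect_equal(sqrt(mean(cd[lower.tri(cd)]^2)), 1, tolerance = 1e-8)
})

test_that("NMDS stress is rank-invariant and per-iteration non-increasing", {
  set.seed(14)
  X <- matrix(rnorm(24), 12, 2)
  D <- euclid_D(X)
  f1 <- nmds(D, k = 2, restarts = 4, seed = 2)
  # strictly increasing transform of the distances preserves ranks
  D2 <- distance_matrix(unclass(D)^1.5)
  f2 <- nmds(D2, k = 2, restarts = 4, seed = 2)
  expect_lt(abs(f1$stress - f2$stress), 1e-4)
  expect_true(all(diff(f1$stress_trace) <= 1e-12))
  expect_true(all(diff(f2$stress_trace) <= 1e-12))
})

test_that("NMDS is deterministic given a seed and validates inputs", {
  x <- log_transform(to_relative_abundance(rand_abundance(10, 16, 77)))
  D <- bray_curtis(x)
  a <- nmds(D, restarts = 3, seed = 5)
  b <- nmds(D, restarts = 3, seed = 5)
  expect_identical(a$points, b$points)
  expect_identical(a$stress, b$stress)
  expect_true(all(a$restart_stresses >= a$stress - 1e-12))
  expect_error(nmds(D, k = 9), "requires more than")
  allsame <- distance_matrix(matrix(1, 4, 4) - diag(4))
  expect_error(nmds(allsame, k = 2), "degenerate ranks")
})

test_that("stress is invariant under rotation/reflection and bounded", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  D <- euclid_D(matrix(rnorm(30), 10, 3))
  s <- nmds_stress(X, D)
  expect_gte(s, 0)
  expect_lte(s, 1)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(nmds_stress(X %*% R, D), s, tolerance = 1e-10)
  expect_equal(nmds_stress(X %*% diag(c(-1, 1)), D), s, tolerance = 1e-10)
  # perfect configuration has zero stress
  expect_lt(nmds_stress(as.matrix(X), euclid_D(X)), 1e-9)
})
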