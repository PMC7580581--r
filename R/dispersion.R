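# Multivariate homogeneity of group dispersions.
#
# A significant PERMANOVA can reflect differences in group location
# (centroids) or in group spread. This test isolates the spread
# component: samples are embedded by principal coordinates, each
# sample's distance to its own group centre is computed - subtracting
# the squared contribution of the "imaginary" axes that arise from
# non-Euclidean dissimilarities such as Bray-Curtis - and a one-way
# ANOVA asks whether mean distances differ among groups.

#' Test for homogeneity of multivariate group dispersions
#'
#' @param D a [distance_matrix()].
#' @param groups grouping vector/factor aligned to `D`; every group
#'   needs at least two samples.
#' @param center `"centroid"` (group mean in principal-coordinate
#'   space) or `"spatial_median"` (minimiser of the summed distances,
#'   found numerically).
#' @param p_mode `"classical_F"` for the F-distribution p-value of the
#'   one-way ANOVA on the distances, or `"permutation"` for a
#'   label-permutation p-value of the same F statistic.
#' @param permutations,seed used when `p_mode = "permutation"`.
#' @return a `dispersion_test` list: per-sample `distances`,
#'   `group_means`, `F`, `df`, `p`, and `n_clamped` (number of negative
#'   squared distances clamped to zero by the imaginary-axis
#'   correction).
#' @export
dispersion_test <- function(D, groups,
                            center = c("centroid", "spatial_median"),
                            p_mode = c("classical_F", "permutation"),
                            permutations = 999, seed = NULL) {
  center <- match.arg(center)
  p_mode <- match.arg(p_mode)
  D <- distance_matrix(as.matrix(D))
  n <- nrow(D)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n) stopf("`groups` is not aligned to D")
  if (nlevels(groups) < 2L) stopf("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stopf("group '%s' has fewer than two samples; its dispersion is undefined",
          names(sizes)[sizes < 2L][1])

  pc <- pcoa(D)
  A <- pc$real_axes
  B <- pc$imaginary_axes
  if (is.null(B)) B <- matrix(0, n, 0)

  dist_to_center <- function(g) {
    idx <- which(groups == g)
    Ar <- A[idx, , drop = FALSE]
    Br <- B[idx, , drop = FALSE]
    ctr <- group_center(Ar, Br, center)
    z2 <- rowSums(sweep(Ar, 2, ctr$real)^2)
    if (ncol(Br)) z2 <- z2 - rowSums(sweep(Br, 2, ctr$imag)^2)
    z2
  }

  z2 <- numeric(n)
  for (g in levels(groups)) z2[groups == g] <- dist_to_center(g)
  n_clamped <- sum(z2 < 0)
  d <- sqrt(pmax(z2, 0))
  names(d) <- rownames(D)

  k <- nlevels(groups)
  anova_F <- function(dd, gg) {
    gm <- tapply(dd, gg, mean)
    ssb <- sum(tabulate(gg) * (gm - mean(dd))^2)
    ssw <- sum((dd - gm[as.integer(gg)])^2)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  Fobs <- anova_F(d, groups)

  if (p_mode == "classical_F") {
    p <- stats::pf(Fobs, k - 1, n - k, lower.tail = FALSE)
  } else {
    perm_F <- with_seed(seed, vapply(seq_len(permutations), function(b) {
      gp <- groups[sample.int(n)]
      # dispersion recomputed in full: centres depend on the labels
      z2p <- numeric(n)
      ok <- all(table(gp) >= 2L)
      if (!ok) return(NA_real_)
      for (g in levels(gp)) {
        idx <- which(gp == g)
        Ar <- A[idx, , drop = FALSE]
        Br <- B[idx, , drop = FALSE]
        ctr <- group_center(Ar, Br, center)
        v <- rowSums(sweep(Ar, 2, ctr$real)^2)
        if (ncol(Br)) v <- v - rowSums(sweep(Br, 2, ctr$imag)^2)
        z2p[idx] <- v
      }
      anova_F(sqrt(pmax(z2p, 0)), gp)
    }, numeric(1)))
    p <- permutation_pvalue(Fobs, perm_F[!is.na(perm_F)])
  }

  structure(list(
    distances = d,
    group_means = tapply(d, groups, mean),
    F = Fobs, df = c(k - 1L, n - k), p = p,
    n_clamped = n_clamped, center = center, p_mode = p_mode,
    groups = groups
  ), class = "dispersion_test")
}

# Group centre in split (real, imaginary) principal-coordinate space.
# The centroid is the column-mean pair; the spatial median minimises the
# summed (signature-corrected) distances and is found by quasi-Newton
# descent on a smoothed objective starting from the centroid.
group_center <- function(Ar, Br, center) {
  cr <- colMeans(Ar)
  ci <- if (ncol(Br)) colMeans(Br) else numeric(0)
  if (center == "centroid" || nrow(Ar) <= 2L)
    return(list(real = cr, imag = ci))
  r <- ncol(Ar)
  obj <- function(par) {
    z2 <- rowSums(sweep(Ar, 2, par[seq_len(r)])^2)
    if (ncol(Br)) z2 <- z2 - rowSums(sweep(Br, 2, par[-seq_len(r)])^2)
    sum(sqrt(pmax(z2, 0) + 1e-12))
  }
  fit <- stats::optim(c(cr, ci), obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(real = fit$par[seq_len(r)],
       imag = if (ncol(Br)) fit$par[-seq_len(r)] else numeric(0))
}

#' @export
print.dispersion_test <- function(x, digits = 4, ...) {
  cat(sprintf("Homogeneity of multivariate dispersions (%s, %s)\n",
              x$center, x$p_mode))
  cat("group mean distances to", x$center, ":\n")
  print(signif(x$group_means, digits))
  cat(sprintf("F = %.4g on (%d, %d) df, p = %.4g", x$F, x$df[1], x$df[2],
              x$p))
  if (x$n_clamped > 0)
    cat(sprintf("  [%d negative squared distance(s) clamped]", x$n_clamped))
  cat("\n")
  invisible(x)
}
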