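# Ordination: principal coordinates (the embedding behind the
# dispersion test) and non-metric multidimensional scaling (the
# visualisation of choice for chemical fingerprints).

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centred matrix of a dissimilarity
#' matrix. Non-Euclidean dissimilarities (such as Bray-Curtis on sparse
#' fingerprints) yield negative eigenvalues; the corresponding
#' "imaginary" axes are returned separately, scaled by the square root
#' of the eigenvalue magnitude, so downstream consumers can apply the
#' signed correction to squared distances.
#'
#' @param D a [distance_matrix()].
#' @param zero_tol eigenvalues within `zero_tol * max(1, |lambda|_max)`
#'   of zero are treated as zero and their axes dropped.
#' @return a `pcoa_result`: `eigenvalues` (all, descending),
#'   `real_axes` (n x r), `imaginary_axes` (n x s or `NULL`), `trace`.
#' @export
pcoa <- function(D, zero_tol = 1e-9) {
  D <- distance_matrix(as.matrix(D))
  n <- nrow(D)
  if (n < 2L) stopf("need at least two samples")
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- zero_tol * max(1, max(abs(e$values)))
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  real_axes <- if (length(pos)) {
    a <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), length(pos))
    dimnames(a) <- list(rownames(D), paste0("PCo", seq_along(pos)))
    a
  } else matrix(0, n, 0, dimnames = list(rownames(D), NULL))
  imag_axes <- if (length(neg)) {
    a <- e$vectors[, rev(neg), drop = FALSE] %*%
      diag(sqrt(-e$values[rev(neg)]), length(neg))
    dimnames(a) <- list(rownames(D), paste0("iPCo", seq_along(neg)))
    a
  } else NULL
  structure(list(eigenvalues = e$values, real_axes = real_axes,
                 imaginary_axes = imag_axes, trace = sum(diag(G))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("PCoA: %d samples; %d positive, %d negative eigenvalues\n",
              nrow(x$real_axes), ncol(x$real_axes),
              if (is.null(x$imaginary_axes)) 0 else ncol(x$imaginary_axes)))
  cat(sprintf("first eigenvalues: %s\n",
              paste(signif(utils::head(ev, 5), 4), collapse = ", ")))
  invisible(x)
}

# Least-squares monotone (isotonic) fit of the configuration distances
# on the dissimilarity ranks, with Kruskal's primary treatment of ties:
# pairs with equal dissimilarity impose no order constraint among
# themselves, implemented by pre-sorting tied blocks by configuration
# distance before pool-adjacent-violators.
monotone_fit <- function(dissim, confdist) {
  o <- order(dissim, confdist)
  fit <- numeric(length(confdist))
  fit[o] <- stats::isoreg(confdist[o])$yf
  fit
}

lower_vec <- function(D) D[lower.tri(D)]

stress_of <- function(X, d) {
  cd <- lower_vec(as.matrix(stats::dist(X)))
  dhat <- monotone_fit(d, cd)
  list(stress = sqrt(sum((cd - dhat)^2) / sum(cd^2)), cd = cd, dhat = dhat)
}

# Guttman transform: configuration update toward the current disparities
guttman_update <- function(X, cd, dhat) {
  n <- nrow(X)
  ratio <- ifelse(cd > 0, dhat / cd, 0)
  R <- matrix(0, n, n)
  R[lower.tri(R)] <- ratio
  R <- R + t(R)
  Bm <- -R
  diag(Bm) <- rowSums(R)
  (Bm %*% X) / n
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a `k`-dimensional configuration whose inter-point distances
#' best preserve the rank order of the input dissimilarities, minimising
#' `stress1 = sqrt(sum (cd - dhat)^2 / sum cd^2)` where `cd` are
#' configuration distances and `dhat` their monotone regression on the
#' dissimilarity ranks. Each start is iterated with Guttman updates
#' (step-halved whenever a step would increase stress, so the stress
#' trace is non-increasing) until the stress change falls below `tol`.
#' The first start is the PCoA configuration; the remaining starts are
#' random. The best (lowest-stress) start is returned, centred and
#' scaled so the root-mean-square inter-point distance is 1 (stress is
#' invariant to this scaling).
#'
#' @param D a [distance_matrix()]; needs `n >= k + 2` samples.
#' @param k embedding dimension.
#' @param restarts number of starts (including the PCoA start).
#' @param seed seed for the random starts.
#' @param maxit,tol iteration cap and stress-change convergence
#'   tolerance per start.
#' @return an `nmds_fit`: `points` (n x k), `stress`, `converged`,
#'   `restart_stresses`, `stress_trace` (of the best start), `k`.
#' @export
nmds <- function(D, k = 2, restarts = 20, seed = NULL, maxit = 300,
                 tol = 1e-6) {
  D <- distance_matrix(as.matrix(D))
  n <- nrow(D)
  if (k >= n - 1L) stopf("k = %d requires more than %d samples", k, n)
  d <- lower_vec(unclass(D))
  if (diff(range(d)) == 0) stopf("degenerate ranks: all dissimilarities equal")

  run_start <- function(X) {
    X <- scale(X, center = TRUE, scale = FALSE)
    res <- stress_of(X, d)
    trace <- res$stress
    converged <- FALSE
    for (it in seq_len(maxit)) {
      Xn <- guttman_update(X, res$cd, res$dhat)
      resn <- stress_of(Xn, d)
      h <- 0
      while (resn$stress > res$stress && h < 12) {
        Xn <- (Xn + X) / 2
        resn <- stress_of(Xn, d)
        h <- h + 1
      }
      if (resn$stress > res$stress) { converged <- TRUE; break }
      delta <- res$stress - resn$stress
      X <- Xn
      res <- resn
      trace <- c(trace, res$stress)
      if (delta < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = res$stress, trace = trace, converged = converged)
  }

  pc <- pcoa(D)
  X0 <- pc$real_axes
  starts <- with_seed(seed, {
    first <- if (ncol(X0) >= k) X0[, seq_len(k), drop = FALSE]
             else cbind(X0, matrix(stats::rnorm(n * (k - ncol(X0)), 0, 1e-3),
                                   n))
    c(list(first),
      lapply(seq_len(max(0, restarts - 1)), function(i)
        matrix(stats::runif(n * k, -1, 1), n, k)))
  })
  fits <- lapply(starts, run_start)
  stresses <- vapply(fits, `[[`, numeric(1), "stress")
  best <- fits[[which.min(stresses)]]

  X <- scale(best$X, center = TRUE, scale = FALSE)
  rms <- sqrt(mean(lower_vec(as.matrix(stats::dist(X)))^2))
  X <- X / rms
  dimnames(X) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  structure(list(points = X, stress = best$stress,
                 converged = best$converged,
                 restart_stresses = stresses,
                 stress_trace = best$trace, k = k),
            class = "nmds_fit")
}

#' Kruskal stress-1 of a configuration
#'
#' Recomputes the NMDS objective for given coordinates: the monotone
#' (isotonic) regression of the configuration distances on the
#' dissimilarity ranks is refit from scratch.
#'
#' @param coordinates n x k numeric matrix.
#' @param D a [distance_matrix()] with matching n.
#' @return stress-1 in `[0, 1]`.
#' @export
nmds_stress <- function(coordinates, D) {
  D <- as.matrix(D)
  if (nrow(coordinates) != nrow(D))
    stopf("coordinates and D have different numbers of samples")
  stress_of(as.matrix(coordinates), lower_vec(unclass(D)))$stress
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress-1 = %.5f (%d starts; best of %s)\n",
              x$k, x$stress, length(x$restart_stresses),
              paste(signif(range(x$restart_stresses), 4), collapse = " - ")))
  invisible(x)
}

#' Plot an NMDS configuration
#'
#' @param x an `nmds_fit`.
#' @param groups optional grouping (colours) for the points.
#' @param pch_groups optional second grouping mapped to plotting symbols
#'   (e.g. age class).
#' @param ... passed to [graphics::plot()].
#' @export
plot.nmds_fit <- function(x, groups = NULL, pch_groups = NULL, ...) {
  pts <- x$points
  col <- if (is.null(groups)) "black"
         else grDevices::hcl.colors(nlevels(as.factor(groups)),
                                    "Dark 3")[as.integer(as.factor(groups))]
  pch <- if (is.null(pch_groups)) 19 else c(19, 1, 17, 2)[
    as.integer(as.factor(pch_groups))]
  graphics::plot(pts[, 1], pts[, 2], col = col, pch = pch,
                 xlab = "NMDS1", ylab = "NMDS2",
                 main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(as.factor(groups)),
                     col = grDevices::hcl.colors(
                       nlevels(as.factor(groups)), "Dark 3"),
                     pch = 19, bty = "n")
  invisible(x)
}
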