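# Bray-Curtis dissimilarity and a Euclidean-embeddability diagnostic.

#' Bray-Curtis dissimilarity matrix
#'
#' Computes `d_ij = sum_m |x_im - x_jm| / sum_m (x_im + x_jm)` between
#' all sample pairs: 0 for identical fingerprints, 1 for fingerprints
#' with disjoint compound sets. Intended to run on log-transformed
#' relative abundances (the package's preprocessing endpoint); other
#' unit states require `force = TRUE`.
#'
#' @param x an [abundance_matrix()] (or plain non-negative numeric
#'   matrix, accepted as-is).
#' @param force allow unit states other than `"log_relative"`.
#' @return a [distance_matrix()] in the sample order of `x`.
#' @export
bray_curtis <- function(x, force = FALSE) {
  if (inherits(x, "abundance_matrix") && !force &&
      unit_state(x) != "log_relative")
    stopf(paste0("bray_curtis expects log_relative abundances (got '%s'); ",
                 "preprocess first or use force = TRUE"), unit_state(x))
  m <- unclass(x)
  if (!is.matrix(m) || !is.numeric(m)) stopf("`x` must be a numeric matrix")
  if (any(m < 0)) stopf("Bray-Curtis requires non-negative data")
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  rs <- rowSums(m)
  den <- outer(rs, rs, "+")
  both_zero <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(both_zero))
    stopf("Bray-Curtis undefined for all-zero sample pair ('%s', '%s')",
          rownames(m)[both_zero[1, 1]], rownames(m)[both_zero[1, 2]])
  D <- num / den
  diag(D) <- 0
  distance_matrix(D, rownames(m))
}

#' Is a dissimilarity matrix Euclidean-embeddable?
#'
#' A dissimilarity matrix can be represented exactly by points in
#' Euclidean space iff its Gower-centred matrix is positive
#' semi-definite. Bray-Curtis matrices on sparse data typically are not,
#' which is why the ordination and dispersion machinery must handle
#' negative eigenvalues ("imaginary" principal-coordinate axes).
#'
#' @param D a [distance_matrix()].
#' @param tol eigenvalue tolerance relative to the largest magnitude.
#' @return list with `embeddable` (logical) and `min_eigenvalue`.
#' @export
is_euclidean_embeddable <- function(D, tol = 1e-10) {
  G <- gower_center(D)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-12)
  list(embeddable = min(ev) >= -tol * scale, min_eigenvalue = min(ev))
}
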