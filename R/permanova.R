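# Distance-based multivariate analysis of variance (PERMANOVA) with
# sequential (Type I) sums of squares and permutation null distributions.
#
# The decomposition works on the Gower-centred matrix G of the squared
# dissimilarities. For cumulative design matrices X_0 (intercept) c X_1
# c ... c X_k with orthogonal projectors H_j, the sum of squares of term
# j is tr(H_j G) - tr(H_{j-1} G); the residual is tr((I - H_k) G) and the
# total tr(G). Pseudo-F compares a term's mean square to the residual
# mean square, and significance comes from re-computing pseudo-F under
# random reorderings of the samples (rows and columns of G permuted
# together, one shared permutation stream for all terms).

#' Gower double-centring of a dissimilarity matrix
#'
#' Computes `G = J A J` with `A_ij = -d_ij^2 / 2` and `J = I - 11'/n`.
#' `G` plays the role of the outer-product matrix of centred data: its
#' trace is the total sum of squares `(1/n) sum_{i<j} d_ij^2` and its row
#' sums are zero.
#'
#' @param D a [distance_matrix()].
#' @return a plain symmetric numeric matrix.
#' @export
gower_center <- function(D) {
  D <- unclass(as.matrix(D))
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) +
    mean(A)
}

# Build the factor for one model term. Plain terms name a metadata
# column; "child %in% parent" denotes nesting and is encoded as the
# parent:child interaction, so that added after the parent's own term it
# contributes (levels of child) - (levels of parent) degrees of freedom.
term_factor <- function(metadata, term) {
  term <- trimws(term)
  cols <- if (grepl("%in%", term, fixed = TRUE)) {
    rev(trimws(strsplit(term, "%in%", fixed = TRUE)[[1]]))  # parent, child
  } else term
  for (col in cols)
    if (!col %in% names(metadata))
      stopf("metadata has no column '%s' (needed by term '%s')", col, term)
  vals <- lapply(cols, function(col) metadata[[col]])
  if (any(vapply(vals, anyNA, TRUE)))
    stopf("term '%s' has missing metadata values", term)
  droplevels(factor(do.call(paste, c(vals, sep = ":"))))
}

# all permutations of 1..n (n small), identity included
all_permutations <- function(n) {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v),
                          function(i) cbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

#' Permutational multivariate analysis of variance
#'
#' Fits an ordered sequence of model terms to a dissimilarity matrix
#' using sequential (Type I) sums of squares, so that term R-squared
#' values and the residual sum to one. Terms are metadata column names;
#' nesting is written `"child %in% parent"` (e.g.
#' `"family_id %in% colony"`) and must follow its parent term.
#'
#' Permutation p-values use the add-one convention
#' `p = (#{F_perm >= F_obs} + 1) / (B + 1)`, ties counting as exceeding.
#' When the requested number of random permutations exceeds the `n!`
#' distinct orderings of a small sample, the test switches to exhaustive
#' enumeration (noted in the result's `"permutation_mode"` attribute) and
#' the p-value is the exact proportion over all orderings.
#'
#' @param D a [distance_matrix()].
#' @param metadata data frame row-aligned to `D` (e.g. the `metadata`
#'   element of a `fingerprint_dataset`).
#' @param terms character vector of ordered model terms.
#' @param permutations number of random permutations (0 skips p-values).
#' @param seed seed for the permutation stream.
#' @param strata optional factor restricting permutations to shuffle
#'   samples only within its levels.
#' @return a `permanova_table` data frame with columns `term`, `df`,
#'   `SS`, `F`, `R2`, `p`, plus `Residual` and `Total` rows.
#' @export
permanova <- function(D, metadata, terms, permutations = 99999,
                      seed = NULL, strata = NULL) {
  D <- distance_matrix(as.matrix(D))
  n <- nrow(D)
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != n)
    stopf("metadata (%d rows) is not aligned to D (%d samples)",
          nrow(metadata), n)
  if (length(terms) < 1L) stopf("at least one model term is required")

  G <- gower_center(D)
  SS_total <- sum(diag(G))

  X <- matrix(1, n, 1)
  prev_rank <- 1L
  Qs <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (j in seq_along(terms)) {
    f <- term_factor(metadata, terms[j])
    # plain indicator columns (works for single-level factors too, which
    # are then caught by the rank-based estimability check)
    X <- cbind(X, vapply(levels(f), function(l) as.numeric(f == l),
                         numeric(n)))
    qrX <- qr(X)
    r <- qrX$rank
    if (r - prev_rank < 1L)
      stopf("term '%s' is not estimable after the preceding terms",
            terms[j])
    Qs[[j]] <- qr.Q(qrX)[, seq_len(r), drop = FALSE]
    ranks[j] <- r
    prev_rank <- r
  }
  df_res <- n - prev_rank
  if (df_res < 1L) stopf("model leaves no residual degrees of freedom")

  # tr(H_j G) for every cumulative projector (intercept part vanishes
  # because G is doubly centred)
  term_traces <- function(Gm)
    vapply(Qs, function(Q) sum((Gm %*% Q) * Q), numeric(1))

  trs <- term_traces(G)
  SS <- diff(c(0, trs))
  SS_res <- SS_total - trs[length(trs)]
  df <- diff(c(1L, ranks))
  Fobs <- (SS / df) / (SS_res / df_res)

  pvals <- rep(NA_real_, length(terms))
  mode <- "none"
  if (permutations > 0) {
    exhaustive <- is.null(strata) && n <= 9 && factorial(n) <= permutations
    if (exhaustive) {
      perms <- all_permutations(n)
      mode <- "exhaustive"
      message(sprintf(
        "permanova: %d requested permutations exceed the %d distinct orderings; using exhaustive enumeration",
        as.integer(permutations), nrow(perms)))
    } else {
      perms <- with_seed(seed, {
        if (is.null(strata)) {
          t(vapply(seq_len(permutations), function(b) sample.int(n),
                   integer(n)))
        } else {
          strata <- as.factor(strata)
          idx <- split(seq_len(n), strata)
          t(vapply(seq_len(permutations), function(b) {
            p <- integer(n)
            for (g in idx) p[g] <- if (length(g) > 1L) sample(g) else g
            p
          }, integer(n)))
        }
      })
      mode <- "random"
    }
    exceed <- numeric(length(terms))
    for (b in seq_len(nrow(perms))) {
      p <- perms[b, ]
      trs_p <- term_traces(G[p, p])
      SS_p <- diff(c(0, trs_p))
      SSres_p <- SS_total - trs_p[length(trs_p)]
      Fp <- (SS_p / df) / (SSres_p / df_res)
      exceed <- exceed + (Fp >= Fobs)
    }
    pvals <- if (mode == "exhaustive") exceed / nrow(perms)
             else (exceed + 1) / (nrow(perms) + 1)
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(SS, SS_res, SS_total),
    F = c(Fobs, NA, NA),
    R2 = c(SS / SS_total, SS_res / SS_total, 1),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  structure(out, class = c("permanova_table", "data.frame"),
            permutations = if (mode == "exhaustive") nrow(perms)
                           else as.integer(permutations),
            permutation_mode = mode, seed = seed)
}

#' @export
print.permanova_table <- function(x, digits = 4, ...) {
  mode <- attr(x, "permutation_mode") %||% "none"
  cat(sprintf("PERMANOVA (sequential SS; %s permutations: %s)\n",
              mode, format(attr(x, "permutations") %||% 0, big.mark = ",")))
  df <- as.data.frame(x)
  for (col in c("SS", "F", "R2", "p"))
    df[[col]] <- signif(df[[col]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' One-way PERMANOVA statistics by the direct group-sum identity
#'
#' Computes the single-factor pseudo-F and R-squared straight from the
#' pairwise dissimilarities, without design matrices or projections:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `SS_between = SS_total - SS_within`. This independent route is used to
#' cross-check the projection-based [permanova()] fit.
#'
#' @param D a [distance_matrix()].
#' @param groups grouping vector/factor of length `nrow(D)`.
#' @return list with `F`, `R2`, `SS_between`, `SS_within`, `SS_total`,
#'   `df_between`, `df_within`.
#' @export
permanova_oneway <- function(D, groups) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n) stopf("`groups` is not aligned to D")
  if (nlevels(groups) < 2L) stopf("need at least two groups")
  if (any(table(groups) == 0L)) stopf("empty group")
  D2 <- D^2
  SS_total <- sum(D2[upper.tri(D2)]) / n
  SS_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- D2[idx, idx, drop = FALSE]
    SS_within <- SS_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  SS_between <- SS_total - SS_within
  a <- nlevels(groups)
  Fstat <- (SS_between / (a - 1)) / (SS_within / (n - a))
  list(F = Fstat, R2 = SS_between / SS_total, SS_between = SS_between,
       SS_within = SS_within, SS_total = SS_total,
       df_between = a - 1L, df_within = n - a)
}

#' Permutation p-value with the add-one convention
#'
#' `p = (#{permuted >= observed} + 1) / (length(permuted) + 1)`. Ties
#' count toward the numerator (conservative), and p can never be 0.
#'
#' @param observed observed statistic.
#' @param permuted vector of statistics under permutation.
#' @return the p-value.
#' @export
permutation_pvalue <- function(observed, permuted) {
  if (length(permuted) < 1L) stopf("`permuted` must be non-empty")
  (sum(permuted >= observed) + 1) / (length(permuted) + 1)
}
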