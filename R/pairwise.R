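# Pairwise group comparisons and univariate compound-count tests.

#' Pairwise PERMANOVAs with Bonferroni correction
#'
#' For every unordered pair of levels of a grouping factor, subsets the
#' dissimilarity matrix to the two groups, runs a one-way [permanova()],
#' and Bonferroni-corrects the p-values by the number of tests emitted.
#' The grouping may be a single metadata column, several columns (their
#' combination defines the groups, e.g. colony x age class), or an
#' explicit vector.
#'
#' @param D a [distance_matrix()].
#' @param metadata data frame aligned to `D` (ignored when `grouping`
#'   is an explicit vector).
#' @param grouping metadata column name(s) or a vector/factor of length
#'   `nrow(D)`.
#' @param permutations permutations per pairwise test.
#' @param seed master seed; each pair uses a seed derived from it.
#' @return a `pairwise_table` data frame with columns `group1`,
#'   `group2`, `F`, `R2`, `p`, `p_corrected`; pairs skipped because a
#'   level has fewer than two samples are recorded in the `"skipped"`
#'   attribute.
#' @export
pairwise_permanova <- function(D, metadata = NULL, grouping,
                               permutations = 99999, seed = NULL) {
  D <- distance_matrix(as.matrix(D))
  n <- nrow(D)
  if (is.character(grouping) && length(grouping) < n) {
    if (is.null(metadata)) stopf("metadata required to resolve grouping columns")
    metadata <- as.data.frame(metadata)
    for (col in grouping)
      if (!col %in% names(metadata))
        stopf("metadata has no column '%s'", col)
    g <- droplevels(factor(do.call(paste,
                                   c(metadata[grouping], sep = ":"))))
  } else {
    g <- droplevels(as.factor(grouping))
  }
  if (length(g) != n) stopf("grouping is not aligned to D")
  if (nlevels(g) < 2L) stopf("grouping needs at least two levels")

  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(ncol(pairs))) {
    l1 <- pairs[1, j]; l2 <- pairs[2, j]
    if (sum(g == l1) < 2L || sum(g == l2) < 2L) {
      skipped <- c(skipped, paste(l1, "vs", l2))
      message("pairwise_permanova: skipping ", l1, " vs ", l2,
              " (a level has fewer than two samples)")
      next
    }
    idx <- which(g %in% c(l1, l2))
    fit <- permanova(D[idx, idx], data.frame(group = g[idx]), "group",
                     permutations = permutations,
                     seed = if (is.null(seed)) NULL
                            else derive_seed(seed + j, "pairwise"))
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = l1, group2 = l2,
      F = fit$F[1], R2 = fit$R2[1], p = fit$p[1],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no testable pairs")
  out <- do.call(rbind, rows)
  out$p_corrected <- pmin(1, out$p * nrow(out))
  structure(out, class = c("pairwise_table", "data.frame"),
            permutations = permutations, skipped = skipped, seed = seed)
}

#' @export
print.pairwise_table <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise PERMANOVAs (%d tests, Bonferroni-corrected)\n",
              nrow(x)))
  df <- as.data.frame(x)
  for (col in c("F", "R2", "p", "p_corrected"))
    df[[col]] <- signif(df[[col]], digits)
  print(df, row.names = FALSE)
  if (length(attr(x, "skipped")))
    cat("skipped:", paste(attr(x, "skipped"), collapse = "; "), "\n")
  invisible(x)
}

#' Compare per-sample compound counts between groups
#'
#' Univariate check that groups do not differ in the sheer number of
#' detected compounds: Student's two-sample equal-variance t-test for
#' two groups, or a one-way ANOVA for several.
#'
#' @param counts numeric vector of per-sample nonzero-compound counts
#'   (see [compound_counts()]).
#' @param groups grouping vector/factor aligned to `counts`.
#' @param test `"t_test"` (exactly two groups) or `"anova"`.
#' @return list with `method`, `statistic`, `df`, `p`.
#' @export
compare_counts <- function(counts, groups, test = c("t_test", "anova")) {
  test <- match.arg(test)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != length(counts))
    stopf("`groups` is not aligned to `counts`")
  if (any(table(groups) < 2L)) stopf("every group needs at least two samples")
  if (test == "t_test") {
    if (nlevels(groups) != 2L) stopf("t_test requires exactly two groups")
    fit <- stats::t.test(counts ~ groups, var.equal = TRUE)
    list(method = "two-sample t-test (equal variances)",
         statistic = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value)
  } else {
    fit <- stats::anova(stats::lm(counts ~ groups))
    list(method = "one-way ANOVA",
         statistic = fit$`F value`[1],
         df = c(fit$Df[1], fit$Df[2]),
         p = fit$`Pr(>F)`[1])
  }
}
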