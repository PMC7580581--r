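# Bootstrap standardisation of PERMANOVA effect sizes.
#
# p-values cannot be compared across studies with different sample
# sizes, but R2 distributions can: resampling a fixed number of
# mother-offspring families per colony (with replacement) from each
# dataset and refitting the PERMANOVA yields R2 distributions on a
# common footing. The resampling unit is the family, not the single
# individual: the family term only makes sense when mothers and pups
# enter together, and a family drawn twice enters twice under fresh
# labels so the family term's degrees of freedom are identical in every
# replicate.

#' Bootstrap PERMANOVA R-squared over families
#'
#' For each replicate, draws `pairs_per_colony` families with
#' replacement independently within each of the two colonies (all
#' members of a drawn family are carried, so twin trios keep their
#' pups), recomputes Bray-Curtis on the resampled rows, refits the
#' model, and records the focal terms' R-squared. Preprocessing is done
#' once on the full dataset, not per replicate: per-sample
#' normalisation does not depend on which other samples are present,
#' and refiltering compounds per replicate would mix compound-set churn
#' into the sampling variance being measured.
#'
#' @param dataset a preprocessed `fingerprint_dataset`
#'   (`unit_state = "log_relative"`) with exactly two colonies, each
#'   holding at least two families.
#' @param terms PERMANOVA model terms (see [permanova()]).
#' @param focal subset of `terms` whose R-squared is recorded.
#' @param pairs_per_colony families drawn per colony per replicate.
#' @param replicates number of bootstrap datasets.
#' @param seed seed; the whole run is reproducible from it.
#' @return a `bootstrap_effect_sizes` object: `replicates` (matrix, one
#'   column per focal term), `full` (full-data R-squared), and the
#'   specification used.
#' @export
bootstrap_effect_sizes <- function(dataset,
                                   terms = c("age_class", "colony",
                                             "family_id %in% colony"),
                                   focal = c("colony",
                                             "family_id %in% colony"),
                                   pairs_per_colony = 15,
                                   replicates = 5000,
                                   seed = NULL) {
  if (!inherits(dataset, "fingerprint_dataset"))
    stopf("`dataset` must be a fingerprint_dataset")
  if (unit_state(dataset$abundance) != "log_relative")
    stopf("dataset must be preprocessed (unit_state 'log_relative'), got '%s'",
          unit_state(dataset$abundance))
  if (!all(focal %in% terms)) stopf("`focal` must be a subset of `terms`")
  if (pairs_per_colony < 2) stopf("pairs_per_colony must be >= 2")
  if (replicates < 1) stopf("replicates must be >= 1")
  md <- dataset$metadata
  if (is.null(md$family_id) || anyNA(md$family_id))
    stopf("every sample needs a family_id")
  colonies <- sort(unique(md$colony))
  if (length(colonies) != 2L)
    stopf("bootstrap standardisation expects exactly 2 colonies, got %d",
          length(colonies))
  fam_members <- split(seq_len(nrow(md)), md$family_id)
  fam_colony <- vapply(fam_members,
                       function(i) md$colony[i[1]], character(1))
  fams_by_colony <- split(names(fam_members), fam_colony)
  if (any(lengths(fams_by_colony) < 2L))
    stopf("each colony needs at least two families to resample")

  X <- unclass(dataset$abundance)
  full_fit <- permanova(bray_curtis(dataset$abundance), md, terms,
                        permutations = 0)
  full_R2 <- full_fit$R2[match(focal, full_fit$term)]
  names(full_R2) <- focal

  reps <- with_seed(seed, {
    out <- matrix(NA_real_, replicates, length(focal),
                  dimnames = list(NULL, focal))
    for (b in seq_len(replicates)) {
      idx <- integer(0)
      fam_lab <- character(0)
      for (cl in colonies) {
        draw <- sample(fams_by_colony[[cl]], pairs_per_colony,
                       replace = TRUE)
        for (j in seq_along(draw)) {
          members <- fam_members[[draw[j]]]
          idx <- c(idx, members)
          fam_lab <- c(fam_lab,
                       rep(sprintf("%s_bs%02d", cl, j), length(members)))
        }
      }
      md_b <- data.frame(colony = md$colony[idx],
                         age_class = md$age_class[idx],
                         family_id = fam_lab,
                         stringsAsFactors = FALSE)
      Xb <- X[idx, , drop = FALSE]
      rownames(Xb) <- sprintf("r%03d", seq_along(idx))
      fit <- permanova(bray_curtis(Xb), md_b, terms, permutations = 0)
      out[b, ] <- fit$R2[match(focal, fit$term)]
    }
    out
  })

  structure(list(replicates = reps, full = full_R2, terms = terms,
                 focal = focal, pairs_per_colony = pairs_per_colony,
                 n_replicates = replicates, seed = seed),
            class = "bootstrap_effect_sizes")
}

#' Mode of a sample by Gaussian kernel density
#'
#' Fits a Gaussian kernel density with Silverman's rule-of-thumb
#' bandwidth, evaluated on a 512-point grid spanning
#' `[min - 3h, max + 3h]`, and returns the grid point of maximal
#' density (ties broken toward the smaller value). This
#' "maximum-density" point summarises a bootstrap R-squared
#' distribution more robustly than the mean when the distribution is
#' skewed.
#'
#' @param samples numeric vector; at least 10 values unless all are
#'   identical.
#' @return the location of the density maximum.
#' @export
max_density_estimate <- function(samples) {
  x <- as.numeric(samples)
  x <- x[is.finite(x)]
  if (!length(x)) stopf("no finite values")
  if (diff(range(x)) == 0) return(x[1])
  if (length(x) < 10L) stopf("need at least 10 values")
  h <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = h, kernel = "gaussian", n = 512,
                      from = min(x) - 3 * h, to = max(x) + 3 * h)
  d$x[which.max(d$y)]
}

#' Summarise a bootstrap R-squared distribution
#'
#' One row per focal term: median, quartiles, 1.5 x IQR whisker bounds
#' (clipped to observed values, as in a standard boxplot), 2.5% and
#' 97.5% quantiles (linear-interpolation type 7), the maximum-density
#' estimate (`NA` with fewer than 10 replicates, where a kernel mode is
#' meaningless), and the full-data R-squared.
#'
#' @param dist a [bootstrap_effect_sizes()] result.
#' @return a `bootstrap_summary` data frame.
#' @export
summarize_bootstrap <- function(dist) {
  if (!inherits(dist, "bootstrap_effect_sizes"))
    stopf("`dist` must be a bootstrap_effect_sizes object")
  rows <- lapply(dist$focal, function(term) {
    x <- dist$replicates[, term]
    q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975),
                         names = FALSE, type = 7)
    iqr <- q[4] - q[2]
    data.frame(term = term,
               median = q[3], q25 = q[2], q75 = q[4],
               whisker_low = min(x[x >= q[2] - 1.5 * iqr]),
               whisker_high = max(x[x <= q[4] + 1.5 * iqr]),
               q2.5 = q[1], q97.5 = q[5],
               max_density = if (length(x) >= 10L || diff(range(x)) == 0)
                 max_density_estimate(x) else NA_real_,
               full_R2 = unname(dist$full[term]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}

#' @export
print.bootstrap_effect_sizes <- function(x, ...) {
  cat(sprintf(
    "Bootstrap effect sizes: %d replicates, %d families per colony\n",
    x$n_replicates, x$pairs_per_colony))
  print(summarize_bootstrap(x), row.names = FALSE)
  invisible(x)
}

#' Boxplot of bootstrap R-squared distributions
#'
#' @param x a [bootstrap_effect_sizes()] result.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.bootstrap_effect_sizes <- function(x, ...) {
  graphics::boxplot(x$replicates, ylab = expression(R^2),
                    main = "Bootstrap effect sizes", ...)
  graphics::points(seq_along(x$full), x$full, pch = 19, col = "grey40")
  invisible(x)
}
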