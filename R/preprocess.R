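# Preprocessing of aligned peak tables, applied in a fixed order:
# rare-compound exclusion -> relative abundance (percent) -> log(x+1).
# Normalising after filtering means excluded singleton compounds never
# influence the percent denominators.

#' Exclude compounds observed in too few samples
#'
#' Drops every compound detected (nonzero) in fewer than `min_samples`
#' samples. With the default `min_samples = 2` this removes singleton
#' compounds - peaks seen in a single sample only - which carry no
#' between-group information and mostly reflect alignment noise.
#'
#' @param x an [abundance_matrix()] with `unit_state = "raw"`.
#' @param min_samples minimum number of samples a compound must appear
#'   in; `1` is the identity.
#' @return filtered `abundance_matrix`; dropped compound labels are
#'   attached as attribute `"dropped_compounds"`.
#' @export
filter_rare_compounds <- function(x, min_samples = 2) {
  if (!inherits(x, "abundance_matrix")) stopf("`x` must be an abundance_matrix")
  if (unit_state(x) != "raw")
    stopf("filter_rare_compounds expects raw abundances, got '%s'",
          unit_state(x))
  prevalence <- colSums(unclass(x) > 0)
  keep <- prevalence >= min_samples
  if (!any(keep)) stopf("empty matrix after filtering")
  out <- x[, keep, drop = FALSE]
  attr(out, "dropped_compounds") <- colnames(x)[!keep]
  out
}

#' Normalise each sample to relative abundance (percent)
#'
#' Scales every row to sum to 100 so that samples are compared by
#' composition, not by total signal (which varies with swab loading and
#' injection volume).
#'
#' @param x an [abundance_matrix()] with `unit_state = "raw"`.
#' @return `abundance_matrix` with `unit_state = "relative_percent"`.
#' @export
to_relative_abundance <- function(x) {
  if (!inherits(x, "abundance_matrix")) stopf("`x` must be an abundance_matrix")
  if (unit_state(x) != "raw")
    stopf("to_relative_abundance expects raw abundances, got '%s'",
          unit_state(x))
  totals <- rowSums(unclass(x))
  if (any(totals == 0))
    stopf("sample '%s' has zero total abundance",
          rownames(x)[which(totals == 0)[1]])
  abundance_matrix(unclass(x) / totals * 100, "relative_percent")
}

#' log(x+1)-transform a relative abundance matrix
#'
#' Applies the natural-log transform `ln(x + 1)` cellwise, compressing
#' the dynamic range so that dominant peaks do not swamp the Bray-Curtis
#' comparison. Zeros map to zeros, so the presence/absence pattern is
#' preserved. Requires percent-scale input; calling it twice is an error.
#'
#' @param x an [abundance_matrix()] with `unit_state = "relative_percent"`.
#' @return `abundance_matrix` with `unit_state = "log_relative"`.
#' @export
log_transform <- function(x) {
  if (!inherits(x, "abundance_matrix")) stopf("`x` must be an abundance_matrix")
  if (unit_state(x) != "relative_percent")
    stopf("log_transform expects relative_percent abundances, got '%s'",
          unit_state(x))
  abundance_matrix(log1p(unclass(x)), "log_relative")
}

#' Run the full preprocessing chain on a dataset
#'
#' [filter_rare_compounds()], then [to_relative_abundance()], then
#' [log_transform()], leaving the metadata untouched.
#'
#' @param dataset a `fingerprint_dataset` with raw abundances.
#' @param min_samples passed to [filter_rare_compounds()].
#' @return the dataset with preprocessed abundances
#'   (`unit_state = "log_relative"`).
#' @export
preprocess_pipeline <- function(dataset, min_samples = 2) {
  if (!inherits(dataset, "fingerprint_dataset"))
    stopf("`dataset` must be a fingerprint_dataset")
  x <- filter_rare_compounds(dataset$abundance, min_samples)
  dropped <- attr(x, "dropped_compounds")
  x <- log_transform(to_relative_abundance(x))
  out <- dataset
  out$abundance <- x
  attr(out, "dropped_compounds") <- dropped
  out
}

#' Number of detected compounds per sample
#'
#' @param x an [abundance_matrix()] (any unit state; zero means
#'   undetected in all of them).
#' @return named integer vector of per-sample nonzero counts.
#' @export
compound_counts <- function(x) {
  if (!inherits(x, "abundance_matrix")) stopf("`x` must be an abundance_matrix")
  counts <- rowSums(unclass(x) > 0)
  storage.mode(counts) <- "integer"
  counts
}
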