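#' Construct an abundance matrix
#'
#' An `abundance_matrix` is a samples-by-compounds numeric matrix of
#' non-negative GC-MS peak abundances. Rows are samples, columns are
#' compounds labelled by their (aligned) retention times. The matrix
#' carries a `unit_state` recording where it sits in the preprocessing
#' chain: `"raw"` (arbitrary instrument units), `"relative_percent"`
#' (each sample row sums to 100) or `"log_relative"` (log(x+1) of
#' percentages). Downstream functions check this state so that, for
#' example, abundances cannot be log-transformed twice.
#'
#' @param values numeric matrix with unique row names (sample ids) and
#'   unique column names (compound labels); all entries must be finite
#'   and non-negative.
#' @param unit_state one of `"raw"`, `"relative_percent"`,
#'   `"log_relative"`.
#' @return an `abundance_matrix` object.
#' @export
abundance_matrix <- function(values,
                             unit_state = c("raw", "relative_percent",
                                            "log_relative")) {
  unit_state <- match.arg(unit_state)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must have sample row names and compound column names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicated sample ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicated compound labels: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  if (any(!is.finite(values)))
    stopf("abundances must be finite")
  if (any(values < 0))
    stopf("abundances must be non-negative")
  if (unit_state == "relative_percent") {
    rs <- rowSums(values)
    bad <- which(rs > 0 & abs(rs - 100) > 1e-6)
    if (length(bad))
      stopf("relative_percent rows must sum to 100; offending sample: %s",
            rownames(values)[bad[1]])
  }
  structure(values, unit_state = unit_state,
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, unit_state = attr(x, "unit_state"),
                     class = c("abundance_matrix", "matrix", "array"))
  out
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d compounds [%s]\n",
              nrow(x), ncol(x), unit_state(x)))
  nz <- rowSums(unclass(x) > 0)
  cat(sprintf("compounds per sample: mean %.1f, sd %.1f, range %d-%d\n",
              mean(nz), stats::sd(nz), min(nz), max(nz)))
  invisible(x)
}

#' Unit state of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return `"raw"`, `"relative_percent"` or `"log_relative"`.
#' @export
unit_state <- function(x) attr(x, "unit_state") %||% "raw"

#' Construct and validate sample metadata
#'
#' Per-sample metadata: the breeding colony, the age class
#' (`"mother"`/`"pup"`) and an optional family id grouping a mother with
#' her pup(s). Invariants enforced: sample ids unique; a family contains
#' at most one mother; all members of a family belong to one colony.
#'
#' @param df data frame with columns `sample_id`, `colony`, and
#'   optionally `age_class` and `family_id` (`NA` allowed for samples
#'   never used in a family term).
#' @return validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "colony")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("metadata is missing required column(s): %s",
          paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$colony <- as.character(df$colony)
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample_id in metadata: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]),
                collapse = ", "))
  if ("age_class" %in% names(df)) {
    df$age_class <- as.character(df$age_class)
    ok <- is.na(df$age_class) | df$age_class %in% c("mother", "pup")
    if (!all(ok))
      stopf("age_class must be 'mother' or 'pup' (offending sample: %s)",
            df$sample_id[!ok][1])
  }
  if ("family_id" %in% names(df)) {
    df$family_id <- as.character(df$family_id)
    fams <- split(df[!is.na(df$family_id), , drop = FALSE],
                  df$family_id[!is.na(df$family_id)])
    for (f in fams) {
      if (length(unique(f$colony)) > 1L)
        stopf("family '%s' spans colonies (%s)", f$family_id[1],
              paste(unique(f$colony), collapse = ", "))
      if ("age_class" %in% names(f) &&
          sum(f$age_class == "mother", na.rm = TRUE) > 1L)
        stopf("family '%s' has more than one mother", f$family_id[1])
    }
  }
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Bind an abundance matrix to row-aligned metadata
#'
#' Intersects the matrix's samples with the metadata, reorders the
#' metadata to the matrix's sample order, and records any samples
#' dropped from either side. The result is the unit every downstream
#' stage consumes.
#'
#' @param matrix an [abundance_matrix()].
#' @param metadata a [sample_metadata()] table (or coercible data frame).
#' @return a `fingerprint_dataset`: list with elements `abundance` and
#'   `metadata` (row-aligned), with attribute `"dropped"` naming samples
#'   present on only one side.
#' @export
validate_dataset <- function(matrix, metadata) {
  if (!inherits(matrix, "abundance_matrix"))
    stopf("`matrix` must be an abundance_matrix")
  metadata <- sample_metadata(metadata)
  common <- intersect(rownames(matrix), metadata$sample_id)
  if (length(common) == 0L)
    stopf("no overlapping samples between matrix and metadata")
  dropped <- c(setdiff(rownames(matrix), common),
               setdiff(metadata$sample_id, common))
  if (length(dropped))
    message("validate_dataset: dropped ", length(dropped),
            " sample(s) without a match: ",
            paste(dropped, collapse = ", "))
  keep <- rownames(matrix)[rownames(matrix) %in% common]
  mat <- matrix[keep, , drop = FALSE]
  md <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  class(md) <- c("sample_metadata", "data.frame")
  structure(list(abundance = mat, metadata = md),
            dropped = dropped, class = "fingerprint_dataset")
}

#' @export
print.fingerprint_dataset <- function(x, ...) {
  cat("fingerprint_dataset\n")
  print(x$abundance)
  cat(sprintf("colonies: %s\n",
              paste(sort(unique(x$metadata$colony)), collapse = ", ")))
  if ("age_class" %in% names(x$metadata))
    cat(sprintf("age classes: %s\n",
                paste(names(table(x$metadata$age_class)), collapse = ", ")))
  invisible(x)
}

#' Construct a distance matrix object
#'
#' Square symmetric matrix of pairwise dissimilarities with a zero
#' diagonal, carrying sample ids in the order of the source abundance
#' matrix. Accepts a square matrix or a [stats::dist] object.
#'
#' @param D square numeric matrix or `dist` object.
#' @param sample_ids optional ids; defaults to `D`'s dimnames/labels.
#' @return a `distance_matrix` (square numeric matrix subclass).
#' @export
distance_matrix <- function(D, sample_ids = NULL) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stopf("`D` must be a square matrix or dist object")
  if (is.null(sample_ids)) sample_ids <- rownames(D)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(D)))
  if (length(sample_ids) != nrow(D))
    stopf("sample_ids length does not match matrix dimension")
  if (max(abs(D - t(D))) > 1e-8) stopf("distance matrix is not symmetric")
  if (max(abs(diag(D))) > 1e-8) stopf("distance matrix diagonal is not zero")
  if (any(D < -1e-12)) stopf("negative dissimilarities")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(sample_ids, sample_ids)
  structure(D, class = c("distance_matrix", "matrix", "array"))
}

#' @export
`[.distance_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  # subsetting the same ids on both margins keeps it a distance matrix
  if (is.matrix(out) && nrow(out) == ncol(out) &&
      !is.null(rownames(out)) && identical(rownames(out), colnames(out)))
    out <- structure(out, class = c("distance_matrix", "matrix", "array"))
  out
}

#' @export
print.distance_matrix <- function(x, ...) {
  v <- x[lower.tri(x)]
  cat(sprintf("distance_matrix: %d samples; range [%.4f, %.4f], mean %.4f\n",
              nrow(x), min(v), max(v), mean(v)))
  invisible(x)
}
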