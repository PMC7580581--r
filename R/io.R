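# Reading and writing aligned peak tables and metadata.
#
# Alignment itself (retention-time matching across samples) happens
# upstream; these readers consume its delimited-text output. Two dialects
# are supported: "wide" (one row per sample, one column per compound) and
# "long" (one row per observed sample/compound/abundance triple, with
# absent cells meaning "peak not detected", i.e. abundance 0).

# Auto-detect the delimiter among comma / tab / semicolon from the header
# line. Decimal commas are deliberately unsupported: files are expected to
# use the point as decimal separator, avoiding silent locale corruption.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

read_delim_checked <- function(path, sep) {
  # read as character first so ragged rows and bad numbers can be
  # reported with a line number
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stopf("file '%s' is empty", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    stopf("ragged row in '%s': line %d has %d fields, expected %d",
          path, bad, ncols[bad], ncols[1])
  }
  mat <- do.call(rbind, fields)
  mat[] <- trimws(mat)
  list(header = mat[1, ], body = mat[-1, , drop = FALSE])
}

# `lines`: the file line number each value came from (recycled)
parse_abundance <- function(x, path, lines) {
  lines <- rep_len(lines, length(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(x %in% c("", "NA")))
  if (length(bad))
    stopf("non-numeric abundance '%s' at line %d of '%s'",
          x[bad[1]], lines[bad[1]], path)
  v[x %in% c("", "NA")] <- 0
  neg <- which(v < 0)
  if (length(neg))
    stopf("negative abundance %s at line %d of '%s'",
          x[neg[1]], lines[neg[1]], path)
  v
}

#' Read an aligned GC-MS peak table
#'
#' @param path delimited text file (comma, tab or semicolon separated;
#'   auto-detected). Lines starting with `#` are ignored.
#' @param dialect `"wide"`: header of compound labels with first column
#'   `sample_id`, one row per sample. `"long"`: columns `sample_id`,
#'   `compound_id`, `abundance`; combinations not listed are taken as 0
#'   (peak not detected).
#' @return an [abundance_matrix()] with `unit_state = "raw"`.
#' @export
read_peak_table <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  sep <- detect_sep(path)
  parsed <- read_delim_checked(path, sep)
  if (dialect == "wide") {
    header <- parsed$header
    if (tolower(header[1]) != "sample_id")
      stopf("wide peak table must have 'sample_id' as its first column")
    body <- parsed$body
    if (nrow(body) == 0L) stopf("peak table '%s' has no samples", path)
    samples <- body[, 1]
    vals <- body[, -1, drop = FALSE]
    m <- matrix(0, nrow(vals), ncol(vals),
                dimnames = list(samples, header[-1]))
    for (i in seq_len(nrow(vals)))
      m[i, ] <- parse_abundance(vals[i, ], path, lines = i + 1L)
    return(abundance_matrix(m, "raw"))
  }
  # long dialect
  header <- tolower(parsed$header)
  need <- c("sample_id", "compound_id", "abundance")
  if (!all(need %in% header))
    stopf("long peak table must have columns sample_id, compound_id, abundance")
  body <- parsed$body
  sid <- body[, match("sample_id", header)]
  cid <- body[, match("compound_id", header)]
  ab <- parse_abundance(body[, match("abundance", header)], path,
                        lines = seq_len(nrow(body)) + 1L)
  key <- paste(sid, cid, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    pair <- strsplit(d, "\r", fixed = TRUE)[[1]]
    stopf("duplicate entry for sample '%s', compound '%s'", pair[1], pair[2])
  }
  samples <- unique(sid)
  compounds <- unique(cid)
  m <- matrix(0, length(samples), length(compounds),
              dimnames = list(samples, compounds))
  m[cbind(match(sid, samples), match(cid, compounds))] <- ab
  abundance_matrix(m, "raw")
}

#' Read a sample metadata table
#'
#' Delimited text with a header containing at least `sample_id` and
#' `colony`; `age_class` and `family_id` are optional. Validation (unique
#' ids, one mother per family, families confined to one colony) is done
#' by [sample_metadata()].
#'
#' @param path delimited text file.
#' @return a `sample_metadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          strip.white = TRUE)
  names(df) <- tolower(names(df))
  df[df == ""] <- NA
  sample_metadata(df)
}

#' Write a result table as CSV
#'
#' Writes any of the package's result tables (PERMANOVA tables, pairwise
#' tables, dispersion summaries, coordinates, ...) as comma-separated
#' text with a header. Numeric columns are rendered with 15 significant
#' digits so that a write/read round trip is lossless well beyond 6
#' significant digits.
#'
#' @param table data frame (or matrix with column names).
#' @param path output file path.
#' @export
write_result_table <- function(table, path) {
  if (is.matrix(table)) table <- as.data.frame(table)
  if (!is.data.frame(table)) stopf("`table` must be a data frame or matrix")
  if (is.null(names(table)) || any(!nzchar(names(table))))
    stopf("`table` must have named columns")
  out <- table
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- trimws(formatC(out[[j]], digits = 15, format = "g"))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stopf("could not write '%s': %s", path,
                         conditionMessage(ok))
  invisible(path)
}

#' Write an abundance matrix as a peak table
#'
#' Inverse of [read_peak_table()]. The wide dialect writes first column
#' `sample_id` and one column per compound label; the long dialect writes
#' every (sample, compound) cell, zeros included, so that both dialects
#' round-trip losslessly.
#'
#' @param x an [abundance_matrix()].
#' @param path output file path.
#' @param dialect `"wide"` or `"long"`.
#' @export
write_peak_table <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!inherits(x, "abundance_matrix")) stopf("`x` must be an abundance_matrix")
  if (dialect == "wide") {
    df <- data.frame(sample_id = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      sample_id = rep(rownames(x), each = ncol(x)),
      compound_id = rep(colnames(x), times = nrow(x)),
      abundance = as.vector(t(unclass(x))),
      stringsAsFactors = FALSE)
  }
  write_result_table(df, path)
}
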