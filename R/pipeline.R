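# End-to-end orchestration of the study analysis: read or simulate ->
# preprocess -> Bray-Curtis -> {PERMANOVA, dispersion, pairwise, NMDS,
# bootstrap effect sizes}, with every stage's seed derived
# deterministically from a master seed and all results written as CSV
# next to a JSON run manifest.

#' Configuration for a full pipeline run
#'
#' Exactly one input source must be given: either `peak_table` +
#' `metadata` file paths, or a synthetic `preset` name (see
#' [study_preset()]).
#'
#' @param peak_table,metadata input file paths (wide peak table dialect).
#' @param preset synthetic preset name, or a ready-made
#'   [synthetic_config()].
#' @param min_samples rare-compound filter threshold.
#' @param terms PERMANOVA model terms.
#' @param pairwise_grouping metadata column(s) defining the groups for
#'   pairwise PERMANOVAs (`NULL` skips the stage).
#' @param permutations permutations for the main and pairwise tests.
#' @param bootstrap logical: run the bootstrap effect-size stage (needs
#'   two colonies with family structure).
#' @param pairs_per_colony,bootstrap_replicates bootstrap settings.
#' @param focal focal terms for the bootstrap.
#' @param nmds_restarts restarts for the NMDS stage.
#' @param outdir output directory (created if missing).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(peak_table = NULL, metadata = NULL, preset = NULL,
                       min_samples = 2,
                       terms = c("age_class", "colony",
                                 "family_id %in% colony"),
                       pairwise_grouping = c("colony", "age_class"),
                       permutations = 999,
                       bootstrap = TRUE,
                       pairs_per_colony = 15,
                       bootstrap_replicates = 200,
                       focal = c("colony", "family_id %in% colony"),
                       nmds_restarts = 10,
                       outdir = "scent_run",
                       seed = 1L) {
  have_files <- !is.null(peak_table) || !is.null(metadata)
  have_preset <- !is.null(preset)
  if (have_files && have_preset)
    stopf("give either input files or a synthetic preset, not both")
  if (!have_files && !have_preset)
    stopf("one of {peak_table + metadata, preset} is required")
  if (have_files && (is.null(peak_table) || is.null(metadata)))
    stopf("both peak_table and metadata paths are required")
  structure(list(peak_table = peak_table, metadata = metadata,
                 preset = preset, min_samples = min_samples, terms = terms,
                 pairwise_grouping = pairwise_grouping,
                 permutations = permutations, bootstrap = bootstrap,
                 pairs_per_colony = pairs_per_colony,
                 bootstrap_replicates = bootstrap_replicates,
                 focal = focal, nmds_restarts = nmds_restarts,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full fingerprint analysis pipeline
#'
#' Executes every stage configured in a [run_config()] and writes the
#' result tables (`permanova.csv`, `dispersion.csv`, `pairwise.csv`,
#' `nmds_coordinates.csv`, `bootstrap_replicates.csv`,
#' `bootstrap_summary.csv`), a human-readable `summary.txt`, and a
#' `manifest.json` recording the seed, configuration, package version
#' and input checksums - enough to reproduce the run exactly.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_study_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  say <- function(...) if (!quiet) message("[scentR] ", sprintf(...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list(config = config)

  # --- input stage
  if (!is.null(config$preset)) {
    say("simulating dataset (preset or config)")
    sc <- if (inherits(config$preset, "synthetic_config")) config$preset
          else study_preset(config$preset,
                            seed = derive_seed(config$seed, "simulate"))
    dataset <- generate_dataset(sc)
    checksums <- NULL
  } else {
    say("reading %s / %s", config$peak_table, config$metadata)
    dataset <- validate_dataset(read_peak_table(config$peak_table, "wide"),
                                read_sample_metadata(config$metadata))
    checksums <- as.list(tools::md5sum(c(config$peak_table,
                                         config$metadata)))
  }
  results$dataset <- dataset

  say("preprocessing (min_samples = %d)", config$min_samples)
  pre <- preprocess_pipeline(dataset, config$min_samples)
  results$preprocessed <- pre

  say("Bray-Curtis dissimilarities (%d samples)", nrow(pre$abundance))
  D <- bray_curtis(pre$abundance)
  results$distance <- D

  terms <- intersect_terms(config$terms, pre$metadata)
  say("PERMANOVA: %s (%d permutations)", paste(terms, collapse = " + "),
      config$permutations)
  results$permanova <- permanova(D, pre$metadata, terms,
                                 permutations = config$permutations,
                                 seed = derive_seed(config$seed, "permanova"))
  write_result_table(as.data.frame(results$permanova),
                     file.path(config$outdir, "permanova.csv"))

  say("dispersion homogeneity test (colony)")
  disp <- dispersion_test(D, pre$metadata$colony)
  results$dispersion <- disp
  write_result_table(
    data.frame(group = names(disp$group_means),
               mean_distance = as.numeric(disp$group_means),
               F = disp$F, df1 = disp$df[1], df2 = disp$df[2], p = disp$p),
    file.path(config$outdir, "dispersion.csv"))

  if (!is.null(config$pairwise_grouping)) {
    grouping <- intersect(config$pairwise_grouping, names(pre$metadata))
    say("pairwise PERMANOVAs by %s", paste(grouping, collapse = " x "))
    pw <- pairwise_permanova(D, pre$metadata, grouping,
                             permutations = config$permutations,
                             seed = derive_seed(config$seed, "pairwise"))
    results$pairwise <- pw
    write_result_table(as.data.frame(pw),
                       file.path(config$outdir, "pairwise.csv"))
  }

  say("NMDS (k = 2, %d restarts)", config$nmds_restarts)
  ord <- nmds(D, k = 2, restarts = config$nmds_restarts,
              seed = derive_seed(config$seed, "nmds"))
  results$nmds <- ord
  write_result_table(
    data.frame(sample_id = rownames(ord$points), ord$points,
               stringsAsFactors = FALSE),
    file.path(config$outdir, "nmds_coordinates.csv"))

  if (isTRUE(config$bootstrap) &&
      length(unique(pre$metadata$colony)) == 2L &&
      !is.null(pre$metadata$family_id)) {
    say("bootstrap effect sizes (%d replicates, %d pairs/colony)",
        config$bootstrap_replicates, config$pairs_per_colony)
    bt <- bootstrap_effect_sizes(
      pre, terms = terms, focal = intersect(config$focal, terms),
      pairs_per_colony = config$pairs_per_colony,
      replicates = config$bootstrap_replicates,
      seed = derive_seed(config$seed, "bootstrap"))
    results$bootstrap <- bt
    write_result_table(as.data.frame(bt$replicates),
                       file.path(config$outdir, "bootstrap_replicates.csv"))
    write_result_table(as.data.frame(summarize_bootstrap(bt)),
                       file.path(config$outdir, "bootstrap_summary.csv"))
  }

  cfg_plain <- lapply(unclass(config)[setdiff(names(config), "outdir")],
                      function(v) if (is.object(v)) unclass(v) else v)
  manifest <- list(
    package = "scentR",
    version = as.character(utils::packageVersion("scentR")),
    seed = config$seed,
    config = cfg_plain,
    input_checksums = checksums,
    n_samples = nrow(pre$abundance),
    n_compounds = ncol(pre$abundance),
    timestamp_free = TRUE)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  summary_lines <- c(
    sprintf("scentR pipeline run (seed %d)", config$seed),
    sprintf("samples: %d, compounds after filtering: %d",
            nrow(pre$abundance), ncol(pre$abundance)),
    sprintf("mean compounds per sample: %.1f",
            mean(compound_counts(pre$abundance))),
    "", "PERMANOVA:",
    utils::capture.output(print(results$permanova)),
    "", "Dispersion:",
    utils::capture.output(print(results$dispersion)),
    "",
    sprintf("NMDS stress: %.4f", ord$stress))
  writeLines(summary_lines, file.path(config$outdir, "summary.txt"))

  say("done; outputs in %s", config$outdir)
  invisible(results)
}

# Keep only model terms that are estimable on this dataset: columns
# present and complete, more than one level, and fewer levels than
# samples (drops the age term for pup-only designs and the family term
# when every family is a singleton).
intersect_terms <- function(terms, metadata) {
  n <- nrow(metadata)
  ok <- vapply(terms, function(tm) {
    cols <- if (grepl("%in%", tm, fixed = TRUE))
      trimws(strsplit(tm, "%in%", fixed = TRUE)[[1]]) else trimws(tm)
    if (!all(cols %in% names(metadata))) return(FALSE)
    if (any(vapply(cols, function(cc) anyNA(metadata[[cc]]), TRUE)))
      return(FALSE)
    f <- term_factor(metadata, tm)
    nlevels(f) > 1L && nlevels(f) < n
  }, TRUE)
  if (!any(ok)) stopf("no usable model terms for this dataset")
  terms[ok]
}
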