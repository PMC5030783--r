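# Reproducible end-to-end pipelines over directories of stack pairs and
# OTU tables: configuration validation, per-stage outputs as TSV, and a
# JSON manifest with file checksums so that deterministic stages can be
# verified to re-run bit-identically.

#' Configuration for the viability pipeline
#'
#' @param input_dir Directory holding stack pairs (discovered via their JSON
#'   sidecars, not by filename parsing).
#' @param output_dir Directory for outputs (created if needed).
#' @param k Clusters per channel.
#' @param exclusion_mode `"auto"`, `"roi"`, `"both"` or `"none"`.
#' @param min_volume Volume threshold for the automatic exclusion filter.
#' @param roi_dir Optional directory of ROI mask TIFFs named `<stem>_roi.tif`.
#' @param seed Master seed (recorded; the analysis stages are deterministic).
#' @return A validated `viability_config` list.
#' @export
viability_config <- function(input_dir, output_dir, k = 4L,
                             exclusion_mode = "auto", min_volume = 300L,
                             roi_dir = NULL, seed = 1L) {
  stopifnot(dir.exists(input_dir))
  if (!exclusion_mode %in% c("auto", "roi", "both", "none")) {
    stop("invalid exclusion_mode")
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 k = as.integer(k), exclusion_mode = exclusion_mode,
                 min_volume = as.integer(min_volume), roi_dir = roi_dir,
                 seed = as.integer(seed)),
            class = "viability_config")
}

config_checksum <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

manifest_entry <- function(paths) {
  data.frame(file = basename(unlist(paths)),
             md5 = unname(tools::md5sum(unlist(paths))),
             stringsAsFactors = FALSE)
}

write_manifest <- function(output_dir, config, outputs, warnings) {
  manifest <- list(tool = "oralbiofilm",
                   version = as.character(utils::packageVersion("oralbiofilm")),
                   config = unclass(config),
                   config_md5 = config_checksum(config),
                   outputs = manifest_entry(outputs),
                   warnings = warnings)
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  path
}

# discover stack pairs by their sidecars: a sidecar is any .json next to a
# matching pair of channel TIFFs
discover_stack_pairs <- function(input_dir) {
  sidecars <- list.files(input_dir, pattern = "\\.json$", full.names = TRUE)
  sidecars <- sidecars[!grepl("_truth\\.json$", sidecars)]
  sort(sidecars)
}

#' Run the viability pipeline over a directory of stack pairs
#'
#' Discovers stack pairs by their JSON sidecars, quantifies each pair
#' ([quantify_stack_pair()]), aggregates per-subject survival series
#' ([build_survival_series()]), and writes `measurements.tsv`,
#' `survival_series.tsv` and `manifest.json` into the output directory.
#' Unreadable pairs are skipped with a warning in the manifest; a run with
#' no processable pair is an error.
#'
#' @param config A [viability_config()].
#' @return Invisibly, a list with `measurements` (data.frame), `series`
#'   (data.frame) and `manifest` (path).
#' @export
run_viability_pipeline <- function(config) {
  stopifnot(inherits(config, "viability_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sidecars <- discover_stack_pairs(config$input_dir)
  if (length(sidecars) == 0) stop("no stack pairs found in ", config$input_dir)
  warnings <- character(0)
  rows <- list()
  for (sc in sidecars) {
    res <- tryCatch({
      pair <- read_stack_pair(sc)
      roi <- NULL
      if (config$exclusion_mode %in% c("roi", "both")) {
        roi_path <- file.path(config$roi_dir %||% config$input_dir,
                              paste0(basename(sub("\\.json$", "", sc)), "_roi.tif"))
        if (!file.exists(roi_path)) stop("missing ROI mask: ", roi_path)
        roi <- slices_to_array(tiff::readTIFF(roi_path, all = TRUE)) > 0
      }
      m <- quantify_stack_pair(pair, k = config$k,
                               exclusion_mode = config$exclusion_mode,
                               min_volume = config$min_volume,
                               roi_mask = roi)
      data.frame(subject = m$subject, timepoint = m$timepoint,
                 field = m$field, live_voxels = m$live_voxels,
                 dead_voxels = m$dead_voxels,
                 fraction_live = m$fraction_live,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning_msg <- sprintf("skipped %s: %s", basename(sc), conditionMessage(e))
      warnings <<- c(warnings, warning_msg)
      warning(warning_msg, call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0) stop("no stack pair could be processed")
  measurements <- do.call(rbind, rows)
  series <- withCallingHandlers(
    build_survival_series(measurements),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  meas_path <- file.path(config$output_dir, "measurements.tsv")
  series_path <- file.path(config$output_dir, "survival_series.tsv")
  write.table(measurements, meas_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(series, series_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- write_manifest(config$output_dir, config,
                             c(meas_path, series_path), warnings)
  invisible(list(measurements = measurements, series = series,
                 manifest = manifest))
}

#' Configuration for the composition pipeline
#'
#' @param counts_path,metadata_path OTU table and sample metadata TSVs (see
#'   [read_otu_table()]).
#' @param output_dir Output directory.
#' @param rank Rank for [summarize_shifts()].
#' @param min_abundance Heat-map display threshold (percent).
#' @param common_otus_only Apply [filter_common_otus()] before the OTU-level
#'   stages (heat map, log2 fold change).
#' @param seed Master seed (recorded).
#' @return A validated `composition_config` list.
#' @export
composition_config <- function(counts_path, metadata_path, output_dir,
                               rank = "phylum", min_abundance = 2,
                               common_otus_only = TRUE, seed = 1L) {
  stopifnot(file.exists(counts_path), file.exists(metadata_path))
  rank <- match.arg(rank, c("phylum", "class", "order", "family", "genus"))
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 output_dir = output_dir, rank = rank,
                 min_abundance = min_abundance,
                 common_otus_only = isTRUE(common_otus_only),
                 seed = as.integer(seed)),
            class = "composition_config")
}

#' Run the paired T0/T3 composition pipeline
#'
#' Reads the OTU table, optionally restricts to OTUs common to all samples,
#' and writes `shift_summary.tsv` (per-taxon quartiles and Bonferroni-
#' corrected paired Wilcoxon p-values at the configured rank),
#' `log2_fold_change.tsv` plus `log2fc_excluded.tsv` (zero-mean OTUs),
#' `heatmap_matrix.tsv` (subject-paired column order in the header), a
#' `run_metadata.json` recording the statistical conventions, and
#' `manifest.json`.
#'
#' @param config A [composition_config()].
#' @return Invisibly, a list with `shifts`, `fold_change`, `heatmap` and
#'   `manifest`.
#' @export
run_composition_pipeline <- function(config) {
  stopifnot(inherits(config, "composition_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  withCallingHandlers({
    table <- read_otu_table(config$counts_path, config$metadata_path)
    tp <- table$metadata$timepoint
    paired_subjects <- intersect(table$metadata$subject[tp == "T0"],
                                 table$metadata$subject[tp == "T3"])
    if (length(paired_subjects) == 0) stop("no complete T0/T3 pairs in table")
    otu_level <- if (config$common_otus_only) filter_common_otus(table) else table
    shifts <- summarize_shifts(table, config$rank)
    fc <- log2_fold_change(otu_level)
    hm <- heatmap_matrix(otu_level, config$min_abundance)

    shifts_path <- file.path(config$output_dir, "shift_summary.tsv")
    fc_path <- file.path(config$output_dir, "log2_fold_change.tsv")
    fc_excl_path <- file.path(config$output_dir, "log2fc_excluded.tsv")
    hm_path <- file.path(config$output_dir, "heatmap_matrix.tsv")
    meta_path <- file.path(config$output_dir, "run_metadata.json")
    write.table(shifts, shifts_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(fc$result, fc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(fc$excluded, fc_excl_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    hm_df <- data.frame(genus = rownames(hm$matrix), hm$matrix,
                        check.names = FALSE, stringsAsFactors = FALSE)
    write.table(hm_df, hm_path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(quantile_type = attr(shifts, "quantile_type"),
           zero_handling = attr(shifts, "zero_handling"),
           m = attr(shifts, "m"), rank = config$rank,
           common_otus_only = config$common_otus_only,
           log2fc_mode = fc$mode, heatmap_transform = "log10(1 + percent)",
           seed = config$seed),
      meta_path, auto_unbox = TRUE, digits = NA)
    manifest <- write_manifest(config$output_dir, config,
                               c(shifts_path, fc_path, fc_excl_path,
                                 hm_path, meta_path), warnings)
    invisible(list(shifts = shifts, fold_change = fc, heatmap = hm,
                   manifest = manifest))
  }, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}
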