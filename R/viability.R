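#' Reassign double-labeled voxels to the dead class
#'
#' In a mixed environmental biofilm a fraction of cells takes up both stains.
#' Voxels that are foreground in both binarized channels ("orange") are
#' always counted as dead and removed from the live mask; the dead mask is
#' unchanged.
#'
#' @param live,dead Logical foreground masks of identical shape.
#' @return List with `live` (live minus the overlap), `dead` (unchanged) and
#'   `double` (the overlap). The outputs partition the input union: `live`
#'   and `dead` are disjoint and their union equals the union of the inputs.
#' @export
reassign_double_labeled <- function(live, dead) {
  stopifnot_same_shape(live, dead, "live and dead masks")
  list(live = live & !dead, dead = dead, double = live & dead)
}

#' Voxel coverage of a binary mask
#'
#' The area covered by stained bacteria: the count of all non-zero voxels in
#' the entire binarized stack, summed over every z-slice.
#'
#' @param mask Logical (or 0/1) array.
#' @return Integer voxel count.
#' @export
coverage_area <- function(mask) {
  sum(mask != 0)
}

#' Live fraction in percent
#'
#' `100 * live / (live + dead)`, with 100% being the sum of both classes.
#' When both counts are zero the fraction is undefined and `NA` is returned
#' (never 0), so that empty fields can be excluded rather than biasing a
#' series.
#'
#' @param live,dead Non-negative voxel counts.
#' @return Percent in `[0, 100]`, or `NA_real_` when both counts are zero.
#' @export
live_fraction <- function(live, dead) {
  if (live < 0 || dead < 0) stop("counts must be non-negative")
  if (live + dead == 0) return(NA_real_)
  100 * live / (live + dead)
}

#' Quantify one confocal stack pair
#'
#' Runs the full viability pipeline on a two-channel stack in fixed order:
#' per-channel clustering of non-zero intensities, background-cluster
#' removal, exclusion of yeast/mucosa regions from both channels (ROI mask
#' and/or automatic large-component filter), double-label reassignment,
#' voxel counting, and fraction computation.
#'
#' @param pair A `stack_pair`.
#' @param k Clusters per channel (default 4).
#' @param exclusion_mode `"auto"` (large-component filter, default),
#'   `"roi"` (use `roi_mask`), `"both"`, or `"none"`.
#' @param min_volume Volume threshold (voxels) for the automatic filter.
#' @param roi_mask Logical exclusion array for `"roi"`/`"both"`.
#' @param method Clustering method, see [cluster_channel()].
#' @param keep_masks Keep intermediate masks in the result for audit.
#' @return A `viability_measurement`: list with `subject`, `timepoint`,
#'   `field`, `live_voxels`, `dead_voxels`, `fraction_live` (percent, `NA`
#'   when no foreground survives), `undefined`, `provenance` (thresholds and
#'   options used) and, if `keep_masks`, a `masks` element.
#' @export
quantify_stack_pair <- function(pair, k = 4,
                                exclusion_mode = c("auto", "roi", "both", "none"),
                                min_volume = 300L, roi_mask = NULL,
                                method = "dp", keep_masks = FALSE) {
  stopifnot(inherits(pair, "stack_pair"))
  exclusion_mode <- match.arg(exclusion_mode)
  stopifnot_same_shape(pair$live, pair$dead, "channel arrays")

  masks <- segment_stack_pair(pair, k = k, method = method)
  if (exclusion_mode %in% c("roi", "both")) {
    if (is.null(roi_mask)) stop("exclusion_mode '", exclusion_mode,
                                "' requires roi_mask")
    masks <- apply_exclusions(masks, roi_mask)
  }
  if (exclusion_mode %in% c("auto", "both")) {
    masks <- auto_exclude_large_components(masks, min_volume)$masks
  }
  parts <- reassign_double_labeled(masks$live, masks$dead)
  live_n <- coverage_area(parts$live)
  dead_n <- coverage_area(parts$dead)
  frac <- live_fraction(live_n, dead_n)

  meta <- pair$metadata
  out <- list(subject = meta$subject %||% NA_character_,
              timepoint = meta$timepoint %||% NA_character_,
              field = meta$field %||% NA_integer_,
              live_voxels = live_n, dead_voxels = dead_n,
              fraction_live = frac, undefined = is.na(frac),
              provenance = c(masks$provenance,
                             list(exclusion_mode = exclusion_mode,
                                  min_volume = min_volume)))
  if (keep_masks) out$masks <- c(parts, list(exclusion = masks$exclusion))
  structure(out, class = "viability_measurement")
}

#' @export
print.viability_measurement <- function(x, ...) {
  cat(sprintf("<viability_measurement> %s %s field %s: live %d, dead %d, %s\n",
              x$subject, x$timepoint, x$field, x$live_voxels, x$dead_voxels,
              if (x$undefined) "fraction undefined (no foreground)"
              else sprintf("%.1f%% live", x$fraction_live)))
  invisible(x)
}

#' Aggregate per-field viability into per-subject survival series
#'
#' Groups measurements by subject and orders time points T0 (removal), T1
#' (1 h), T2 (24 h), T3 (48 h). Per panel the mean live fraction over fields
#' and the sample (n-1) standard deviation are reported. Measurements with
#' undefined fractions are excluded with a warning; time points with no
#' usable field appear as gaps (`NA`), never as zeros. The result does not
#' depend on the input order.
#'
#' @param measurements List of `viability_measurement` objects, or a
#'   data.frame with columns `subject`, `timepoint`, `fraction_live`.
#' @return A data.frame with one row per subject and time point: `subject`,
#'   `timepoint`, `hours`, `n_fields`, `mean_fraction`, `sd_fraction` (`NA`
#'   when fewer than 2 fields).
#' @export
#' @examples
#' m <- data.frame(subject = "S1", timepoint = "T0",
#'                 fraction_live = c(50, 60, 70, 80, 90))
#' build_survival_series(m) # mean 70, sd sqrt(250)
build_survival_series <- function(measurements) {
  df <- if (is.data.frame(measurements)) {
    measurements
  } else {
    if (length(measurements) == 0) stop("no measurements supplied")
    do.call(rbind, lapply(measurements, function(m) {
      data.frame(subject = m$subject, timepoint = m$timepoint,
                 fraction_live = m$fraction_live,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) == 0) stop("no measurements supplied")
  if (!all(df$timepoint %in% TIMEPOINTS)) {
    stop("timepoints must be one of ", paste(TIMEPOINTS, collapse = ", "))
  }
  n_undef <- sum(is.na(df$fraction_live))
  if (n_undef > 0) {
    warning(sprintf("excluding %d measurement(s) with undefined live fraction",
                    n_undef))
    df <- df[!is.na(df$fraction_live), , drop = FALSE]
  }
  subjects <- sort(unique(df$subject))
  rows <- list()
  for (s in subjects) {
    for (tp in TIMEPOINTS) {
      v <- df$fraction_live[df$subject == s & df$timepoint == tp]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, timepoint = tp, hours = TIMEPOINT_HOURS[[tp]],
        n_fields = length(v),
        mean_fraction = if (length(v)) mean(v) else NA_real_,
        sd_fraction = if (length(v) >= 2) sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
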