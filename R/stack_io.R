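# Disk layout for confocal stack pairs: two single-channel multi-page
# 16-bit TIFFs (suffixes _live.tif / _dead.tif), a JSON sidecar with the
# acquisition metadata, and optionally a label TIFF + JSON summary for
# simulated ground truth.

array_to_slices <- function(a) {
  lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / 65535)
}

slices_to_array <- function(slices) {
  if (!is.list(slices)) slices <- list(slices)
  d <- c(length(slices), dim(slices[[1]]))
  a <- array(0, d)
  for (z in seq_along(slices)) a[z, , ] <- slices[[z]]
  round(a * 65535)
}

#' Write / read a stack pair (TIFF + JSON sidecar)
#'
#' @param pair A `stack_pair`.
#' @param dir Output directory (created if needed).
#' @param basename File stem; writes `<stem>_live.tif`, `<stem>_dead.tif`,
#'   `<stem>.json` and, when `truth` is supplied, `<stem>_labels.tif`
#'   (voxel codes 0 = background, 1 = live, 2 = dead, 3 = double-labeled,
#'   4 = yeast) and `<stem>_truth.json`.
#' @param truth Optional `stack_ground_truth`.
#' @return Invisibly, the paths written.
#' @export
write_stack_pair <- function(pair, dir, basename, truth = NULL) {
  stopifnot(inherits(pair, "stack_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, basename)
  paths <- c(live = paste0(stem, "_live.tif"),
             dead = paste0(stem, "_dead.tif"),
             sidecar = paste0(stem, ".json"))
  tiff::writeTIFF(array_to_slices(pair$live), paths[["live"]],
                  bits.per.sample = 16L)
  tiff::writeTIFF(array_to_slices(pair$dead), paths[["dead"]],
                  bits.per.sample = 16L)
  jsonlite::write_json(pair$metadata, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth)) {
    paths[["labels"]] <- paste0(stem, "_labels.tif")
    paths[["truth"]] <- paste0(stem, "_truth.json")
    tiff::writeTIFF(array_to_slices(truth$labels), paths[["labels"]],
                    bits.per.sample = 16L)
    jsonlite::write_json(list(class_counts = as.list(truth$class_counts),
                              true_fraction = truth$true_fraction,
                              undefined = truth$undefined),
                         paths[["truth"]], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' @rdname write_stack_pair
#' @param sidecar_path Path of the `<stem>.json` sidecar; the channel TIFFs
#'   are located next to it.
#' @export
read_stack_pair <- function(sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  stem <- sub("\\.json$", "", sidecar_path)
  live_path <- paste0(stem, "_live.tif")
  dead_path <- paste0(stem, "_dead.tif")
  for (p in c(live_path, dead_path)) {
    if (!file.exists(p)) stop("missing channel file: ", p)
  }
  live <- slices_to_array(tiff::readTIFF(live_path, all = TRUE))
  dead <- slices_to_array(tiff::readTIFF(dead_path, all = TRUE))
  if (!identical(dim(live), dim(dead))) {
    stop("mixed grid shapes within pair: ", sidecar_path)
  }
  structure(list(live = live, dead = dead, metadata = as.list(meta)),
            class = "stack_pair")
}

#' Read the ground-truth summary written next to a simulated pair
#'
#' @param sidecar_path Path of the pair's `<stem>.json` sidecar.
#' @return List with `class_counts`, `true_fraction`, `undefined`, or `NULL`
#'   when no truth file exists.
#' @export
read_stack_truth <- function(sidecar_path) {
  p <- paste0(sub("\\.json$", "", sidecar_path), "_truth.json")
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}
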