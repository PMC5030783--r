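#' Cluster the non-zero intensities of one confocal channel
#'
#' Partitions the multiset of non-zero voxel intensities of a single channel
#' into `k` clusters by exact 1-D k-means: the partition minimizing the
#' within-cluster sum of squares. In one dimension the optimal partition is
#' contiguous in sorted order, so a dynamic program over the run-length
#' encoded intensity histogram solves the objective exactly and
#' deterministically — there is no random initialization. A Lloyd-iteration
#' mode with a fixed seed is available for comparison with conventional
#' k-means implementations.
#'
#' The lowest-mean cluster is interpreted downstream as background and noise
#' (see [remove_background()]). If the channel holds fewer than `k` distinct
#' non-zero values, `k` is reduced to that number.
#'
#' @param channel 3-D array (or vector) of non-negative intensities.
#' @param k Number of clusters; the default of 4 leaves three foreground
#'   clusters after background removal.
#' @param method `"dp"` for the exact dynamic program (default) or `"lloyd"`
#'   for seeded Lloyd iterations via [stats::kmeans()].
#' @param seed Seed for the `"lloyd"` method only.
#'
#' @return An object of class `cluster_result`: a list with `k` (effective
#'   number of clusters), `means` (ascending cluster means), `sizes` (voxels
#'   per cluster), `breaks` (upper intensity bound of each cluster; a voxel
#'   with intensity `v > 0` belongs to the first cluster with `breaks >= v`),
#'   `sse`, and `empty = TRUE` with `k = 0` when the channel has no non-zero
#'   voxel (an empty-channel signal, not an error).
#' @seealso [remove_background()]
#' @export
#' @examples
#' ch <- array(0, c(2, 4, 1))
#' ch[1:8] <- c(1, 2, 10, 11, 20, 21, 30, 31)
#' cl <- cluster_channel(ch, k = 4)
#' cl$means # 1.5 10.5 20.5 30.5
cluster_channel <- function(channel, k = 4, method = c("dp", "lloyd"),
                            seed = 1L) {
  method <- match.arg(method)
  v <- as.numeric(channel)
  if (any(v < 0)) stop("channel intensities must be non-negative")
  v <- v[v > 0]
  if (length(v) == 0) {
    return(structure(list(k = 0L, means = numeric(0), sizes = numeric(0),
                          breaks = numeric(0), sse = 0, empty = TRUE),
                     class = "cluster_result"))
  }
  tab <- table(v)
  vals <- as.numeric(names(tab))
  cnts <- as.numeric(tab)
  keff <- min(k, length(vals))
  if (method == "dp") {
    fit <- .kmeans1d_dp(vals, cnts, keff)
    breaks <- vals[fit$ends]
    res <- list(k = fit$k, means = as.numeric(fit$means),
                sizes = as.numeric(fit$sizes), breaks = breaks,
                sse = fit$sse, empty = FALSE)
  } else {
    cl <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      stats::kmeans(v, centers = keff, nstart = 5, iter.max = 100)
    })
    ord <- order(cl$centers)
    # canonicalize: relabel ascending by mean, report interval breaks
    lab <- match(cl$cluster, ord)
    breaks <- vapply(seq_len(keff), function(i) max(v[lab == i]), numeric(1))
    res <- list(k = keff, means = as.numeric(sort(cl$centers)),
                sizes = as.numeric(table(lab)), breaks = breaks,
                sse = cl$tot.withinss, empty = FALSE)
  }
  structure(res, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<cluster_result> empty channel (no non-zero voxels)\n")
  } else {
    cat(sprintf("<cluster_result> k = %d clusters of non-zero intensities\n", x$k))
    cat("  means: ", paste(signif(x$means, 6), collapse = ", "), "\n", sep = "")
    cat("  sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Remove the background/noise cluster from a channel
#'
#' The lowest-mean intensity cluster represents background and noise and is
#' subtracted from the stack; the remaining clusters form the foreground
#' mask. With a single cluster (uniform non-zero intensity) all non-zero
#' voxels are kept: removing the only cluster would erase genuinely stained
#' uniform fields. An empty-channel `cluster_result` yields an all-`FALSE`
#' mask.
#'
#' @param channel 3-D array of non-negative intensities.
#' @param clusters A [cluster_channel()] result for this channel.
#' @return Logical array of the channel's shape: `TRUE` on foreground voxels.
#' @export
remove_background <- function(channel, clusters) {
  stopifnot(inherits(clusters, "cluster_result"))
  if (isTRUE(clusters$empty)) {
    return(array(FALSE, dim = dim(channel) %||% length(channel)))
  }
  if (clusters$k == 1L) {
    mask <- channel > 0
  } else {
    # voxels above the background cluster's upper intensity bound
    mask <- channel > clusters$breaks[1]
  }
  if (!is.null(dim(channel))) dim(mask) <- dim(channel)
  mask
}

#' Build per-channel foreground masks for a stack pair
#'
#' Runs [cluster_channel()] and [remove_background()] on both channels of a
#' confocal stack pair.
#'
#' @param pair A `stack_pair` (see [generate_stack_pair()] /
#'   [read_stack_pair()]).
#' @param k Clusters per channel (default 4).
#' @param method Clustering method, see [cluster_channel()].
#' @return A `foreground_masks` object: list with logical arrays `live` and
#'   `dead`, the applied `exclusion` mask (all-`FALSE` here), and a
#'   `provenance` list recording the background thresholds used.
#' @export
segment_stack_pair <- function(pair, k = 4, method = "dp") {
  stopifnot(inherits(pair, "stack_pair"))
  cl_live <- cluster_channel(pair$live, k = k, method = method)
  cl_dead <- cluster_channel(pair$dead, k = k, method = method)
  masks <- list(
    live = remove_background(pair$live, cl_live),
    dead = remove_background(pair$dead, cl_dead),
    exclusion = array(FALSE, dim(pair$live)),
    provenance = list(
      k = k, method = method,
      live_background_max = if (cl_live$k > 1) cl_live$breaks[1] else NA_real_,
      dead_background_max = if (cl_dead$k > 1) cl_dead$breaks[1] else NA_real_,
      live_cluster_means = cl_live$means,
      dead_cluster_means = cl_dead$means))
  class(masks) <- "foreground_masks"
  masks
}

#' Apply an exclusion mask to both channel masks
#'
#' Voxels inside the exclusion region (yeast blobs, oral mucosa cells, any
#' manually drawn ROI) are cleared from both channel masks; all other voxels
#' are left unchanged. The applied exclusion is accumulated in the
#' `exclusion` slot.
#'
#' @param masks A `foreground_masks` object.
#' @param exclusion Logical array of the masks' shape; `TRUE` marks voxels to
#'   exclude.
#' @return The updated `foreground_masks`.
#' @export
apply_exclusions <- function(masks, exclusion) {
  stopifnot(inherits(masks, "foreground_masks"))
  exclusion <- exclusion != 0
  stopifnot_same_shape(masks$live, exclusion, "mask and exclusion")
  masks$live <- masks$live & !exclusion
  masks$dead <- masks$dead & !exclusion
  masks$exclusion <- masks$exclusion | exclusion
  masks
}

#' Automatically exclude large connected components (yeast / mucosa)
#'
#' An automated stand-in for manual selection of yeast and oral mucosa cells:
#' connected components (26-connectivity in 3-D) of the union of the two
#' channel masks whose volume reaches `min_volume` voxels are removed from
#' both channels. Yeast blobs are an order of magnitude larger than cocci, so
#' a volume threshold of a few cell volumes separates them. Idempotent.
#'
#' @param masks A `foreground_masks` object.
#' @param min_volume Minimum component volume in voxels to exclude (at
#'   least 1).
#' @return A list with `masks` (updated `foreground_masks`) and `exclusion`
#'   (logical array of removed voxels).
#' @export
auto_exclude_large_components <- function(masks, min_volume) {
  stopifnot(inherits(masks, "foreground_masks"))
  if (length(min_volume) != 1 || min_volume < 1) {
    stop("min_volume must be a single integer >= 1")
  }
  union_mask <- masks$live | masks$dead
  lab <- .label_components_26(as.logical(union_mask), as.integer(dim(union_mask)))
  vol <- tabulate(lab[lab > 0L])
  big <- which(vol >= min_volume)
  exclusion <- array(FALSE, dim(union_mask))
  if (length(big)) exclusion[lab %in% big] <- TRUE
  list(masks = apply_exclusions(masks, exclusion), exclusion = exclusion)
}
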