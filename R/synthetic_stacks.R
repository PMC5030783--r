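# Synthetic two-channel confocal stacks with voxel-level ground truth.
#
# The generator emulates dual-stained (Syto 9 / propidium iodide) biofilm
# z-stacks: live cocci appear in the green channel, dead cocci and yeast
# blobs in the red channel, double-labeled cells in both. Cells are solid
# spheres (ellipsoids in voxel space when the z pitch exceeds the in-plane
# pitch), chains are touching sphere sequences along a drifting path, and
# every rendered class is recorded in a disjoint label grid so that the
# segmentation and viability stages can be scored against known truth.

#' Parameters for the synthetic confocal stack generator
#'
#' @param dim Grid shape as `c(z, y, x)` voxels.
#' @param pitch_xy,pitch_z Voxel pitch in micrometres; the z/xy ratio flattens
#'   rendered spheres along z (placement-only anisotropy; intensities are
#'   pitch-independent).
#' @param n_live,n_dead,n_double Counts of single live, dead and
#'   double-labeled cocci.
#' @param n_chains Number of coccoid chains; each chain's cells share one
#'   viability class.
#' @param chain_length_range Inclusive range of cells per chain.
#' @param chain_classes Optional character vector (`"live"`/`"dead"`) fixing
#'   each chain's class; by default each chain is live with probability
#'   `n_live / (n_live + n_dead)` (0.5 when both are zero).
#' @param n_yeast Number of large yeast blobs (red channel only).
#' @param yeast_radius_range In-plane yeast radius range (voxels).
#' @param cell_radius_range In-plane cell radius range (voxels); a degenerate
#'   range gives every cell an identical voxel volume.
#' @param live_intensity,dead_intensity,double_intensity,yeast_intensity
#'   Per-class foreground intensity ranges (16-bit counts); one value per
#'   cell (per channel for double-labeled cells) is drawn uniformly.
#' @param noise_rate Poisson shot-noise event rate per voxel; a voxel
#'   receives a noise contribution with probability `1 - exp(-noise_rate)`,
#'   so the background is mostly exactly zero (dark current) with sparse
#'   bright speckle, as in photon-counting confocal acquisition.
#' @param noise_mean,noise_sd Gaussian amplitude (truncated at zero) of a
#'   noise event, in 16-bit counts.
#' @param bleed_through Fraction of each cell's intensity leaking into the
#'   other channel, in `[0, 1)`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `stack_sim_params` list, validated.
#' @export
stack_sim_params <- function(dim = c(12L, 64L, 64L),
                             pitch_xy = 0.5, pitch_z = 1.0,
                             n_live = 80L, n_dead = 20L, n_double = 10L,
                             n_chains = 2L, chain_length_range = c(4L, 8L),
                             chain_classes = NULL,
                             n_yeast = 2L, yeast_radius_range = c(6L, 9L),
                             cell_radius_range = c(2L, 2L),
                             live_intensity = c(3000, 6000),
                             dead_intensity = c(3000, 6000),
                             double_intensity = c(3000, 6000),
                             yeast_intensity = c(4000, 7000),
                             noise_rate = 0.05,
                             noise_mean = 150, noise_sd = 150,
                             bleed_through = 0.03,
                             seed = 1L) {
  p <- list(dim = as.integer(dim), pitch_xy = pitch_xy, pitch_z = pitch_z,
            n_live = as.integer(n_live), n_dead = as.integer(n_dead),
            n_double = as.integer(n_double), n_chains = as.integer(n_chains),
            chain_length_range = as.integer(chain_length_range),
            chain_classes = chain_classes,
            n_yeast = as.integer(n_yeast),
            yeast_radius_range = yeast_radius_range,
            cell_radius_range = cell_radius_range,
            live_intensity = live_intensity, dead_intensity = dead_intensity,
            double_intensity = double_intensity,
            yeast_intensity = yeast_intensity,
            noise_rate = noise_rate,
            noise_mean = noise_mean, noise_sd = noise_sd,
            bleed_through = bleed_through, seed = as.integer(seed))
  validate_stack_sim_params(p)
  structure(p, class = "stack_sim_params")
}

validate_stack_sim_params <- function(p) {
  stopifnot(length(p$dim) == 3, all(p$dim > 0))
  counts <- c(p$n_live, p$n_dead, p$n_double, p$n_chains, p$n_yeast)
  if (any(counts < 0)) stop("object counts must be >= 0")
  if (p$bleed_through < 0 || p$bleed_through >= 1) {
    stop("bleed_through must lie in [0, 1)")
  }
  ranges <- list(p$live_intensity, p$dead_intensity, p$double_intensity,
                 p$yeast_intensity)
  if (any(vapply(ranges, function(r) any(r < 0) || r[2] < r[1], logical(1)))) {
    stop("intensity ranges must be non-negative with min <= max")
  }
  if (p$noise_mean < 0 || p$noise_sd < 0 || (p$noise_rate %||% 0) < 0) {
    stop("noise parameters must be >= 0")
  }
  if (p$chain_length_range[1] < 1 ||
      p$chain_length_range[2] < p$chain_length_range[1]) {
    stop("chain_length_range must satisfy 1 <= min <= max")
  }
  invisible(p)
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# integer voxel offsets of an ellipsoid with in-plane radius r and z semi-axis
# r / z_aspect (flattened when z pitch > xy pitch)
ellipsoid_offsets <- function(r, z_aspect) {
  rz <- max(r / z_aspect, 0.5)
  dz <- seq.int(-floor(rz), floor(rz))
  dy <- seq.int(-floor(r), floor(r))
  g <- expand.grid(dz = dz, dy = dy, dx = dy)
  keep <- (g$dz / rz)^2 + (g$dy / r)^2 + (g$dx / r)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# linear indices of an object footprint at integer center (cz, cy, cx);
# NULL if any voxel falls outside the grid
footprint_idx <- function(center, offsets, dim) {
  z <- center[1] + offsets[, 1]; y <- center[2] + offsets[, 2]
  x <- center[3] + offsets[, 3]
  if (any(z < 1 | z > dim[1] | y < 1 | y > dim[2] | x < 1 | x > dim[3])) {
    return(NULL)
  }
  z + dim[1] * ((y - 1) + dim[2] * (x - 1))
}

place_object <- function(occupied, offsets, dim, max_attempts = 200L) {
  for (i in seq_len(max_attempts)) {
    center <- c(sample.int(dim[1], 1), sample.int(dim[2], 1),
                sample.int(dim[3], 1))
    idx <- footprint_idx(center, offsets, dim)
    if (!is.null(idx) && !any(occupied[idx])) {
      return(list(center = center, idx = idx))
    }
  }
  NULL
}

# a chain of n touching equal spheres along a direction with angular drift
place_chain <- function(occupied, n_cells, r, z_aspect, dim,
                        max_attempts = 200L) {
  offsets <- ellipsoid_offsets(r, z_aspect)
  for (a in seq_len(max_attempts)) {
    center <- c(sample.int(dim[1], 1), sample.int(dim[2], 1),
                sample.int(dim[3], 1))
    dir <- rnorm(3); dir[1] <- dir[1] / z_aspect  # flatten step along z
    dir <- dir / sqrt(sum(dir^2))
    centers <- vector("list", n_cells)
    pos <- as.numeric(center)
    ok <- TRUE
    idx_all <- integer(0)
    for (i in seq_len(n_cells)) {
      ci <- as.integer(round(pos))
      idx <- footprint_idx(ci, offsets, dim)
      if (is.null(idx) || any(occupied[idx]) || any(idx %in% idx_all)) {
        ok <- FALSE; break
      }
      centers[[i]] <- ci
      idx_all <- c(idx_all, idx)
      dir <- dir + rnorm(3, sd = 0.25)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + c(2 * max(r / z_aspect, 1), 2 * r, 2 * r) * dir
    }
    if (ok) return(list(centers = centers, cell_idx = split_chain_idx(idx_all, n_cells)))
  }
  NULL
}

split_chain_idx <- function(idx_all, n_cells) {
  split(idx_all, rep(seq_len(n_cells), each = length(idx_all) / n_cells))
}

#' Generate one synthetic confocal stack pair with ground truth
#'
#' Renders a two-channel (live/dead) 3-D stack according to `params`:
#' yeast blobs first, then chains, then single cocci, each placed by
#' rejection sampling so that no two objects overlap and every object lies
#' fully inside the grid. Class intensities are drawn per cell; a
#' `bleed_through` fraction of each cell's intensity leaks into the opposite
#' channel; truncated-Gaussian noise is added everywhere and intensities are
#' quantized to 16-bit counts.
#'
#' @param params A [stack_sim_params()] object.
#' @param metadata Optional list with `subject`, `timepoint`, `field`.
#' @return A list with `pair` (a `stack_pair`: arrays `live`, `dead`,
#'   `metadata`) and `truth` (a `stack_ground_truth`: `labels` array coded
#'   0 = background, 1 = live, 2 = dead, 3 = double-labeled, 4 = yeast;
#'   per-class voxel counts; `true_fraction` = 100 * live / (live + dead +
#'   double) in percent with double-labeled counted as dead, `NA` with
#'   `undefined = TRUE` when no bacterial voxels exist).
#' @export
#' @examples
#' sim <- generate_stack_pair(stack_sim_params(n_live = 50, n_dead = 50,
#'                                             n_double = 0, n_chains = 0,
#'                                             n_yeast = 0, seed = 7))
#' sim$truth$true_fraction # exactly 50
generate_stack_pair <- function(params = stack_sim_params(),
                                metadata = list(subject = "S1",
                                                timepoint = "T0",
                                                field = 1L)) {
  validate_stack_sim_params(params)
  with_seed(params$seed, render_stack_pair(params, metadata))
}

render_stack_pair <- function(p, metadata) {
  d <- p$dim
  z_aspect <- p$pitch_z / p$pitch_xy
  n_vox <- prod(d)
  live_sig <- numeric(n_vox); dead_sig <- numeric(n_vox)
  labels <- integer(n_vox)
  occupied <- logical(n_vox)

  fail <- function(what) {
    stop(sprintf("failed to place %s after bounded attempts; grid too small for requested object counts", what),
         call. = FALSE)
  }
  draw_r <- function(range) {
    if (range[1] == range[2]) range[1] else runif(1, range[1], range[2])
  }

  # yeast first: large red-only blobs that cells must avoid
  for (i in seq_len(p$n_yeast)) {
    r <- draw_r(p$yeast_radius_range)
    pl <- place_object(occupied, ellipsoid_offsets(r, z_aspect), d)
    if (is.null(pl)) fail("yeast blob")
    occupied[pl$idx] <- TRUE
    labels[pl$idx] <- 4L
    intensity <- runif(1, p$yeast_intensity[1], p$yeast_intensity[2])
    dead_sig[pl$idx] <- pmax(dead_sig[pl$idx], intensity)
    live_sig[pl$idx] <- pmax(live_sig[pl$idx], p$bleed_through * intensity)
  }

  # chains: all cells of a chain share one viability class
  if (p$n_chains > 0) {
    classes <- p$chain_classes
    if (is.null(classes)) {
      p_live <- if (p$n_live + p$n_dead > 0) p$n_live / (p$n_live + p$n_dead) else 0.5
      classes <- ifelse(runif(p$n_chains) < p_live, "live", "dead")
    }
    stopifnot(length(classes) == p$n_chains)
    for (i in seq_len(p$n_chains)) {
      len <- if (!is.null(p$chain_lengths)) {
        p$chain_lengths[i]  # pre-drawn when a cohort target fixes the budget
      } else if (p$chain_length_range[1] == p$chain_length_range[2]) {
        p$chain_length_range[1]
      } else sample(seq(p$chain_length_range[1], p$chain_length_range[2]), 1)
      r <- draw_r(p$cell_radius_range)
      ch <- place_chain(occupied, len, r, z_aspect, d)
      if (is.null(ch)) fail("coccoid chain")
      for (cell in ch$cell_idx) {
        occupied[cell] <- TRUE
        intensity <- if (classes[i] == "live") {
          runif(1, p$live_intensity[1], p$live_intensity[2])
        } else runif(1, p$dead_intensity[1], p$dead_intensity[2])
        if (classes[i] == "live") {
          labels[cell] <- 1L
          live_sig[cell] <- pmax(live_sig[cell], intensity)
          dead_sig[cell] <- pmax(dead_sig[cell], p$bleed_through * intensity)
        } else {
          labels[cell] <- 2L
          dead_sig[cell] <- pmax(dead_sig[cell], intensity)
          live_sig[cell] <- pmax(live_sig[cell], p$bleed_through * intensity)
        }
      }
    }
  }

  # single cocci
  singles <- c(rep("live", p$n_live), rep("dead", p$n_dead),
               rep("double", p$n_double))
  for (cls in singles) {
    r <- draw_r(p$cell_radius_range)
    pl <- place_object(occupied, ellipsoid_offsets(r, z_aspect), d)
    if (is.null(pl)) fail(sprintf("%s coccus", cls))
    occupied[pl$idx] <- TRUE
    if (cls == "live") {
      labels[pl$idx] <- 1L
      intensity <- runif(1, p$live_intensity[1], p$live_intensity[2])
      live_sig[pl$idx] <- intensity
      dead_sig[pl$idx] <- pmax(dead_sig[pl$idx], p$bleed_through * intensity)
    } else if (cls == "dead") {
      labels[pl$idx] <- 2L
      intensity <- runif(1, p$dead_intensity[1], p$dead_intensity[2])
      dead_sig[pl$idx] <- intensity
      live_sig[pl$idx] <- pmax(live_sig[pl$idx], p$bleed_through * intensity)
    } else {
      labels[pl$idx] <- 3L
      live_sig[pl$idx] <- runif(1, p$double_intensity[1], p$double_intensity[2])
      dead_sig[pl$idx] <- runif(1, p$double_intensity[1], p$double_intensity[2])
    }
  }

  # sparse shot noise: most background voxels stay exactly zero
  shot_noise <- function() {
    if (p$noise_rate == 0 || (p$noise_sd == 0 && p$noise_mean == 0)) {
      return(0)
    }
    hit <- runif(n_vox) < (1 - exp(-p$noise_rate))
    amp <- numeric(n_vox)
    amp[hit] <- pmax(0, rnorm(sum(hit), p$noise_mean, p$noise_sd))
    amp
  }
  noise_live <- shot_noise()
  noise_dead <- shot_noise()
  live <- pmin(round(live_sig + noise_live), 65535)
  dead <- pmin(round(dead_sig + noise_dead), 65535)
  dim(live) <- d; dim(dead) <- d; dim(labels) <- d

  counts <- c(live = sum(labels == 1L), dead = sum(labels == 2L),
              double = sum(labels == 3L), yeast = sum(labels == 4L))
  denom <- counts[["live"]] + counts[["dead"]] + counts[["double"]]
  true_fraction <- if (denom > 0) 100 * counts[["live"]] / denom else NA_real_

  pair <- structure(list(live = live, dead = dead,
                         metadata = c(metadata,
                                      list(pitch_xy = p$pitch_xy,
                                           pitch_z = p$pitch_z,
                                           seed = p$seed))),
                    class = "stack_pair")
  truth <- structure(list(labels = labels, class_counts = counts,
                          true_fraction = true_fraction,
                          undefined = denom == 0),
                     class = "stack_ground_truth")
  list(pair = pair, truth = truth)
}

#' @export
print.stack_pair <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<stack_pair> %s / %s / field %s, %s voxels (z x y x x)\n",
              m$subject %||% "?", m$timepoint %||% "?", m$field %||% "?",
              paste(dim(x$live), collapse = " x ")))
  invisible(x)
}

#' Generate a survival cohort of synthetic stack pairs
#'
#' Emulates the imaging design of the study: per subject, at least five
#' stacks at random positions per time point, across T0 (removal from the
#' mouth), T1 (1 h), T2 (24 h) and T3 (48 h of reactor incubation). Each
#' field's true live fraction is the trajectory target plus Gaussian jitter,
#' realized by splitting a fixed total cell budget (singles plus chain
#' cells) between the live and dead classes; with zero jitter, no
#' double-labeled cells, no chains and a budget divisible by the target
#' granularity the field truths equal the targets exactly.
#'
#' @param n_subjects Number of subjects.
#' @param trajectory Named numeric vector of target live fractions (percent)
#'   for `T0`, `T1`, `T2`, `T3`.
#' @param params Base [stack_sim_params()]; `n_live + n_dead + n_double` plus
#'   the expected chain cells set the per-field cell budget.
#' @param fields_per_timepoint Fields (stacks) per subject and time point;
#'   must be >= 1, the study design uses >= 5.
#' @param jitter_sd SD (percentage points) of per-field jitter around the
#'   trajectory target.
#' @param seed Master seed; per-field seeds are derived deterministically.
#' @return A list of records, each with `pair`, `truth`, and
#'   `target_fraction`.
#' @export
generate_survival_cohort <- function(n_subjects, trajectory, params,
                                     fields_per_timepoint = 5L,
                                     jitter_sd = 5, seed = 1L) {
  if (fields_per_timepoint < 1) stop("at least one field per time point is required")
  if (!all(TIMEPOINTS %in% names(trajectory))) {
    stop("trajectory must name all of T0, T1, T2, T3")
  }
  if (any(trajectory < 0 | trajectory > 100)) {
    stop("trajectory fractions must lie in [0, 100]")
  }
  validate_stack_sim_params(params)
  out <- list()
  counter <- 0L
  for (s in seq_len(n_subjects)) {
    subject <- sprintf("S%02d", s)
    for (tp in TIMEPOINTS) {
      for (f in seq_len(fields_per_timepoint)) {
        counter <- counter + 1L
        field_seed <- (params$seed + 977L * counter) %% 2147483647L
        target <- with_seed(field_seed * 2L + 1L, {
          min(100, max(0, trajectory[[tp]] +
                            if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0))
        })
        fp <- field_params_for_target(params, target, field_seed)
        rec <- generate_stack_pair(fp, metadata = list(subject = subject,
                                                       timepoint = tp,
                                                       field = f))
        rec$target_fraction <- target
        out[[counter]] <- rec
      }
    }
  }
  out
}

# split the cell budget so the voxel-level truth hits the target fraction:
# chains are assigned greedily under the live/dead budgets, singles fill the
# exact remainder (equal cell radii make voxel and cell fractions coincide)
field_params_for_target <- function(params, target, field_seed) {
  p <- params
  p$seed <- as.integer(field_seed)
  chain_lens <- with_seed(field_seed * 2L, {
    if (p$n_chains > 0) {
      if (p$chain_length_range[1] == p$chain_length_range[2]) {
        rep(p$chain_length_range[1], p$n_chains)
      } else {
        sample(seq(p$chain_length_range[1], p$chain_length_range[2]),
               p$n_chains, replace = TRUE)
      }
    } else integer(0)
  })
  n_singles <- p$n_live + p$n_dead + p$n_double
  total <- n_singles + sum(chain_lens)
  n_live_target <- round(target / 100 * total)
  # assign whole chains without overshooting either class budget
  classes <- character(length(chain_lens))
  live_left <- n_live_target
  dead_left <- total - n_live_target
  for (i in seq_along(chain_lens)) {
    len <- chain_lens[i]
    if (live_left >= dead_left && live_left >= len) {
      classes[i] <- "live"; live_left <- live_left - len
    } else if (dead_left >= len) {
      classes[i] <- "dead"; dead_left <- dead_left - len
    } else if (live_left >= len) {
      classes[i] <- "live"; live_left <- live_left - len
    } else {
      classes[i] <- "dead"; dead_left <- max(0L, dead_left - len)
    }
  }
  n_double <- min(p$n_double, dead_left)
  p$n_live <- as.integer(live_left)
  p$n_dead <- as.integer(dead_left - n_double)
  p$n_double <- as.integer(n_double)
  p$n_chains <- length(chain_lens)
  if (length(chain_lens)) {
    p$chain_length_range <- range(chain_lens)
    p$chain_classes <- classes
    p$chain_lengths <- chain_lens
  }
  p
}
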