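#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian smoothing scale (voxels) applied to the
#'   counterstain before thresholding.
#' @param foreground_threshold Either `"otsu"` (automatic global threshold
#'   from the smoothed intensity histogram) or a fixed AU value.
#' @param min_seed_separation Chebyshev radius (voxels) of the window used
#'   to suppress nearby distance-transform maxima; roughly the smallest
#'   expected nucleus radius.
#' @param min_seed_distance Minimum distance-transform value (voxels) for a
#'   maximum to seed a nucleus; suppresses rim artefacts.
#' @param debris_volume_threshold Objects with voxel volume less than or
#'   equal to this are removed as nuclear debris (default 2000 voxels).
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                foreground_threshold = "otsu",
                                min_seed_separation = 3L,
                                min_seed_distance = 1.5,
                                debris_volume_threshold = 2000) {
  if (debris_volume_threshold < 0)
    nmp_error("invalid_params", "debris_volume_threshold must be >= 0")
  if (is.numeric(foreground_threshold) &&
      (foreground_threshold < 0 || foreground_threshold > 255))
    nmp_error("invalid_params", "fixed foreground threshold must be in [0, 255] AU")
  structure(list(smoothing_sigma = smoothing_sigma,
                 foreground_threshold = foreground_threshold,
                 min_seed_separation = as.integer(min_seed_separation),
                 min_seed_distance = min_seed_distance,
                 debris_volume_threshold = debris_volume_threshold),
            class = "segmentation_params")
}

#' Otsu's automatic global threshold
#'
#' Maximises between-class variance over a 256-bin histogram of the
#' intensity values (8-bit AU range). Returns the bin-centre threshold;
#' voxels at or above it are foreground.
#'
#' @param x Numeric vector or array of intensities in [0, 255].
#' @return Threshold in AU.
#' @export
otsu_threshold <- function(x) {
  h <- tabulate(pmin(pmax(floor(as.numeric(x)), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_total <- mu[256]
  between <- (mu_total * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)          # first maximising bin; deterministic
  levels[k] + 1                    # voxels >= threshold are foreground
}

#' Automated 3D nuclear instance segmentation
#'
#' Segments the counterstain (DAPI) channel into nuclear instances:
#' Gaussian smoothing, global foreground threshold (Otsu or fixed),
#' Euclidean distance transform of the foreground, distance maxima as
#' seeds (plateau-merged, suppressed within `min_seed_separation`), seeded
#' watershed on the inverted distance map, then the debris filter.
#' Deterministic for fixed input and parameters.
#'
#' @param counterstain 3D numeric array (z, y, x) of AU intensities.
#' @param params A [segmentation_params()].
#' @return A 3D integer label array (`label_map`): 0 background, labels a
#'   contiguous set 1..K. An all-background input yields 0 labels.
#' @export
segment_nuclei <- function(counterstain, params = segmentation_params()) {
  stopifnot(length(dim(counterstain)) == 3L)
  dims <- dim(counterstain)
  sm <- cpp_gauss_smooth(as.numeric(counterstain), dims,
                         params$smoothing_sigma)
  thr <- if (identical(params$foreground_threshold, "otsu"))
    otsu_threshold(sm) else params$foreground_threshold
  mask <- sm >= thr
  dim(mask) <- dims
  if (!any(mask))
    return(label_map(array(0L, dims)))

  edt <- cpp_distance_transform(as.logical(mask), dims)
  edt_s <- cpp_gauss_smooth(edt, dims, 1)   # regularise ragged maxima
  maxima <- cpp_local_maxima(edt_s, dims, params$min_seed_separation,
                             params$min_seed_distance)
  if (!any(maxima))
    return(label_map(array(0L, dims)))
  seeds <- cpp_label_components(as.logical(maxima), dims)  # merge plateaus
  lab <- cpp_watershed(-edt_s, seeds, as.logical(mask), dims)
  dim(lab) <- dims
  filter_debris(label_map(lab), params$debris_volume_threshold)
}

label_map <- function(arr) {
  storage.mode(arr) <- "integer"
  class(arr) <- c("label_map", class(arr))
  arr
}

#' Remove nuclear debris from a label map
#'
#' Drops every labelled object whose voxel volume is less than or equal to
#' the debris threshold (exclusive-at-threshold: a 2000-voxel object is
#' removed at the default threshold of 2000, a 2001-voxel object is kept)
#' and compacts the surviving labels to the contiguous set 1..K, preserving
#' their order.
#'
#' @param labels 3D integer label array (0 = background).
#' @param debris_volume_threshold Volume cutoff in voxels.
#' @return Filtered, compacted `label_map`.
#' @export
filter_debris <- function(labels, debris_volume_threshold = 2000) {
  if (debris_volume_threshold < 0)
    nmp_error("invalid_params", "debris_volume_threshold must be >= 0")
  dims <- dim(labels)
  lab <- as.integer(labels)
  nmax <- max(lab, 0L)
  if (nmax == 0L) {
    dim(lab) <- dims
    return(label_map(lab))
  }
  vol <- tabulate(lab[lab > 0L], nbins = nmax)
  keep <- which(vol > debris_volume_threshold)
  remap <- integer(nmax)
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  dim(lab) <- dims
  label_map(lab)
}

#' Manual seed-and-grow segmentation control
#'
#' The manual control route: one ellipse-like seed is placed at the centre
#' of each nucleus by the analyst, then grown to the nuclear boundary.
#' Growth is multi-source breadth-first region growing over the global
#' foreground mask, so seeds sharing a merged blob partition it rather than
#' merge. The debris filter is not applied: each manual seed is taken to
#' mark a real nucleus. A seed landing on background (below the foreground
#' threshold) yields a minimal single-voxel label and a recorded warning.
#'
#' @param counterstain 3D numeric array (z, y, x).
#' @param seeds Data frame or matrix of seed points with columns (z, y, x),
#'   1-based voxel coordinates; one label per seed, in row order.
#' @param params A [segmentation_params()] (only the foreground threshold
#'   is used; neither smoothing nor the debris filter applies to the
#'   manual route).
#' @return A `label_map` with exactly one label per seed. Background-seed
#'   warnings are recorded in the `run_log` attribute.
#' @export
seed_and_grow <- function(counterstain, seeds,
                          params = segmentation_params()) {
  stopifnot(length(dim(counterstain)) == 3L)
  seeds <- as.matrix(as.data.frame(seeds)[, c("z", "y", "x")])
  if (nrow(seeds) < 1L)
    nmp_error("invalid_params", "at least one seed is required")
  if (anyDuplicated(seeds))
    nmp_error("invalid_params", "seeds must be pairwise distinct")
  dims <- dim(counterstain)
  if (any(seeds < 1) || any(t(seeds) > dims))
    nmp_error("invalid_params", "all seeds must lie inside the stack")
  # the manual route grows each seed to the detectable intensity boundary
  # of the raw counterstain; no smoothing, which would erode the boundary
  thr <- if (identical(params$foreground_threshold, "otsu"))
    otsu_threshold(counterstain) else params$foreground_threshold
  mask <- counterstain >= thr
  seed0 <- round(seeds) - 1L  # to 0-based for the C++ kernel
  storage.mode(seed0) <- "integer"
  lab <- cpp_region_grow(as.logical(mask), seed0, dims)
  dim(lab) <- dims

  run_log <- character()
  bg <- which(!mask[cbind(seeds[, 1], seeds[, 2], seeds[, 3])])
  for (s in bg)
    run_log <- c(run_log, sprintf(
      "seed %d at (%d, %d, %d) lies on background; minimal label retained",
      s, seeds[s, 1], seeds[s, 2], seeds[s, 3]))
  if (length(run_log)) warning(paste(run_log, collapse = "\n"))
  out <- label_map(lab)
  attr(out, "run_log") <- run_log
  out
}

#' Two-method segmentation error
#'
#' Relative difference in retained nucleus counts between the automated
#' segmentation and the manual seed-and-grow control:
#' `|K_auto - K_manual| / K_manual`. Counts are the currency of all
#' downstream analyses, so the comparison is count-based.
#'
#' @param labels_auto,labels_manual Label maps covering the same region.
#' @return Non-negative fraction.
#' @export
segmentation_error <- function(labels_auto, labels_manual) {
  k_auto <- n_labels(labels_auto)
  k_manual <- n_labels(labels_manual)
  if (k_manual == 0L)
    nmp_error("undefined_error",
              "manual segmentation has no nuclei; error is undefined")
  abs(k_auto - k_manual) / k_manual
}

#' Number of retained labels in a label map
#' @param labels Integer label array.
#' @return Count of distinct non-zero labels.
#' @export
n_labels <- function(labels) {
  m <- max(as.integer(labels), 0L)
  if (m == 0L) return(0L)
  sum(tabulate(as.integer(labels)[labels > 0L], nbins = m) > 0L)
}
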