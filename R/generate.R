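#' Generate a ground-truthed synthetic embryo stack
#'
#' Realises an [embryo_model()] as a 3-channel 8-bit image stack plus the
#' exact ground truth every downstream stage can be scored against. Nuclei
#' are axis-aligned ellipsoids placed by rejection sampling (bounding-sphere
#' overlap at most `max_overlap`); each nucleus carries one per-channel mean
#' drawn from its class model and modulated by the rostrocaudal gradients at
#' its centroid, so ground-truth per-nucleus means are exact. Depth
#' attenuation and additive noise are applied last, then intensities are
#' clipped to [0, 255] and quantised to integers (8-bit AU).
#'
#' The random draws consume the model seed in a fixed documented order:
#' (1) the per-nucleus class assignment — a single
#' `sample(classes, n, replace = TRUE, prob = class_proportions)` call, or a
#' single shuffle of the exact `class_counts`; (2) notochord-stripe
#' membership; (3) per-nucleus placement and radii; (4) per-nucleus
#' intensity draws; (5) voxel noise.
#'
#' @param model An [embryo_model()].
#' @return A list of class `synthetic_embryo` with elements
#'   \describe{
#'     \item{stack}{4D numeric array, dim (nz, ny, nx, 3), channels
#'       (dapi, sox2, t), integer-valued AU in [0, 255].}
#'     \item{truth}{Ground-truth data frame: id, centroid (z, y, x; 1-based
#'       voxel coordinates), volume (voxels), class, mean_sox2, mean_t,
#'       mean_dapi (pre-noise, pre-attenuation), r_max.}
#'     \item{labels}{3D integer array of true instance labels (0 background).}
#'     \item{model}{The model echoed back.}
#'   }
#' @export
generate_embryo_stack <- function(model) {
  validate_embryo_model(model)
  set.seed(model$seed)
  dims <- model$stack_shape
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  n <- model$n_nuclei

  stack <- array(0, dim = c(dims, 3L),
                 dimnames = list(NULL, NULL, NULL, c("dapi", "sox2", "t")))
  for (ch in names(model$background))
    stack[, , , ch] <- model$background[[ch]]
  labels <- array(0L, dim = dims)

  truth <- empty_ground_truth()
  if (n > 0L) {
    cls <- draw_classes(model)
    stripe <- draw_stripe_membership(cls, model)
    placement <- place_nuclei(cls, stripe, model)
    labels <- paint_labels(placement, dims)

    # exact voxel centroids/volumes from the painted label map
    vox <- which(labels > 0L)
    lab_at <- labels[vox]
    coord <- arrayInd(vox, dims)
    vol <- tabulate(lab_at, nbins = n)
    if (any(vol == 0L))
      nmp_error("packing_failure",
                "a nucleus was fully overwritten during painting; lower max_overlap")
    cz <- rowsum(coord[, 1], lab_at)[, 1] / vol
    cy <- rowsum(coord[, 2], lab_at)[, 1] / vol
    cx <- rowsum(coord[, 3], lab_at)[, 1] / vol

    # gradients are evaluated at the voxelised centroid so recorded
    # ground-truth means are exactly the painted values
    vals <- draw_intensities(placement, model, centroid_x = cx)

    truth <- data.frame(id = seq_len(n), z = cz, y = cy, x = cx,
                        volume = vol, class = cls,
                        mean_sox2 = vals$sox2, mean_t = vals$t,
                        mean_dapi = vals$dapi, r_max = placement$rmax,
                        stringsAsFactors = FALSE)
    class(truth) <- c("ground_truth", "data.frame")

    stack[, , , "dapi"][vox] <- vals$dapi[lab_at]
    stack[, , , "sox2"][vox] <- vals$sox2[lab_at]
    stack[, , , "t"][vox]    <- vals$t[lab_at]
  }

  if (model$attenuation_per_slice > 0) {
    attf <- (1 - model$attenuation_per_slice)^(seq_len(nz) - 1)
    stack <- stack * attf   # recycles along z (first dimension)
  }
  if (model$noise_sd > 0)
    stack <- stack + rnorm(length(stack), sd = model$noise_sd)
  stack <- round(pmin(pmax(stack, 0), 255))

  structure(list(stack = stack, truth = truth, labels = labels,
                 model = model),
            class = "synthetic_embryo")
}

empty_ground_truth <- function() {
  truth <- data.frame(id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), volume = integer(),
                      class = character(), mean_sox2 = numeric(),
                      mean_t = numeric(), mean_dapi = numeric(),
                      r_max = numeric(), stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

draw_classes <- function(model) {
  if (!is.null(model$class_counts)) {
    cc <- model$class_counts[POPULATION_CLASSES]
    sample(rep(POPULATION_CLASSES, times = cc))
  } else {
    sample(POPULATION_CLASSES, model$n_nuclei, replace = TRUE,
           prob = model$class_proportions[POPULATION_CLASSES])
  }
}

draw_stripe_membership <- function(cls, model) {
  ns <- model$notochord_stripe
  stripe <- rep(FALSE, length(cls))
  if (isTRUE(ns$enabled)) {
    ti <- cls == "T_ONLY"
    stripe[ti] <- runif(sum(ti)) < ns$fraction
  }
  stripe
}

# Rostrocaudal placement bands (fractions of the x extent) per class: the
# Sox2 domain is rostral, the T domain caudal, double positives bridge the
# junction region, negatives are unrestricted.
CLASS_X_BANDS <- list(
  SOX2_T_DOUBLE = c(0.30, 0.75),
  SOX2_ONLY     = c(0.02, 0.45),
  T_ONLY        = c(0.55, 0.98),
  NEGATIVE      = c(0.02, 0.98)
)
STRIPE_X_BAND <- c(0.60, 0.98)
STRIPE_Y_BAND <- c(0.65, 0.88)

place_nuclei <- function(cls, stripe, model, max_attempts_per_nucleus = 500L) {
  dims <- model$stack_shape
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  n <- length(cls)
  rr <- model$nucleus_radius_range
  cenz <- ceny <- cenx <- rz <- ry <- rx <- rmax <- numeric(n)
  sep <- 1 - model$max_overlap
  for (i in seq_len(n)) {
    band <- CLASS_X_BANDS[[cls[i]]]
    ybandlo <- 1; ybandhi <- ny
    if (stripe[i]) {
      band <- STRIPE_X_BAND
      ybandlo <- STRIPE_Y_BAND[1] * ny
      ybandhi <- STRIPE_Y_BAND[2] * ny
    }
    placed <- FALSE
    for (att in seq_len(max_attempts_per_nucleus)) {
      r3 <- runif(3, rr[1], rr[2])
      rm <- max(r3)
      zlo <- 1 + rm; zhi <- nz - rm
      ylo <- max(1 + rm, ybandlo); yhi <- min(ny - rm, ybandhi)
      xlo <- max(1 + rm, band[1] * nx); xhi <- min(nx - rm, band[2] * nx)
      if (zlo > zhi || ylo > yhi || xlo > xhi)
        nmp_error("packing_failure", sprintf(
          "nucleus %d (radius %.1f voxels) cannot fit inside its placement band",
          i, rm))
      cz <- runif(1, zlo, zhi)
      cy <- runif(1, ylo, yhi)
      cx <- runif(1, xlo, xhi)
      if (i > 1L) {
        j <- seq_len(i - 1L)
        d2 <- (cenz[j] - cz)^2 + (ceny[j] - cy)^2 + (cenx[j] - cx)^2
        if (any(d2 < (sep * (rmax[j] + rm))^2)) next
      }
      cenz[i] <- cz; ceny[i] <- cy; cenx[i] <- cx
      rz[i] <- r3[1]; ry[i] <- r3[2]; rx[i] <- r3[3]; rmax[i] <- rm
      placed <- TRUE
      break
    }
    if (!placed)
      nmp_error("packing_failure", sprintf(
        "could not place nucleus %d of %d after %d attempts; reduce n_nuclei or the stack density",
        i, n, max_attempts_per_nucleus))
  }
  list(cls = cls, stripe = stripe, cz = cenz, cy = ceny, cx = cenx,
       rz = rz, ry = ry, rx = rx, rmax = rmax)
}

paint_labels <- function(p, dims) {
  labels <- array(0L, dim = dims)
  for (i in seq_along(p$cz)) {
    zr <- max(1, floor(p$cz[i] - p$rz[i])):min(dims[1], ceiling(p$cz[i] + p$rz[i]))
    yr <- max(1, floor(p$cy[i] - p$ry[i])):min(dims[2], ceiling(p$cy[i] + p$ry[i]))
    xr <- max(1, floor(p$cx[i] - p$rx[i])):min(dims[3], ceiling(p$cx[i] + p$rx[i]))
    gz <- ((zr - p$cz[i]) / p$rz[i])^2
    gy <- ((yr - p$cy[i]) / p$ry[i])^2
    gx <- ((xr - p$cx[i]) / p$rx[i])^2
    inside <- outer(outer(gz, gy, `+`), gx, `+`) <= 1
    sub <- labels[zr, yr, xr, drop = FALSE]
    sub[inside] <- i
    labels[zr, yr, xr] <- sub
  }
  labels
}

# Rostrocaudal gradient multipliers at fractional position xf in [0, 1]
# (0 = rostral): Sox2 declines caudally, T declines rostrally.
gradient_multipliers <- function(xf, gradient_params) {
  list(sox2 = 1 - gradient_params$sox2_decline * xf,
       t    = 1 - gradient_params$t_rise * (1 - xf))
}

draw_intensities <- function(p, model, centroid_x = p$cx) {
  n <- length(p$cls)
  nx <- model$stack_shape[3]
  g <- gradient_multipliers(centroid_x / nx, model$gradient_params)
  sox2 <- t_ <- numeric(n)
  for (i in seq_len(n)) {
    ip <- model$intensity_params[[p$cls[i]]]
    mu_t <- ip$t
    if (p$stripe[i])
      mu_t <- c(model$notochord_stripe$t_mean, ip$t[2])
    sox2[i] <- trunc_norm(ip$sox2[1], ip$sox2[2]) * g$sox2[i]
    t_[i]   <- trunc_norm(mu_t[1], mu_t[2]) * g$t[i]
  }
  dapi <- trunc_norm(rep(model$dapi_mean, n), model$dapi_spread)
  list(sox2 = sox2, t = t_, dapi = dapi)
}

trunc_norm <- function(mean, sd) pmin(pmax(rnorm(length(mean), mean, sd), 0), 255)

#' Extract four control regions from a ground-truthed stack
#'
#' Finds four spatially pure sub-volumes matching the per-sample internal
#' controls used to calibrate positivity thresholds: (a) only Sox2+ cells,
#' (b) only T+ cells, (c) single-positive cells of either marker, and
#' (d) no Sox2 or T positivity. A region is pure when every nucleus whose
#' centroid falls inside it has a compatible class. For the mixed region a
#' crop containing both a Sox2-only and a T-only nucleus is preferred; a
#' pure single-kind crop is the fallback.
#'
#' @param stack A 4D image array or a `synthetic_embryo` list.
#' @param truth Ground-truth data frame (ignored when `stack` is a
#'   `synthetic_embryo`, which carries its own).
#' @param margin Padding (voxels) added around nucleus extents when
#'   forming crop bounds.
#' @return A `control_roi_set`: list of four crops, each with `bounds`
#'   (z0, y0, x0, z1, y1, x1; 1-based inclusive), `expected_status` and
#'   `nucleus_ids` (ground-truth ids inside).
#' @export
generate_control_rois <- function(stack, truth = NULL, margin = 2) {
  if (inherits(stack, "synthetic_embryo")) {
    truth <- stack$truth
    dims <- dim(stack$stack)[1:3]
  } else {
    dims <- dim(stack)[1:3]
  }
  if (is.null(truth) || nrow(truth) == 0L)
    nmp_error("unsatisfiable_control",
              "ground truth is empty; no control region can be formed",
              statuses_missing = CONTROL_STATUSES)

  allowed <- list(SOX2_ONLY_REGION       = "SOX2_ONLY",
                  T_ONLY_REGION          = "T_ONLY",
                  MIXED_SINGLE_POSITIVES = c("SOX2_ONLY", "T_ONLY"),
                  ALL_NEGATIVE           = "NEGATIVE")

  crop_around <- function(rows) {
    pad <- max(truth$r_max[rows]) + margin
    b <- c(max(1, floor(min(truth$z[rows]) - pad)),
           max(1, floor(min(truth$y[rows]) - pad)),
           max(1, floor(min(truth$x[rows]) - pad)),
           min(dims[1], ceiling(max(truth$z[rows]) + pad)),
           min(dims[2], ceiling(max(truth$y[rows]) + pad)),
           min(dims[3], ceiling(max(truth$x[rows]) + pad)))
    names(b) <- c("z0", "y0", "x0", "z1", "y1", "x1")
    b
  }
  ids_in <- function(b) {
    truth$id[truth$z >= b["z0"] & truth$z <= b["z1"] &
             truth$y >= b["y0"] & truth$y <= b["y1"] &
             truth$x >= b["x0"] & truth$x <= b["x1"]]
  }
  pure_crop <- function(rows, classes_ok) {
    b <- crop_around(rows)
    ids <- ids_in(b)
    if (length(ids) &&
        all(truth$class[match(ids, truth$id)] %in% classes_ok))
      list(bounds = b, nucleus_ids = ids)
    else NULL
  }

  crops <- vector("list", 4L)
  names(crops) <- CONTROL_STATUSES
  missing <- character()
  for (status in CONTROL_STATUSES) {
    ok_classes <- allowed[[status]]
    cand <- which(truth$class %in% ok_classes)
    # single-marker controls anchor the *detection* threshold: prefer the
    # dimmest positive nuclei so the calibrated threshold sits just above
    # the negative floor rather than halfway to the brightest cells
    if (status == "SOX2_ONLY_REGION") cand <- cand[order(truth$mean_sox2[cand])]
    if (status == "T_ONLY_REGION")    cand <- cand[order(truth$mean_t[cand])]
    found <- NULL
    if (status == "MIXED_SINGLE_POSITIVES") {
      # prefer a crop holding both single-positive kinds
      si <- which(truth$class == "SOX2_ONLY")
      ti <- which(truth$class == "T_ONLY")
      for (s in si) {
        if (!is.null(found)) break
        if (!length(ti)) break
        d2 <- (truth$z[ti] - truth$z[s])^2 + (truth$y[ti] - truth$y[s])^2 +
              (truth$x[ti] - truth$x[s])^2
        for (tt in ti[order(d2)][seq_len(min(5L, length(ti)))]) {
          found <- pure_crop(c(s, tt), ok_classes)
          if (!is.null(found)) break
        }
      }
    }
    if (is.null(found)) {
      for (i in cand) {
        found <- pure_crop(i, ok_classes)
        if (!is.null(found)) break
      }
    }
    if (is.null(found)) missing <- c(missing, status)
    else crops[[status]] <- c(found, list(expected_status = status))
  }
  if (length(missing))
    nmp_error("unsatisfiable_control",
              paste("no pure control region found for status:",
                    paste(missing, collapse = ", ")),
              statuses_missing = missing)
  structure(crops, class = "control_roi_set")
}

#' Generate a developmental-stage series of synthetic stacks
#'
#' One stack per stage, typically configured with exact per-class counts so
#' the ground-truth double-positive profile (e.g. a rise to a peak followed
#' by a decline, or a fixed fold change between two stages) is realised
#' exactly before any pipeline error.
#'
#' @param stage_profile Named list of [embryo_model()]s; names are the
#'   stage labels (e.g. "E8.5", "E9.5").
#' @return Named list of `synthetic_embryo` objects, one per stage.
#' @export
generate_stage_series <- function(stage_profile) {
  if (length(stage_profile) < 2L)
    nmp_error("invalid_model", "a stage series needs at least 2 stages")
  labs <- names(stage_profile)
  if (is.null(labs) || any(!nzchar(labs)))
    nmp_error("invalid_model", "every stage needs a label (list names)")
  if (!all(vapply(stage_profile, inherits, logical(1), "embryo_model")))
    nmp_error("invalid_model", "stage_profile elements must be embryo_model objects")
  setNames(lapply(stage_profile, generate_embryo_stack), labs)
}
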