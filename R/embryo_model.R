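#' Synthetic embryo-stack model
#'
#' Parameterises the ground-truthed generator that emulates a 3-channel
#' confocal stack (DAPI counterstain, Sox2, T) of the caudal progenitor
#' region: ellipsoidal nuclei at tissue density, a Sox2+T+ double-positive
#' domain flanked rostrally by a Sox2-high domain and caudally by a T-high
#' domain, an optional T-bright notochord stripe, rostrocaudal intensity
#' gradients, additive Gaussian noise and multiplicative depth attenuation.
#' All intensities are 8-bit arbitrary units (AU, 0-255); axis order is
#' (z, y, x) with x the rostrocaudal axis (rostral at x = 1).
#'
#' @param stack_shape Integer vector (nz, ny, nx) of stack extents in voxels.
#' @param nucleus_radius_range Numeric length-2; ellipsoid semi-axes are
#'   drawn uniformly from this range (voxels).
#' @param n_nuclei Number of nuclei to place.
#' @param class_proportions Named fractions for the four Sox2/T classes
#'   (`SOX2_T_DOUBLE`, `SOX2_ONLY`, `T_ONLY`, `NEGATIVE`); must sum to 1.
#' @param class_counts Optional named integer vector of exact per-class
#'   counts (overrides the multinomial draw from `class_proportions`;
#'   must sum to `n_nuclei`). Used by [generate_stage_series()] to realise
#'   configured fold changes exactly in ground truth.
#' @param intensity_params Per-class, per-channel mean and spread (AU) of
#'   the truncated-normal per-nucleus intensity draw; a list with one
#'   element per class, each `list(sox2 = c(mean, spread), t = c(mean, spread))`.
#' @param dapi_mean,dapi_spread Counterstain per-nucleus mean intensity
#'   draw (AU), identical across classes.
#' @param gradient_params `list(sox2_decline, t_rise)`: fractional drop of
#'   the Sox2 multiplier from rostral to caudal and of the T multiplier
#'   from caudal to rostral. Both in [0, 1).
#' @param notochord_stripe `list(enabled, t_mean, fraction)`: when enabled,
#'   a `fraction` of the T-only nuclei is placed in a thin ventral-caudal
#'   stripe with T drawn around `t_mean` AU (bright notochord).
#' @param noise_sd Additive Gaussian noise s.d. (AU), applied per voxel to
#'   every channel.
#' @param attenuation_per_slice Fractional multiplicative signal loss per
#'   z step (depth attenuation); 0 disables.
#' @param max_overlap Maximum allowed fractional overlap between the
#'   bounding spheres of two nuclei (0 = fully separated).
#' @param background Background intensities, named (dapi, sox2, t), in AU.
#' @param seed Integer seed; identical models generate identical stacks.
#'
#' @return An object of class `embryo_model`.
#' @seealso [generate_embryo_stack()]
#' @export
embryo_model <- function(stack_shape = c(48L, 160L, 160L),
                         nucleus_radius_range = c(3, 6),
                         n_nuclei = 500L,
                         class_proportions = c(SOX2_T_DOUBLE = 0.30,
                                               SOX2_ONLY     = 0.25,
                                               T_ONLY        = 0.25,
                                               NEGATIVE      = 0.20),
                         class_counts = NULL,
                         intensity_params = default_intensity_params(),
                         dapi_mean = 120, dapi_spread = 10,
                         gradient_params = list(sox2_decline = 0.1,
                                                t_rise = 0.1),
                         notochord_stripe = list(enabled = TRUE,
                                                 t_mean = 45,
                                                 fraction = 0.15),
                         noise_sd = 5,
                         attenuation_per_slice = 0.003,
                         max_overlap = 0.1,
                         background = c(dapi = 4, sox2 = 0, t = 0),
                         seed = 1L) {
  model <- structure(list(
    stack_shape = as.integer(stack_shape),
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    n_nuclei = as.integer(n_nuclei),
    class_proportions = class_proportions,
    class_counts = class_counts,
    intensity_params = intensity_params,
    dapi_mean = dapi_mean, dapi_spread = dapi_spread,
    gradient_params = gradient_params,
    notochord_stripe = notochord_stripe,
    noise_sd = noise_sd,
    attenuation_per_slice = attenuation_per_slice,
    max_overlap = max_overlap,
    background = background,
    seed = as.integer(seed)
  ), class = "embryo_model")
  validate_embryo_model(model)
  model
}

#' Default per-class channel intensity parameters
#'
#' Means and spreads (AU) of the per-nucleus truncated-normal intensity
#' draw for each Sox2/T class. Double positives sit at intermediate levels
#' of both markers, single positives somewhat higher in their own marker,
#' and marker-negative channels at a low autofluorescence floor.
#'
#' @return Named list, one element per population class.
#' @export
default_intensity_params <- function() {
  list(
    SOX2_T_DOUBLE = list(sox2 = c(20, 2), t = c(18, 2)),
    SOX2_ONLY     = list(sox2 = c(25, 2), t = c(2, 1)),
    T_ONLY        = list(sox2 = c(2, 1),  t = c(25, 3)),
    NEGATIVE      = list(sox2 = c(2, 1),  t = c(2, 1))
  )
}

validate_embryo_model <- function(m) {
  stopifnot(inherits(m, "embryo_model"))
  if (length(m$stack_shape) != 3L || any(m$stack_shape < 1L))
    nmp_error("invalid_model", "stack_shape must be three positive extents")
  if (length(m$nucleus_radius_range) != 2L ||
      any(m$nucleus_radius_range < 1) ||
      diff(m$nucleus_radius_range) < 0)
    nmp_error("invalid_model", "nucleus radii must be >= 1 voxel, range non-decreasing")
  if (m$n_nuclei < 0L)
    nmp_error("invalid_model", "n_nuclei must be >= 0")
  p <- m$class_proportions
  if (!all(POPULATION_CLASSES %in% names(p)))
    nmp_error("invalid_model", "class_proportions must name all four Sox2/T classes")
  if (abs(sum(p) - 1) > 1e-9)
    nmp_error("invalid_model", "class_proportions must sum to 1 (tolerance 1e-9)")
  if (!is.null(m$class_counts)) {
    cc <- m$class_counts
    if (!all(POPULATION_CLASSES %in% names(cc)) || any(cc < 0) ||
        sum(cc) != m$n_nuclei)
      nmp_error("invalid_model",
                "class_counts must name all four classes and sum to n_nuclei")
  }
  means <- unlist(lapply(m$intensity_params[POPULATION_CLASSES],
                         function(cl) c(cl$sox2[1], cl$t[1])))
  if (any(is.na(means)) || any(means < 0) || any(means > 255))
    nmp_error("invalid_model", "all class intensity means must lie in [0, 255] AU")
  if (m$noise_sd < 0 || m$attenuation_per_slice < 0 ||
      m$attenuation_per_slice >= 1)
    nmp_error("invalid_model", "noise_sd >= 0 and attenuation in [0, 1) required")
  if (m$max_overlap < 0 || m$max_overlap >= 1)
    nmp_error("invalid_model", "max_overlap must be in [0, 1)")
  if (is.null(m$seed) || is.na(m$seed))
    nmp_error("invalid_model", "an explicit integer seed is required")
  invisible(m)
}

#' @export
print.embryo_model <- function(x, ...) {
  cat("Synthetic embryo-stack model\n")
  cat(sprintf("  stack (z,y,x): %s voxels\n",
              paste(x$stack_shape, collapse = " x ")))
  cat(sprintf("  nuclei: %d, radii %s voxels, classes %s\n", x$n_nuclei,
              paste(x$nucleus_radius_range, collapse = "-"),
              paste(sprintf("%s=%.2f", names(x$class_proportions),
                            x$class_proportions), collapse = ", ")))
  cat(sprintf("  noise %.1f AU, attenuation %.3f/slice, seed %d\n",
              x$noise_sd, x$attenuation_per_slice, x$seed))
  invisible(x)
}
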