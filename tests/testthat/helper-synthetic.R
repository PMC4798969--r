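# Shared fixtures, all generated in code.

# small, fast stack for unit tests; no notochord stripe (too small a
# volume for the ventral-caudal stripe band at this scale)
small_model <- function(n_nuclei = 40L, seed = 1L, ...) {
  args <- list(...)
  if (!"notochord_stripe" %in% names(args))
    args$notochord_stripe <- list(enabled = FALSE)
  if (!"nucleus_radius_range" %in% names(args))
    args$nucleus_radius_range <- c(2, 4)
  do.call(embryo_model, c(list(stack_shape = c(24L, 64L, 64L),
                               n_nuclei = n_nuclei, seed = seed), args))
}

# generator-scale debris threshold (nuclei here are 3-6 voxel radius)
small_seg_params <- function(...) {
  args <- list(...)
  if (!"debris_volume_threshold" %in% names(args))
    args$debris_volume_threshold <- 20
  do.call(segmentation_params, args)
}

# paint an axis-aligned ellipsoid into a fresh array
paint_ellipsoid <- function(dims, centre, radii, value = 120,
                            arr = array(0, dims)) {
  g <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                   x = seq_len(dims[3]))
  inside <- ((g$z - centre[1]) / radii[1])^2 +
            ((g$y - centre[2]) / radii[2])^2 +
            ((g$x - centre[3]) / radii[3])^2 <= 1
  arr[as.matrix(g)[inside, , drop = FALSE]] <- value
  arr
}

# analytic voxelisation count of the same ellipsoid
ellipsoid_voxel_count <- function(dims, centre, radii) {
  g <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                   x = seq_len(dims[3]))
  sum(((g$z - centre[1]) / radii[1])^2 +
      ((g$y - centre[2]) / radii[2])^2 +
      ((g$x - centre[3]) / radii[3])^2 <= 1)
}

# circle outline in image coordinates (y down): dorsal at the top,
# ventral at the bottom, observer's right at larger x
circle_outline <- function(n = 72, radius = 20, centre = c(0, 0),
                           context = "axis") {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(y = centre[1] - radius * cos(theta),
               x = centre[2] + radius * sin(theta))
  section_outline(pts, dorsal_index = 1L,
                  ventral_index = which.min(abs(theta - pi)),
                  context = context)
}

# nearest-ground-truth class agreement for classified records
truth_agreement <- function(records, truth) {
  nn <- vapply(seq_len(nrow(records)), function(i) {
    which.min((truth$z - records$z[i])^2 + (truth$y - records$y[i])^2 +
              (truth$x - records$x[i])^2)
  }, integer(1))
  mean(records$class == truth$class[nn])
}

# build a control_roi_set directly from per-crop record tables
fake_controls <- function(a, b, c_, d) {
  mk <- function(recs, status) {
    list(bounds = c(z0 = 1, y0 = 1, x0 = 1, z1 = 1, y1 = 1, x1 = 1),
         expected_status = status, nucleus_ids = recs$id, records = recs)
  }
  structure(list(SOX2_ONLY_REGION = mk(a, "SOX2_ONLY_REGION"),
                 T_ONLY_REGION = mk(b, "T_ONLY_REGION"),
                 MIXED_SINGLE_POSITIVES = mk(c_, "MIXED_SINGLE_POSITIVES"),
                 ALL_NEGATIVE = mk(d, "ALL_NEGATIVE")),
            class = "control_roi_set")
}

fake_records <- function(sox2, t) {
  data.frame(id = seq_along(sox2), z = 1, y = 1, x = 1, volume = 10L,
             mean_sox2 = sox2, mean_t = t, class = NA_character_,
             t_level = NA_character_, stringsAsFactors = FALSE)
}

# brute-force calibration accuracy over an explicit grid (independent of
# the crossprod-based implementation)
brute_force_calibration <- function(controls, grid) {
  classify_one <- function(s, t, ts, tt) {
    sp <- s >= ts; tp <- t >= tt
    if (sp && tp) "SOX2_T_DOUBLE" else if (sp) "SOX2_ONLY" else
      if (tp) "T_ONLY" else "NEGATIVE"
  }
  agrees <- function(cls, status) {
    switch(status,
           SOX2_ONLY_REGION = cls == "SOX2_ONLY",
           T_ONLY_REGION = cls == "T_ONLY",
           MIXED_SINGLE_POSITIVES = cls %in% c("SOX2_ONLY", "T_ONLY"),
           ALL_NEGATIVE = cls == "NEGATIVE")
  }
  best <- 0L
  for (ts in grid) for (tt in grid) {
    acc <- 0L
    for (crop in controls) {
      r <- crop$records
      for (i in seq_len(nrow(r)))
        acc <- acc + agrees(classify_one(r$mean_sox2[i], r$mean_t[i],
                                         ts, tt), crop$expected_status)
    }
    if (acc > best) best <- acc
  }
  best
}
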