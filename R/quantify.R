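#' Per-nucleus two-channel intensity measurement
#'
#' Overlays a nuclear label map on the Sox2 and T channels and measures,
#' for every retained label, the arithmetic mean intensity of each channel
#' over the label's voxels, plus the voxel-coordinate centroid and volume.
#' Classification fields are left unset (`NA`) until [classify_populations()]
#' and [bin_t_levels()] are applied.
#'
#' @param labels 3D integer label array.
#' @param sox2_channel,t_channel 3D numeric arrays, same shape as `labels`.
#' @return Data frame of nucleus records: id, z, y, x (1-based voxel
#'   centroid), volume, mean_sox2, mean_t, class (NA), t_level (NA).
#' @export
quantify_nuclei <- function(labels, sox2_channel, t_channel) {
  dims <- dim(labels)
  if (!identical(dims, dim(sox2_channel)) ||
      !identical(dims, dim(t_channel)))
    nmp_error("dimension_mismatch",
              "channel grids must share the label map's shape")
  vox <- which(labels > 0L)
  if (!length(vox)) return(empty_records())
  lab_at <- as.integer(labels)[vox]
  ids <- sort(unique(lab_at))
  f <- match(lab_at, ids)
  vol <- tabulate(f, nbins = length(ids))
  coord <- arrayInd(vox, dims)
  rec <- data.frame(
    id = ids,
    z = rowsum(coord[, 1], f)[, 1] / vol,
    y = rowsum(coord[, 2], f)[, 1] / vol,
    x = rowsum(coord[, 3], f)[, 1] / vol,
    volume = vol,
    mean_sox2 = rowsum(as.numeric(sox2_channel)[vox], f)[, 1] / vol,
    mean_t = rowsum(as.numeric(t_channel)[vox], f)[, 1] / vol,
    class = NA_character_,
    t_level = NA_character_,
    stringsAsFactors = FALSE
  )
  rec
}

empty_records <- function() {
  data.frame(id = integer(), z = numeric(), y = numeric(), x = numeric(),
             volume = integer(), mean_sox2 = numeric(), mean_t = numeric(),
             class = character(), t_level = character(),
             stringsAsFactors = FALSE)
}

#' Sox2/T positivity threshold pair
#'
#' @param sox2_threshold,t_threshold Positivity thresholds in AU; a nucleus
#'   is positive for a marker when its mean intensity is greater than or
#'   equal to the threshold (closed at the threshold, so a threshold of
#'   7 AU makes 7 AU positive).
#' @param accuracy,n_controls Optional calibration provenance.
#' @return Object of class `threshold_pair`.
#' @export
threshold_pair <- function(sox2_threshold, t_threshold,
                           accuracy = NA_real_, n_controls = NA_integer_) {
  if (sox2_threshold < 0 || sox2_threshold > 255 ||
      t_threshold < 0 || t_threshold > 255)
    nmp_error("invalid_params", "thresholds must lie in [0, 255] AU")
  structure(list(sox2_threshold = sox2_threshold,
                 t_threshold = t_threshold,
                 accuracy = accuracy, n_controls = n_controls),
            class = "threshold_pair")
}

#' Attach measured nucleus records to control regions
#'
#' Assigns each record whose centroid falls inside a control crop's bounds
#' to that crop, replacing (or filling) the crop's `records` element.
#'
#' @param controls A `control_roi_set` (see [generate_control_rois()]).
#' @param records Nucleus records from [quantify_nuclei()].
#' @return The control set with a `records` data frame per crop.
#' @export
control_records <- function(controls, records) {
  for (k in seq_along(controls)) {
    b <- controls[[k]]$bounds
    inside <- records$z >= b["z0"] & records$z <= b["z1"] &
              records$y >= b["y0"] & records$y <= b["y1"] &
              records$x >= b["x0"] & records$x <= b["x1"]
    controls[[k]]$records <- records[inside, , drop = FALSE]
  }
  controls
}

# Per-record agreement with a crop's expected status at thresholds (ts, tt):
# counts, for every candidate pair, how many records classify as the status
# demands. S and T are n x G indicator matrices (record >= candidate).
control_agreement_matrix <- function(controls, ts_grid, tt_grid) {
  g1 <- length(ts_grid); g2 <- length(tt_grid)
  acc <- matrix(0, g1, g2)
  for (crop in controls) {
    r <- crop$records
    if (is.null(r) || nrow(r) == 0L)
      nmp_error("invalid_params",
                "every control crop needs at least one measured record")
    S <- outer(r$mean_sox2, ts_grid, `>=`) * 1
    Tm <- outer(r$mean_t, tt_grid, `>=`) * 1
    acc <- acc + switch(crop$expected_status,
      SOX2_ONLY_REGION       = crossprod(S, 1 - Tm),
      T_ONLY_REGION          = crossprod(1 - S, Tm),
      MIXED_SINGLE_POSITIVES = crossprod(S, 1 - Tm) + crossprod(1 - S, Tm),
      ALL_NEGATIVE           = crossprod(1 - S, 1 - Tm),
      nmp_error("invalid_params",
                paste("unknown expected_status:", crop$expected_status)))
  }
  acc
}

# midpoint index of the longest contiguous run of TRUE (first on ties)
mid_of_longest_run <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  as.integer(floor((starts[best] + ends[best]) / 2))
}

#' Calibrate positivity thresholds on the four internal controls
#'
#' Exhaustive grid search over candidate (Sox2, T) threshold pairs,
#' maximising total per-nucleus agreement with the expected status of all
#' four control crops: Sox2-only crops should classify Sox2+T-, T-only
#' crops T+Sox2-, mixed crops as either single positive, negative crops as
#' double negative. Among equally accurate thresholds the midpoint of the
#' contiguous optimal interval is returned per channel (maximises margin;
#' deterministic).
#'
#' @param controls A `control_roi_set` with measured `records` attached
#'   (see [control_records()]).
#' @param grid_step Candidate grid step in AU (default 0.5; finer than the
#'   8-bit quantisation is pointless).
#' @param grid_range Candidate range in AU.
#' @return A [threshold_pair()] carrying the achieved agreement fraction.
#' @export
calibrate_thresholds <- function(controls, grid_step = 0.5,
                                 grid_range = c(0, 255)) {
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  acc <- control_agreement_matrix(controls, grid, grid)
  best <- max(acc)
  if (best == 0)
    nmp_error("calibration_failure",
              "no candidate threshold pair agrees with any control region")
  n_total <- sum(vapply(controls, function(cr) nrow(cr$records), integer(1)))
  row_ok <- apply(acc, 1, max) == best
  i <- mid_of_longest_run(row_ok)
  j <- mid_of_longest_run(acc[i, ] == best)
  threshold_pair(grid[i], grid[j], accuracy = best / n_total,
                 n_controls = n_total)
}

#' Four-way Sox2/T population classification
#'
#' A nucleus is Sox2+ when `mean_sox2 >=` the Sox2 threshold and T+ when
#' `mean_t >=` the T threshold; the four combinations partition every
#' record set into double positives (`SOX2_T_DOUBLE`), `SOX2_ONLY`,
#' `T_ONLY` and `NEGATIVE`.
#'
#' @param records Nucleus records from [quantify_nuclei()].
#' @param thresholds A [threshold_pair()].
#' @return List: `records` with `class` set, and `counts`
#'   (see [population_counts()]).
#' @export
classify_populations <- function(records, thresholds) {
  sp <- records$mean_sox2 >= thresholds$sox2_threshold
  tp <- records$mean_t >= thresholds$t_threshold
  records$class <- ifelse(sp & tp, "SOX2_T_DOUBLE",
                   ifelse(sp, "SOX2_ONLY",
                   ifelse(tp, "T_ONLY", "NEGATIVE")))
  list(records = records, counts = population_counts(records))
}

#' T-intensity level bins
#'
#' Half-open intensity bins used to grade T expression: negative below the
#' positivity threshold, then level 1 up to level 5 with the last bin open
#' above the final edge. Defaults: negative i < 7 AU; L1 7 <= i < 12;
#' L2 12 <= i < 24; L3 24 <= i < 36; L4 36 <= i < 48; L5 i >= 48; the
#' highest intensity recorded in the reference material was 80 AU.
#'
#' @param positivity Positivity threshold in AU (first bin edge).
#' @param edges Increasing bin edges in AU; the first must equal
#'   `positivity`.
#' @param max_recorded Highest intensity observed (AU), kept for reporting.
#' @return Object of class `t_level_bins`.
#' @export
t_level_bins <- function(positivity = 7, edges = c(7, 12, 24, 36, 48),
                         max_recorded = 80) {
  if (any(diff(edges) <= 0))
    nmp_error("invalid_params", "bin edges must be strictly increasing")
  if (edges[1] != positivity)
    nmp_error("invalid_params",
              "first bin edge must equal the positivity threshold")
  structure(list(positivity = positivity, edges = edges,
                 max_recorded = max_recorded), class = "t_level_bins")
}

#' Assign T-intensity levels
#'
#' Bins each record's mean T intensity into NEG or levels L1..L5 using the
#' half-open scheme of [t_level_bins()] (an intensity equal to an edge
#' falls in the higher bin; the last bin is unbounded above).
#'
#' @param records Nucleus records.
#' @param bins A [t_level_bins()].
#' @return List: `records` with `t_level` set, and `level_counts`, a named
#'   vector over NEG, L1..L5 summing to the record count.
#' @export
bin_t_levels <- function(records, bins = t_level_bins()) {
  k <- findInterval(records$mean_t, bins$edges)   # 0 = below positivity
  records$t_level <- T_LEVELS[k + 1L]
  level_counts <- setNames(tabulate(k + 1L, nbins = length(T_LEVELS)),
                           T_LEVELS)
  list(records = records, level_counts = level_counts)
}

#' Population counts for one stack or embryo
#'
#' @param records Classified nucleus records (`class` set; `t_level`
#'   optional).
#' @return One-row data frame: n_total, n_double, n_sox2_only, n_t_only,
#'   n_negative, and (when `t_level` is set) n_NEG, n_L1..n_L5.
#' @export
population_counts <- function(records) {
  if (nrow(records) > 0 && anyNA(records$class))
    nmp_error("invalid_params", "records must be classified first")
  cls <- factor(records$class, levels = POPULATION_CLASSES)
  ct <- table(cls)
  out <- data.frame(n_total = nrow(records),
                    n_double = as.integer(ct[["SOX2_T_DOUBLE"]]),
                    n_sox2_only = as.integer(ct[["SOX2_ONLY"]]),
                    n_t_only = as.integer(ct[["T_ONLY"]]),
                    n_negative = as.integer(ct[["NEGATIVE"]]))
  if (nrow(records) == 0 || !anyNA(records$t_level)) {
    lv <- table(factor(records$t_level, levels = T_LEVELS))
    for (l in T_LEVELS) out[[paste0("n_", l)]] <- as.integer(lv[[l]])
  }
  out
}

#' Export classified nuclei for 3D rendering
#'
#' Writes the per-nucleus coordinate/class table consumed by any 3D viewer
#' (one row per nucleus; colours per [population_colours()]).
#'
#' @param records Classified nucleus records.
#' @param path Optional CSV path; when given the table is written there.
#' @return The export data frame (id, z, y, x, volume, mean_sox2, mean_t,
#'   class, t_level, colour), invisibly when written to file.
#' @export
export_3d <- function(records, path = NULL) {
  if (nrow(records) > 0 && anyNA(records$class))
    nmp_error("invalid_params", "records must be classified before export")
  out <- records[, c("id", "z", "y", "x", "volume", "mean_sox2", "mean_t",
                     "class", "t_level")]
  out$colour <- unname(population_colours()[out$class])
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
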