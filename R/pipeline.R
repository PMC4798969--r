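#' Pipeline run configuration
#'
#' Exactly one of `generator` (synthetic stacks with ground truth) or
#' `input_paths` (pre-acquired per-channel TIFFs) must be supplied.
#'
#' @param generator Named list of [embryo_model()]s, one per stage (names
#'   are stage labels), or a single `embryo_model` (one stage).
#' @param input_paths Named list, one element per stage, each a named list
#'   of TIFF paths (dapi, sox2, t) and optionally `control_rois` (a CSV of
#'   crop bounds, see [write_control_rois()]).
#' @param seg_params A [segmentation_params()].
#' @param bins A [t_level_bins()].
#' @param grid_step Threshold-calibration grid step in AU.
#' @param fixed_thresholds Optional [threshold_pair()] used when no control
#'   regions are available for a stage.
#' @param embryo_counts_csv Optional CSV of per-embryo population counts
#'   (columns stage, embryo, n_total, n_double, ...) for the statistics
#'   stage.
#' @param output_dir Output directory for all persisted intermediates.
#' @param seed Integer seed, recorded in the manifest.
#' @param log_level "info" or "quiet".
#' @return Object of class `run_config`.
#' @export
run_config <- function(generator = NULL, input_paths = NULL,
                       seg_params = segmentation_params(),
                       bins = t_level_bins(), grid_step = 0.5,
                       fixed_thresholds = NULL,
                       embryo_counts_csv = NULL,
                       output_dir = NULL, seed = NULL,
                       log_level = "info") {
  if (inherits(generator, "embryo_model"))
    generator <- list(stage1 = generator)
  structure(list(generator = generator, input_paths = input_paths,
                 seg_params = seg_params, bins = bins,
                 grid_step = grid_step,
                 fixed_thresholds = fixed_thresholds,
                 embryo_counts_csv = embryo_counts_csv,
                 output_dir = output_dir, seed = seed,
                 log_level = log_level),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Reports every violated invariant; never partially runs anything.
#'
#' @param config A [run_config()].
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  has_gen <- !is.null(config$generator)
  has_in <- !is.null(config$input_paths)
  if (has_gen == has_in)
    errs <- c(errs, "exactly one of {generator, input_paths} must be present")
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    errs <- c(errs, "field 'seed' is missing or not an integer")
  if (is.null(config$output_dir) || !nzchar(config$output_dir))
    errs <- c(errs, "field 'output_dir' is missing")
  if (!inherits(config$seg_params, "segmentation_params"))
    errs <- c(errs, "field 'seg_params' must be segmentation_params()")
  else if (config$seg_params$debris_volume_threshold < 0)
    errs <- c(errs, "field 'seg_params$debris_volume_threshold' is negative")
  if (!inherits(config$bins, "t_level_bins"))
    errs <- c(errs, "field 'bins' must be t_level_bins()")
  if (!is.numeric(config$grid_step) || config$grid_step <= 0)
    errs <- c(errs, "field 'grid_step' must be a positive AU step")
  if (has_gen) {
    ok <- vapply(config$generator, inherits, logical(1), "embryo_model")
    if (!all(ok))
      errs <- c(errs, "every generator stage must be an embryo_model()")
    if (is.null(names(config$generator)) ||
        any(!nzchar(names(config$generator))))
      errs <- c(errs, "generator stages must be named with stage labels")
  }
  errs
}

pipeline_log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(paste0("[nmpquant] ", fmt), ...))
}

#' Run the full quantification pipeline
#'
#' Orchestrates generate (or load) -> segment -> quantify -> calibrate ->
#' classify -> bin -> count -> compare for every stage in the
#' configuration, persisting every intermediate (channel TIFFs, label-map
#' TIFF, ground truth, control-ROI bounds, per-nucleus records, population
#' counts, statistics) under `output_dir`, and returns a manifest with the
#' config echo, the chosen thresholds, debris-removal counts and MD5
#' checksums of every output — enough to reproduce and audit the run.
#' Thresholds are calibrated per sample on that sample's own four control
#' regions.
#'
#' @param config A valid [run_config()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `output_dir`.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs))
    nmp_error("invalid_config",
              paste0("invalid run configuration:\n  ",
                     paste(errs, collapse = "\n  ")))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(config$seed))

  synthetic <- !is.null(config$generator)
  stage_labels <- names(if (synthetic) config$generator else
    config$input_paths)
  stages <- list()
  counts_rows <- list()

  for (lab in stage_labels) {
    pipeline_log(config, "stage %s: preparing inputs", lab)
    sdir <- file.path(out, lab)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    truth <- NULL
    controls <- NULL
    if (synthetic) {
      emb <- generate_embryo_stack(config$generator[[lab]])
      stack <- emb$stack
      truth <- emb$truth
      write_ground_truth(truth, file.path(sdir, "ground_truth.csv"))
    } else {
      ip <- config$input_paths[[lab]]
      stack <- read_image_stack(ip)
      if (!is.null(ip$control_rois))
        controls <- read_control_rois(ip$control_rois)
    }
    stack_paths <- write_image_stack(stack, sdir, prefix = "stack")

    pipeline_log(config, "stage %s: segmenting", lab)
    sp0 <- config$seg_params
    sp0$debris_volume_threshold <- 0
    pre <- segment_nuclei(stack[, , , "dapi"], sp0)
    labels <- filter_debris(pre, config$seg_params$debris_volume_threshold)
    debris_removed <- n_labels(pre) - n_labels(labels)
    write_label_map(labels, file.path(sdir, "labels.tif"))

    pipeline_log(config, "stage %s: quantifying %d nuclei", lab,
                 n_labels(labels))
    records <- quantify_nuclei(labels, stack[, , , "sox2"], stack[, , , "t"])

    if (synthetic)
      controls <- generate_control_rois(stack, truth)
    if (!is.null(controls)) {
      write_control_rois(controls, file.path(sdir, "control_rois.csv"))
      controls <- control_records(controls, records)
      thresholds <- calibrate_thresholds(controls, config$grid_step)
    } else if (!is.null(config$fixed_thresholds)) {
      thresholds <- config$fixed_thresholds
    } else {
      nmp_error("invalid_config", sprintf(
        "stage %s has neither control regions nor fixed thresholds", lab))
    }
    pipeline_log(config,
                 "stage %s: thresholds sox2 %.2f AU, t %.2f AU (control agreement %.3f)",
                 lab, thresholds$sox2_threshold, thresholds$t_threshold,
                 thresholds$accuracy)

    cl <- classify_populations(records, thresholds)
    bl <- bin_t_levels(cl$records, config$bins)
    records <- bl$records
    export_3d(records, file.path(sdir, "records.csv"))
    counts <- population_counts(records)
    counts_rows[[lab]] <- cbind(data.frame(sample = lab, stage = lab),
                                counts)
    stages[[lab]] <- list(
      outputs = c(stack_paths,
                  labels = file.path(sdir, "labels.tif"),
                  records = file.path(sdir, "records.csv"),
                  if (synthetic) c(ground_truth =
                                     file.path(sdir, "ground_truth.csv")),
                  if (!is.null(controls)) c(control_rois =
                                              file.path(sdir, "control_rois.csv"))),
      thresholds = list(sox2 = thresholds$sox2_threshold,
                        t = thresholds$t_threshold,
                        control_agreement = thresholds$accuracy),
      debris_removed = debris_removed,
      n_nuclei = nrow(records))
  }

  counts_df <- do.call(rbind, c(counts_rows, list(make.row.names = FALSE)))
  counts_path <- file.path(out, "population_counts.csv")
  write.csv(counts_df, counts_path, row.names = FALSE)

  # stage-to-stage fold changes in double positives
  stats_rows <- list()
  if (length(stage_labels) >= 2L) {
    for (k in seq_len(length(stage_labels) - 1L)) {
      fc <- fold_change(counts_df$n_double[k + 1L], counts_df$n_double[k])
      stats_rows[[k]] <- data.frame(
        pair = paste(stage_labels[k + 1L], "vs", stage_labels[k]),
        quantity = "n_double_fold_change",
        value = fc$raw, rounded = fc$rounded)
    }
  }
  stats_path <- NULL
  if (length(stats_rows)) {
    stats_path <- file.path(out, "fold_changes.csv")
    write.csv(do.call(rbind, stats_rows), stats_path, row.names = FALSE)
  }

  # optional per-embryo statistics from a supplied counts table
  tests_path <- NULL
  if (!is.null(config$embryo_counts_csv)) {
    emb <- read.csv(config$embryo_counts_csv, stringsAsFactors = FALSE)
    series <- lapply(split(emb, factor(emb$stage, levels = unique(emb$stage))),
                     function(d) stage_counts(d$stage[1], d))
    tests <- rbind(compare_stages(series, "n_double", "none"),
                   compare_stages(series, "n_double", "welch"),
                   compare_stages(series, "n_total", "none"),
                   compare_stages(series, "n_total", "welch"))
    tests_path <- file.path(out, "stage_tests.csv")
    write.csv(tests, tests_path, row.names = FALSE)
  }

  all_outputs <- c(unlist(lapply(stages, function(s) s$outputs)),
                   counts_path, stats_path, tests_path)
  manifest <- list(
    software = list(package = "nmpquant",
                    version = as.character(packageVersion("nmpquant"))),
    seed = as.integer(config$seed),
    config = serialize_config(config),
    stages = stages,
    outputs_md5 = as.list(tools::md5sum(all_outputs))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# plain-list echo of the config for the manifest (no silent defaults)
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' Read a run configuration from a YAML file
#'
#' All generator fields and the explicit seed are taken from the file;
#' see [run_config()] for the schema. Generator stages are maps of
#' [embryo_model()] arguments keyed by stage label.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  generator <- NULL
  if (!is.null(y$generator)) {
    generator <- lapply(y$generator, function(args) {
      if (!is.null(args$class_proportions))
        args$class_proportions <- unlist(args$class_proportions)
      if (!is.null(args$class_counts))
        args$class_counts <- unlist(args$class_counts)
      if (!is.null(args$background))
        args$background <- unlist(args$background)
      do.call(embryo_model, args)
    })
  }
  sp <- if (is.null(y$seg_params)) segmentation_params() else
    do.call(segmentation_params, y$seg_params)
  bn <- if (is.null(y$bins)) t_level_bins() else
    do.call(t_level_bins, lapply(y$bins, unlist))
  ft <- if (is.null(y$fixed_thresholds)) NULL else
    do.call(threshold_pair, y$fixed_thresholds)
  run_config(generator = generator, input_paths = y$input_paths,
             seg_params = sp, bins = bn,
             grid_step = if (is.null(y$grid_step)) 0.5 else y$grid_step,
             fixed_thresholds = ft,
             embryo_counts_csv = y$embryo_counts_csv,
             output_dir = y$output_dir, seed = y$seed,
             log_level = if (is.null(y$log_level)) "info" else y$log_level)
}
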