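#' Write a 3-channel stack as multi-page TIFFs
#'
#' One 8-bit multi-page TIFF per channel (dapi, sox2, t), one page per
#' z-slice.
#'
#' @param stack 4D array (z, y, x, channel) of AU intensities in [0, 255].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three file paths.
#' @export
write_image_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- dimnames(stack)[[4]]
  if (is.null(chans)) chans <- c("dapi", "sox2", "t")
  paths <- character(0)
  for (k in seq_len(dim(stack)[4])) {
    pages <- lapply(seq_len(dim(stack)[1]),
                    function(z) stack[z, , , k] / 255)
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, chans[k]))
    tiff::writeTIFF(pages, p, bits.per.sample = 8L)
    paths[chans[k]] <- p
  }
  paths
}

#' Read a 3-channel stack from per-channel multi-page TIFFs
#'
#' @param paths Named character vector (dapi, sox2, t) of TIFF paths.
#' @return 4D array (z, y, x, channel), AU in [0, 255].
#' @export
read_image_stack <- function(paths) {
  chans <- c("dapi", "sox2", "t")
  vols <- lapply(chans, function(ch) {
    pages <- tiff::readTIFF(paths[[ch]], all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    aperm(simplify2array(pages), c(3, 1, 2)) * 255
  })
  dims <- dim(vols[[1]])
  stack <- array(0, dim = c(dims, 3L),
                 dimnames = list(NULL, NULL, NULL, chans))
  for (k in seq_along(chans)) stack[, , , k] <- round(vols[[k]])
  stack
}

#' Write a label map as a 16-bit multi-page TIFF
#' @param labels 3D integer label array.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L)
    nmp_error("invalid_params", "more than 65535 labels cannot be stored in 16 bits")
  pages <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path TIFF path.
#' @return 3D integer `label_map`.
#' @export
read_label_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- aperm(simplify2array(pages), c(3, 1, 2)) * 65535
  label_map(array(as.integer(round(arr)), dim = dim(arr)))
}

#' Write/read ground truth, seeds and control-ROI definitions as CSV
#'
#' Plain-CSV serialisations of the generator ground truth (id, z, y, x,
#' volume, class, mean_sox2, mean_t), manual seed sets (id, z, y, x) and
#' control-ROI bounds (roi_id, z0, y0, x0, z1, y1, x1, expected_status).
#'
#' @param truth,seeds,controls Objects to serialise.
#' @param path CSV path.
#' @return The path (writers, invisibly) or the parsed object (readers).
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_ground_truth <- function(path) {
  truth <- read.csv(path, stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

#' @rdname csv_io
#' @export
write_seeds <- function(seeds, path) {
  write.csv(as.data.frame(seeds)[, c("id", "z", "y", "x")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_seeds <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname csv_io
#' @export
write_control_rois <- function(controls, path) {
  rows <- lapply(seq_along(controls), function(k) {
    b <- controls[[k]]$bounds
    data.frame(roi_id = k, z0 = b["z0"], y0 = b["y0"], x0 = b["x0"],
               z1 = b["z1"], y1 = b["y1"], x1 = b["x1"],
               expected_status = controls[[k]]$expected_status,
               row.names = NULL)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_control_rois <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  crops <- lapply(seq_len(nrow(df)), function(k) {
    b <- unlist(df[k, c("z0", "y0", "x0", "z1", "y1", "x1")])
    names(b) <- c("z0", "y0", "x0", "z1", "y1", "x1")
    list(bounds = b, expected_status = df$expected_status[k],
         nucleus_ids = integer())
  })
  names(crops) <- df$expected_status
  structure(crops, class = "control_roi_set")
}
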