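test_that("two separated spheres give exactly two labels", {
  dims <- c(24L, 40L, 40L)
  arr <- paint_ellipsoid(dims, c(12, 12, 12), c(5, 5, 5))
  arr <- paint_ellipsoid(dims, c(12, 28, 28), c(5, 5, 5), arr = arr)
  lab <- segment_nuclei(arr, segmentation_params(
    foreground_threshold = 50, debris_volume_threshold = 20))
  expect_identical(n_labels(lab), 2L)
})

test_that("all-background input yields zero labels, not an error", {
  dims <- c(8L, 16L, 16L)
  lab <- segment_nuclei(array(0, dims), segmentation_params(
    foreground_threshold = 50, debris_volume_threshold = 0))
  expect_identical(n_labels(lab), 0L)
  expect_identical(dim(lab), dims)
})

test_that("noiseless non-touching nuclei are recovered one-to-one", {
  m <- embryo_model(n_nuclei = 200L, noise_sd = 0,
                    attenuation_per_slice = 0, max_overlap = 0, seed = 3L)
  emb <- generate_embryo_stack(m)
  lab <- segment_nuclei(emb$stack[, , , "dapi"], small_seg_params())
  expect_identical(n_labels(lab), 200L)
  rec <- quantify_nuclei(lab, emb$stack[, , , "sox2"],
                         emb$stack[, , , "t"])
  tr <- emb$truth
  d <- vapply(seq_len(nrow(rec)), function(i)
    sqrt(min((tr$z - rec$z[i])^2 + (tr$y - rec$y[i])^2 +
             (tr$x - rec$x[i])^2)), numeric(1))
  expect_lt(max(d), 1)
})

test_that("debris filter boundary is exclusive at the threshold", {
  dims <- c(10L, 25L, 20L)             # 5000 voxels
  lab <- array(0L, dims)
  lab[1:2000] <- 1L                    # exactly at the threshold: removed
  lab[2001:4001] <- 2L                 # one voxel over: retained
  out <- filter_debris(lab, 2000)
  expect_identical(n_labels(out), 1L)
  expect_identical(sum(out == 1L), 2001L)
  # threshold 0 retains every non-empty label
  expect_identical(n_labels(filter_debris(lab, 0)), 2L)
})

test_that("debris filter matches a brute-force per-label voxel scan", {
  set.seed(42)
  dims <- c(10L, 20L, 20L)
  lab <- array(sample(0:12, prod(dims), replace = TRUE,
                      prob = c(8, rep(1, 12))), dims)
  for (thr in c(0, 15, 40, 400)) {
    out <- filter_debris(lab, thr)
    oracle_keep <- Filter(function(l) sum(lab == l) > thr, 1:12)
    expect_identical(n_labels(out), length(oracle_keep))
    # compaction preserves label order and exact volumes
    for (k in seq_along(oracle_keep))
      expect_identical(sum(out == k), sum(lab == oracle_keep[k]))
    expect_setequal(unique(as.integer(out)), c(0L, seq_along(oracle_keep)))
  }
})

test_that("raising the debris threshold never increases the retained count", {
  emb <- generate_embryo_stack(small_model(seed = 11L))
  lab <- segment_nuclei(emb$stack[, , , "dapi"],
                        small_seg_params(debris_volume_threshold = 0))
  counts <- vapply(c(0, 10, 50, 200, 1000),
                   function(thr) n_labels(filter_debris(lab, thr)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is deterministic", {
  emb <- generate_embryo_stack(small_model(seed = 12L))
  l1 <- segment_nuclei(emb$stack[, , , "dapi"], small_seg_params())
  l2 <- segment_nuclei(emb$stack[, , , "dapi"], small_seg_params())
  expect_identical(as.integer(l1), as.integer(l2))
})

test_that("seed-and-grow recovers an isolated ellipsoid within 10% of its analytic volume", {
  dims <- c(30L, 40L, 40L)
  centre <- c(15, 20, 20); radii <- c(4, 5, 6)
  arr <- paint_ellipsoid(dims, centre, radii, value = 120)
  lab <- seed_and_grow(arr, data.frame(z = 15, y = 20, x = 20),
                       segmentation_params(foreground_threshold = 60))
  truth <- ellipsoid_voxel_count(dims, centre, radii)
  expect_lt(abs(sum(lab == 1L) - truth) / truth, 0.10)
})

test_that("two seeds in one merged blob partition it into two labels", {
  dims <- c(20L, 30L, 50L)
  arr <- paint_ellipsoid(dims, c(10, 15, 20), c(6, 6, 6))
  arr <- paint_ellipsoid(dims, c(10, 15, 28), c(6, 6, 6), arr = arr)
  blob <- sum(arr > 0)
  lab <- seed_and_grow(arr, data.frame(z = c(10, 10), y = c(15, 15),
                                       x = c(20, 28)),
                       segmentation_params(foreground_threshold = 60))
  expect_identical(n_labels(lab), 2L)
  expect_identical(sum(lab > 0L), blob)    # labels partition the blob
  expect_true(all(c(1L, 2L) %in% lab))
})

test_that("a seed on background yields a minimal label and a warning", {
  dims <- c(8L, 10L, 10L)
  expect_warning(
    lab <- seed_and_grow(array(0, dims), data.frame(z = 4, y = 5, x = 5),
                         segmentation_params(foreground_threshold = 50)),
    "background")
  expect_identical(n_labels(lab), 1L)
  expect_identical(sum(lab == 1L), 1L)
  expect_match(attr(lab, "run_log"), "minimal label")
})

test_that("two-method error is the relative count difference", {
  mk_lab <- function(k) array(c(seq_len(k), rep(0L, 150 - k)),
                              c(1L, 10L, 15L))
  expect_identical(segmentation_error(mk_lab(100), mk_lab(100)), 0)
  expect_identical(segmentation_error(mk_lab(85), mk_lab(100)), 0.15)
  expect_identical(segmentation_error(mk_lab(118), mk_lab(100)), 0.18)
  expect_error(segmentation_error(mk_lab(10), mk_lab(0)),
               class = "undefined_error")
})

test_that("labels form a contiguous set after any operation", {
  emb <- generate_embryo_stack(small_model(seed = 13L))
  lab <- segment_nuclei(emb$stack[, , , "dapi"],
                        small_seg_params(debris_volume_threshold = 100))
  ids <- sort(unique(as.integer(lab)))
  expect_identical(ids, 0:(length(ids) - 1L))
})
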