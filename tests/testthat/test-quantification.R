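test_that("a uniform channel value is measured exactly", {
  dims <- c(6L, 10L, 10L)
  lab <- array(0L, dims); lab[2:4, 3:6, 3:6] <- 1L
  sox2 <- array(20, dims); tch <- array(7, dims)
  rec <- quantify_nuclei(lab, sox2, tch)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$mean_sox2, 20)
  expect_identical(rec$mean_t, 7)
  expect_identical(rec$volume, sum(lab == 1L))
  expect_true(is.na(rec$class) && is.na(rec$t_level))
})

test_that("quantification on true labels reproduces ground-truth means", {
  emb <- generate_embryo_stack(small_model(noise_sd = 0,
                                           attenuation_per_slice = 0,
                                           seed = 14L))
  rec <- quantify_nuclei(emb$labels, emb$stack[, , , "sox2"],
                         emb$stack[, , , "t"])
  expect_identical(rec$id, emb$truth$id)
  expect_true(all(abs(rec$mean_sox2 - emb$truth$mean_sox2) <= 0.5))
  expect_true(all(abs(rec$mean_t - emb$truth$mean_t) <= 0.5))
})

test_that("empty label maps and shape mismatches are handled", {
  dims <- c(4L, 6L, 6L)
  rec <- quantify_nuclei(array(0L, dims), array(0, dims), array(0, dims))
  expect_identical(nrow(rec), 0L)
  expect_error(quantify_nuclei(array(0L, dims), array(0, c(4L, 6L, 7L)),
                               array(0, dims)),
               class = "dimension_mismatch")
})

test_that("separable controls calibrate to the optimal-interval midpoint", {
  ctr <- fake_controls(a = fake_records(c(30, 30), c(2, 2)),
                       b = fake_records(c(2, 2), c(30, 30)),
                       c_ = fake_records(c(30, 2), c(2, 30)),
                       d = fake_records(c(2, 2), c(2, 2)))
  thr <- calibrate_thresholds(ctr, grid_step = 0.5)
  expect_equal(thr$accuracy, 1)
  # optimal interval is (2, 30] per channel; midpoint within one grid step
  expect_lt(abs(thr$sox2_threshold - 16.25), 0.5)
  expect_lt(abs(thr$t_threshold - 16.25), 0.5)
})

test_that("calibration optimum equals brute-force grid evaluation on overlapping controls", {
  set.seed(77)
  ctr <- fake_controls(
    a = fake_records(runif(8, 5, 40), runif(8, 0, 12)),
    b = fake_records(runif(8, 0, 12), runif(8, 5, 40)),
    c_ = fake_records(c(runif(4, 5, 40), runif(4, 0, 12)),
                      c(runif(4, 0, 12), runif(4, 5, 40))),
    d = fake_records(runif(8, 0, 15), runif(8, 0, 15)))
  grid <- seq(0, 40, by = 2)
  thr <- calibrate_thresholds(ctr, grid_step = 2, grid_range = c(0, 40))
  oracle_best <- brute_force_calibration(ctr, grid)
  expect_identical(as.integer(round(thr$accuracy * thr$n_controls)),
                   as.integer(oracle_best))
})

test_that("controls that contradict their expected status raise a calibration failure", {
  ctr <- fake_controls(a = fake_records(30, 255),
                       b = fake_records(255, 30),
                       c_ = fake_records(255, 255),
                       d = fake_records(255, 255))
  expect_error(calibrate_thresholds(ctr), class = "calibration_failure")
})

test_that("positivity is closed at the threshold", {
  thr <- threshold_pair(7, 7)
  rec <- fake_records(c(10, 6.9, 7, 2), c(10, 10, 6.99, 2))
  cl <- classify_populations(rec, thr)
  expect_identical(cl$records$class,
                   c("SOX2_T_DOUBLE", "T_ONLY", "SOX2_ONLY", "NEGATIVE"))
  expect_identical(cl$counts$n_total, 4L)
  expect_identical(cl$counts$n_double, 1L)
})

test_that("the four classes and the T levels each partition any record set", {
  set.seed(5)
  rec <- fake_records(runif(200, 0, 60), runif(200, 0, 60))
  cl <- classify_populations(rec, threshold_pair(runif(1, 0, 30),
                                                 runif(1, 0, 30)))
  with(cl$counts, expect_identical(
    n_double + n_sox2_only + n_t_only + n_negative, n_total))
  bl <- bin_t_levels(cl$records)
  expect_identical(sum(bl$level_counts), 200L)
  expect_false(anyNA(bl$records$t_level))
})

test_that("T-level bins follow the printed half-open scheme", {
  rec <- fake_records(rep(0, 8), c(6.99, 7, 11.99, 12, 24, 36, 47.9, 48))
  lv <- bin_t_levels(rec)$records$t_level
  expect_identical(lv, c("NEG", "L1", "L1", "L2", "L3", "L4", "L4", "L5"))
  expect_error(t_level_bins(edges = c(7, 12, 12, 36, 48)),
               class = "invalid_params")
  expect_error(t_level_bins(positivity = 5), class = "invalid_params")
})

test_that("raising the Sox2 threshold never increases the Sox2-positive count", {
  set.seed(6)
  rec <- fake_records(runif(300, 0, 50), runif(300, 0, 50))
  pos <- vapply(seq(0, 50, by = 5), function(ts) {
    ct <- classify_populations(rec, threshold_pair(ts, 10))$counts
    ct$n_double + ct$n_sox2_only
  }, integer(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("3D export writes one row per record and round-trips exactly", {
  rec <- fake_records(c(20, 3, 9), c(25, 2, 3))
  rec <- classify_populations(rec, threshold_pair(7, 7))$records
  rec <- bin_t_levels(rec)$records
  path <- withr::local_tempfile(fileext = ".csv")
  out <- export_3d(rec, path)
  expect_identical(nrow(out), 3L)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$class, rec$class)
  expect_equal(back$mean_sox2, rec$mean_sox2)
  # colour legend is the fixed four-population mapping
  expect_identical(out$colour, unname(population_colours()[rec$class]))
  expect_setequal(names(population_colours()),
                  c("SOX2_T_DOUBLE", "SOX2_ONLY", "T_ONLY", "NEGATIVE"))
})
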