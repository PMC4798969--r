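test_that("empty model yields a pure-noise stack and empty ground truth", {
  m <- small_model(n_nuclei = 0L, noise_sd = 3)
  emb <- generate_embryo_stack(m)
  expect_identical(nrow(emb$truth), 0L)
  expect_identical(dim(emb$stack), c(m$stack_shape, 3L))
  expect_true(all(emb$labels == 0L))
  # nothing brighter than background + noise in the marker channels
  expect_lt(max(emb$stack[, , , "sox2"]), 3 * 6)
})

test_that("a single noiseless nucleus carries its class means exactly", {
  ip <- default_intensity_params()
  ip$SOX2_T_DOUBLE <- list(sox2 = c(20, 0), t = c(15, 0))
  m <- small_model(
    n_nuclei = 1L, noise_sd = 0, attenuation_per_slice = 0,
    class_counts = c(SOX2_T_DOUBLE = 1L, SOX2_ONLY = 0L, T_ONLY = 0L,
                     NEGATIVE = 0L),
    intensity_params = ip,
    gradient_params = list(sox2_decline = 0, t_rise = 0),
    notochord_stripe = list(enabled = FALSE), background = c(dapi = 4, sox2 = 0, t = 0))
  emb <- generate_embryo_stack(m)
  vox <- emb$labels == 1L
  expect_true(all(emb$stack[, , , "sox2"][vox] == 20))
  expect_true(all(emb$stack[, , , "t"][vox] == 15))
  expect_equal(emb$truth$mean_sox2, 20)
  expect_equal(emb$truth$mean_t, 15)
})

test_that("class assignment matches an independent multinomial draw under the seed policy", {
  m <- embryo_model(n_nuclei = 500L,
                    class_proportions = c(SOX2_T_DOUBLE = 0.25,
                                          SOX2_ONLY = 0.25,
                                          T_ONLY = 0.25, NEGATIVE = 0.25),
                    seed = 1L)
  emb <- generate_embryo_stack(m)
  # oracle: the class draw is the first random call after set.seed(seed)
  set.seed(1L)
  oracle <- sample(c("SOX2_T_DOUBLE", "SOX2_ONLY", "T_ONLY", "NEGATIVE"),
                   500L, replace = TRUE, prob = rep(0.25, 4))
  got <- table(emb$truth$class)
  want <- table(oracle)
  expect_identical(names(got), names(want))
  expect_identical(as.integer(got), as.integer(want))
})

test_that("identical models generate bit-identical stacks and truth", {
  e1 <- generate_embryo_stack(small_model(seed = 9L))
  e2 <- generate_embryo_stack(small_model(seed = 9L))
  expect_identical(e1$stack, e2$stack)
  expect_identical(e1$truth, e2$truth)
  e3 <- generate_embryo_stack(small_model(seed = 10L))
  expect_false(identical(e1$stack, e3$stack))
})

test_that("intensities are clipped to the 8-bit range and quantised", {
  ip <- default_intensity_params()
  ip$SOX2_ONLY <- list(sox2 = c(254, 10), t = c(2, 1))
  m <- small_model(n_nuclei = 30L, noise_sd = 25, intensity_params = ip,
                   seed = 4L)
  emb <- generate_embryo_stack(m)
  expect_gte(min(emb$stack), 0)
  expect_lte(max(emb$stack), 255)
  expect_true(all(emb$stack == round(emb$stack)))
})

test_that("rostrocaudal gradients are monotone with noise and spread off", {
  ip <- list(SOX2_T_DOUBLE = list(sox2 = c(20, 0), t = c(18, 0)),
             SOX2_ONLY = list(sox2 = c(25, 0), t = c(2, 0)),
             T_ONLY = list(sox2 = c(2, 0), t = c(25, 0)),
             NEGATIVE = list(sox2 = c(2, 0), t = c(2, 0)))
  m <- small_model(
    n_nuclei = 30L, noise_sd = 0, attenuation_per_slice = 0,
    class_counts = c(SOX2_T_DOUBLE = 30L, SOX2_ONLY = 0L, T_ONLY = 0L,
                     NEGATIVE = 0L),
    intensity_params = ip,
    gradient_params = list(sox2_decline = 0.5, t_rise = 0.5),
    notochord_stripe = list(enabled = FALSE), seed = 5L)
  tr <- generate_embryo_stack(m)$truth
  ord <- order(tr$x)
  expect_true(all(diff(tr$mean_sox2[ord]) <= 1e-9))
  expect_true(all(diff(tr$mean_t[ord]) >= -1e-9))
})

test_that("image-recomputed per-nucleus means match ground truth within quantisation", {
  m <- small_model(noise_sd = 0, attenuation_per_slice = 0, seed = 6L)
  emb <- generate_embryo_stack(m)
  for (ch in c("sox2", "t")) {
    img <- emb$stack[, , , ch]
    truth_col <- emb$truth[[paste0("mean_", ch)]]
    got <- vapply(emb$truth$id,
                  function(i) mean(img[emb$labels == i]), numeric(1))
    expect_true(all(abs(got - truth_col) <= 0.5))
  }
})

test_that("infeasible packing raises an explicit packing-failure error", {
  m <- embryo_model(stack_shape = c(12L, 20L, 20L), n_nuclei = 400L,
                    seed = 2L)
  expect_error(generate_embryo_stack(m), class = "packing_failure")
})

test_that("control regions are pure for their expected status", {
  emb <- generate_embryo_stack(small_model(n_nuclei = 60L, seed = 8L))
  ctr <- generate_control_rois(emb)
  expect_named(ctr, c("SOX2_ONLY_REGION", "T_ONLY_REGION",
                      "MIXED_SINGLE_POSITIVES", "ALL_NEGATIVE"))
  allowed <- list(SOX2_ONLY_REGION = "SOX2_ONLY",
                  T_ONLY_REGION = "T_ONLY",
                  MIXED_SINGLE_POSITIVES = c("SOX2_ONLY", "T_ONLY"),
                  ALL_NEGATIVE = "NEGATIVE")
  for (status in names(ctr)) {
    cls <- emb$truth$class[match(ctr[[status]]$nucleus_ids, emb$truth$id)]
    expect_gte(length(cls), 1L)
    expect_true(all(cls %in% allowed[[status]]))
  }
  # ground-truth means of crop nuclei classify as their expected status
  # under thresholds separating the default class models
  for (status in c("SOX2_ONLY_REGION", "T_ONLY_REGION", "ALL_NEGATIVE")) {
    rows <- match(ctr[[status]]$nucleus_ids, emb$truth$id)
    sp <- emb$truth$mean_sox2[rows] >= 10
    tp <- emb$truth$mean_t[rows] >= 10
    expect_true(all(switch(status,
                           SOX2_ONLY_REGION = sp & !tp,
                           T_ONLY_REGION = tp & !sp,
                           ALL_NEGATIVE = !sp & !tp)))
  }
})

test_that("missing statuses raise an unsatisfiable-control error naming them", {
  m <- small_model(n_nuclei = 10L,
                   class_counts = c(SOX2_T_DOUBLE = 0L, SOX2_ONLY = 0L,
                                    T_ONLY = 0L, NEGATIVE = 10L),
                   seed = 3L)
  emb <- generate_embryo_stack(m)
  err <- tryCatch(generate_control_rois(emb), error = identity)
  expect_s3_class(err, "unsatisfiable_control")
  expect_setequal(err$statuses_missing,
                  c("SOX2_ONLY_REGION", "T_ONLY_REGION",
                    "MIXED_SINGLE_POSITIVES"))
})

test_that("stage series realises the configured double-positive profile", {
  mk <- function(ndbl, seed) small_model(
    n_nuclei = ndbl + 30L,
    class_counts = c(SOX2_T_DOUBLE = ndbl, SOX2_ONLY = 10L, T_ONLY = 10L,
                     NEGATIVE = 10L),
    seed = seed)
  series <- generate_stage_series(list(E8.5 = mk(20L, 1L),
                                       E9.5 = mk(48L, 2L),
                                       E10.5 = mk(30L, 3L)))
  dp <- vapply(series, function(e) sum(e$truth$class == "SOX2_T_DOUBLE"),
               numeric(1))
  expect_identical(unname(dp), c(20, 48, 30))   # configured rise and fall
  expect_equal(fold_change(dp[["E9.5"]], dp[["E8.5"]])$rounded, 2.4)
  # seeded determinism of the whole series
  series2 <- generate_stage_series(list(E8.5 = mk(20L, 1L),
                                        E9.5 = mk(48L, 2L),
                                        E10.5 = mk(30L, 3L)))
  expect_identical(series$E9.5$stack, series2$E9.5$stack)
  expect_error(generate_stage_series(list(only = mk(5L, 1L))),
               class = "invalid_model")
})

test_that("model invariants are enforced", {
  expect_error(small_model(class_proportions = c(SOX2_T_DOUBLE = 0.5,
                                                 SOX2_ONLY = 0.2,
                                                 T_ONLY = 0.2,
                                                 NEGATIVE = 0.2)),
               class = "invalid_model")
  expect_error(small_model(n_nuclei = -1L), class = "invalid_model")
  expect_error(small_model(nucleus_radius_range = c(0.5, 2)),
               class = "invalid_model")
  ip <- default_intensity_params()
  ip$T_ONLY$t <- c(300, 2)
  expect_error(small_model(intensity_params = ip), class = "invalid_model")
})
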