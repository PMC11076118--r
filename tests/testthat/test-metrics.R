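square_roi <- function(label = "total_tract")
  polygon_roi(label, rbind(c(2, 2), c(12, 2), c(12, 12), c(2, 12)))

test_that("a blank ROI yields zero metrics and no presence", {
  m <- occupancy_metrics(matrix(0, 16, 16), square_roi())
  expect_equal(m$mean_intensity, 0)
  expect_equal(m$median_intensity, 0)
  expect_equal(m$percent_cover, 0)
  expect_false(m$presence)
  expect_true(m$threshold_failed)
  expect_true(is.na(m$threshold_value))
  expect_equal(m$roi_area_px, 100)
})

test_that("cover is the above-threshold pixel fraction times 100", {
  img <- matrix(100, 16, 16)
  img[3:7, 3:7] <- 9000  # 25 of the 100 ROI pixels
  m <- occupancy_metrics(img, square_roi())
  expect_equal(m$percent_cover, 25.0)
  expect_true(m$presence)
  expect_gt(m$threshold_value, 100)
  expect_lt(m$threshold_value, 9000)
})

test_that("presence requires a connected component of minimum size", {
  img <- matrix(100, 16, 16)
  img[c(3, 9), c(3, 9)] <- 9000  # four isolated bright pixels
  m4 <- occupancy_metrics(img, square_roi(),
                          quant_config(min_component_px = 4L))
  m1 <- occupancy_metrics(img, square_roi(),
                          quant_config(min_component_px = 1L))
  expect_false(m4$presence)
  expect_true(m1$presence)
  expect_equal(m4$percent_cover, 4.0)
})

test_that("estimated cover tracks the simulator ground truth", {
  for (s in 1:5) {
    sim <- simulate_tract_image(imaging_params(seed = s))
    q <- quantify_sample(sim$stack, sim$rois)
    err <- q$metrics$total_tract$percent_cover -
      sim$truth$true_cover_percent[["total_tract"]]
    expect_lte(abs(err), 3)
  }
})

test_that("quantification is deterministic and logs its scalars", {
  sim <- simulate_tract_image(imaging_params(seed = 12))
  q1 <- quantify_sample(sim$stack, sim$rois)
  q2 <- quantify_sample(sim$stack, sim$rois)
  expect_identical(q1$metrics, q2$metrics)
  expect_named(q1$log,
               c("int_gfp", "int_auto", "factor", "thresholds",
                 "threshold_failed"))
  expect_true(q1$log$int_auto > 0)
})

test_that("blank tracts give near-zero cover and no presence", {
  res <- vapply(1:20, function(s) {
    sim <- simulate_tract_image(
      imaging_params(seed = s, n_puncta = 0L, n_puncta_spermatheca = 0L))
    q <- quantify_sample(sim$stack, sim$rois)
    q$metrics$total_tract$percent_cover < 1 &&
      !q$metrics$total_tract$presence
  }, TRUE)
  expect_gte(mean(res), 0.95)
})

test_that("noise-free occupancy metrics are monotone in punctum count", {
  shape <- c(64L, 64L)
  roi <- polygon_roi("total_tract",
                     rbind(c(4, 4), c(60, 4), c(60, 60), c(4, 60)))
  withr::with_seed(33, {
    base <- cbind(runif(120, 12, 52), runif(120, 12, 52))
    extra <- cbind(runif(20, 12, 52), runif(20, 12, 52))
  })
  img_for <- function(coords) {
    gfpsperm:::render_puncta(coords, rep(1200, nrow(coords)), 0.9, shape)
  }
  m1 <- occupancy_metrics(img_for(base), roi)
  m2 <- occupancy_metrics(img_for(rbind(base, extra)), roi)
  expect_gte(m2$percent_cover, m1$percent_cover)
  expect_gte(m2$mean_intensity, m1$mean_intensity)
})

test_that("quantify_sample validates its ROI inputs", {
  sim <- simulate_tract_image(imaging_params(seed = 2))
  expect_error(quantify_sample(sim$stack, sim$rois["total_tract"]),
               "autofluorescence_reference")
  expect_error(
    quantify_sample(sim$stack,
                    sim$rois["autofluorescence_reference"]),
    "no site ROI")
})
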