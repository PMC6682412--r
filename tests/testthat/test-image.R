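# Image pipeline: registration, normalization, background subtraction,
# masking, pixel OxD, watershed segmentation, filtering, measurement.

test_that("identical frames register at zero offset", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  sh <- estimate_shift(img, img, max_shift = 10)
  expect_equal(as.numeric(sh), c(0, 0))
})

test_that("integer synthetic drifts are recovered exactly", {
  sim <- suppressWarnings(simulate_timelapse(
    imaging_sim_config(field_size = c(192, 192), n_cells = 12, n_frames = 6,
                       drift_per_frame = c(3, -2), seed = 14)))
  reg <- register_stack(sim$stack)
  expect_equal(reg$offsets$dx, (0:5) * 3)
  expect_equal(reg$offsets$dy, (0:5) * -2)
  # registered chlorophyll frames coincide with frame 1 away from borders
  c1 <- get_channel(reg$stack, "chl", 1)
  c6 <- get_channel(reg$stack, "chl", 6)
  inner_r <- 20:170; inner_c <- 20:170
  expect_gt(cor(c(c1[inner_r, inner_c]), c(c6[inner_r, inner_c])), 0.98)
})

test_that("subpixel drift is recovered within half a pixel per frame", {
  sim <- simulate_timelapse(
    imaging_sim_config(field_size = c(192, 192), n_cells = 15, n_frames = 8,
                       drift_per_frame = c(0.4, 0.4), noise_sd = 20,
                       seed = 15))
  reg <- register_stack(sim$stack)
  expect_true(all(abs(reg$offsets$dx - (0:7) * 0.4) <= 0.5))
  expect_true(all(abs(reg$offsets$dy - (0:7) * 0.4) <= 0.5))
})

test_that("bit-depth normalization maps the camera range onto [0,1] and flags saturation", {
  expect_equal(normalize_bit_depth(matrix(65535), 16)[1, 1], 1.0)
  expect_equal(normalize_bit_depth(matrix(51), 8)[1, 1], 0.2)
  expect_error(normalize_bit_depth(matrix(4096), 12), "exceed")
  m <- matrix(c(0, 4095, 100, 200), 2, 2)
  nm <- normalize_bit_depth(m, 12)
  expect_equal(attr(nm, "n_saturated"), 1)
  expect_true(all(diff(order(m)) == diff(order(nm))))  # order-preserving
})

test_that("background subtraction removes the ROI mean and floors at zero", {
  img <- matrix(0.3, 32, 32)
  out <- subtract_background(img, list(x = c(0, 7), y = c(0, 7)))
  expect_true(all(out == 0))
  expect_equal(attr(out, "background"), 0.3)
  # synthetic cell on constant background drops by exactly the background
  img2 <- matrix(0.1, 32, 32); img2[15:18, 15:18] <- 0.8
  out2 <- subtract_background(img2, list(x = c(0, 7), y = c(0, 7)))
  expect_equal(out2[16, 16], 0.7)
  expect_error(subtract_background(img2, list(x = c(30, 40), y = c(0, 7))),
               "out of bounds")
  labels <- matrix(0L, 32, 32); labels[2:5, 2:5] <- 1L
  expect_warning(
    subtract_background(img2, list(x = c(0, 7), y = c(0, 7)), labels),
    "overlaps")
})

test_that("threshold and expression masks follow their definitions", {
  img <- matrix(seq(0, 1, length.out = 100), 10, 10)
  expect_equal(sum(threshold_mask(img, 0.999)), 1)
  expect_equal(sum(threshold_mask(img, 1e-9)), 99)  # all but the zero pixel
  half <- matrix(rep(c(0.2, 0.8), each = 50), 10, 10)
  expect_equal(sum(threshold_mask(half, 0.5)), 50)
  # co-localization: pixel present in only one channel mask is excluded
  a <- matrix(c(0.5, 0.5, 0, 0.5), 2, 2)
  b <- matrix(c(0.5, 0, 0.5, 0.5), 2, 2)
  m <- expression_mask(a, b, t_expr = 0.1)
  expect_identical(m, a > 0 & b > 0 & a * b > 0.1)
  expect_equal(sum(m), 2)
  # brute-force oracle on a random image
  set.seed(2)
  a2 <- matrix(runif(400), 20, 20); b2 <- matrix(runif(400), 20, 20)
  m405 <- a2 > 0.3; m488 <- b2 > 0.3
  got <- expression_mask(a2, b2, 0.25, m405, m488)
  want <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20)
    want[i, j] <- m405[i, j] && m488[i, j] && a2[i, j] * b2[i, j] > 0.25
  expect_identical(got, want)
})

test_that("pixel OxD maps mask pixels and excludes over-range values", {
  calib <- calibration_set(1, 5, 1, 1)  # linear: R = 1 + 4 oxd
  H <- 16; W <- 16
  i488 <- matrix(0.2, H, W)
  i405 <- matrix(0.2 * (1 + 4 * 0.35), H, W)   # uniform true OxD 0.35
  i405[1, 1] <- 0.2 * (1 + 4 * 1.15)           # leakage-inflated pixel
  mask <- matrix(FALSE, H, W); mask[1:8, 1:8] <- TRUE
  pm <- pixel_oxd_map(i405, i488, calib, mask)
  expect_true(all(is.nan(pm$oxd[!mask])))
  expect_equal(pm$flags[1, 1], 3L)          # > 110% -> excluded
  expect_true(is.nan(pm$oxd[1, 1]))
  inside <- pm$oxd[mask]; inside <- inside[is.finite(inside)]
  expect_equal(median(inside), 0.35, tolerance = 1e-9)
  expect_warning(pixel_oxd_map(i405, i488, calib,
                               matrix(FALSE, H, W)), "empty")
})

test_that("pixel OxD on noise-free synthetic cells equals the generating OxD", {
  cfg <- imaging_sim_config(field_size = c(128, 128), n_cells = 5,
                            n_frames = 2, noise_sd = 0, background_level = 0,
                            cell_ratio_bias_sd = 0, oxd_frame_noise_sd = 0,
                            drift_per_frame = c(0, 0), seed = 16)
  sim <- simulate_timelapse(cfg)
  an <- analyze_stack(sim$stack, cfg$calibration, register = FALSE)
  c1 <- subset(an$cells, frame == 1)
  tf <- subset(sim$truth_frames, frame == 1)
  expect_equal(nrow(c1), 5)
  for (i in seq_len(nrow(c1))) {
    k <- which.min((tf$x - c1$x[i])^2 + (tf$y - c1$y[i])^2)
    # intensities are rounded to camera counts; tolerance reflects that
    expect_lt(abs(c1$median_oxd[i] - tf$oxd[k]), 1e-3)
  }
})

test_that("per-cell OxD is invariant to common rescaling of both channels", {
  calib <- calibration_set(1, 5, 1, 0.6)
  i488 <- matrix(0.1, 8, 8); i405 <- matrix(0.25, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  a <- pixel_oxd_map(i405, i488, calib, mask)$oxd
  b <- pixel_oxd_map(3.7 * i405, 3.7 * i488, calib, mask)$oxd
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("watershed segmentation counts blobs and splits touching cells", {
  H <- 64; W <- 64
  blob <- function(cx, cy, s) {
    outer(1:H, 1:W, function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
  }
  # two well-separated blobs
  img <- blob(20, 20, 4) + blob(45, 45, 4)
  mask <- img > 0.1
  labs <- segment_cells(img, mask, smoothing_sigma = 0)
  expect_equal(length(setdiff(unique(c(labs)), 0L)), 2)
  expect_true(all(labs[!mask] == 0))
  # touching blobs with a saddle
  img2 <- blob(30, 26, 4) + blob(30, 38, 4)
  mask2 <- img2 > 0.1
  labs2 <- segment_cells(img2, mask2, smoothing_sigma = 0, tolerance = 0.05)
  expect_equal(length(setdiff(unique(c(labs2)), 0L)), 2)
  # empty mask
  expect_equal(sum(segment_cells(img, matrix(FALSE, H, W))), 0)
  # labels nest inside the mask
  expect_true(all(mask2[labs2 > 0]))
})

test_that("object filtering enforces area, axis and eccentricity bounds", {
  labs <- matrix(0L, 64, 64)
  labs[10:20, 10:20] <- 1L            # 121 px blocky object
  labs[30, 30] <- 2L                  # single pixel -> below area_min
  labs[40:41, 5:60] <- 3L             # long thin doublet-like streak
  crit <- list(area_min = 10, area_max = 400, major_axis_max = 30,
               minor_axis_min = 1, eccentricity_max = 0.97)
  out <- filter_objects(labs, crit)
  expect_true(1L %in% out$kept)
  expect_false(2L %in% out$kept)
  expect_false(3L %in% out$kept)
  expect_true("area_below_min" %in%
                out$removed$reason[out$removed$label == 2])
  expect_true(any(out$removed$label == 3))
  # permissive criteria keep everything
  out2 <- filter_objects(labs, list(area_min = 0))
  expect_equal(sort(out2$kept), c(1L, 2L, 3L))
  expect_identical(out2$labels, labs)
})

test_that("measure_cells averages OxD over defined pixels only", {
  labs <- matrix(0L, 10, 10); labs[3:6, 3:6] <- 1L
  oxd <- matrix(NaN, 10, 10)
  oxd[3:6, 3:4] <- 0.2; oxd[3:6, 5:6] <- 0.8
  rec <- measure_cells(labs, oxd)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mean_oxd, 0.5)
  expect_true(rec$median_oxd %in% c(0.2, 0.5, 0.8))
  expect_equal(rec$n_oxd_pixels, 16)
  expect_equal(rec$area, 16)
  # label with zero defined OxD pixels
  oxd2 <- matrix(NaN, 10, 10)
  rec2 <- measure_cells(labs, oxd2)
  expect_equal(rec2$n_oxd_pixels, 0)
  expect_true(is.na(rec2$mean_oxd))
})

test_that("simulator stacks are segmented with high detection and small centroid error", {
  cfg <- imaging_sim_config(seed = 17, n_frames = 3)
  sim <- simulate_timelapse(cfg)
  an <- analyze_stack(sim$stack, cfg$calibration)
  for (f in 1:3) {
    # measured centroids of a registered stack live in the frame-1
    # coordinate system, i.e. at the cells' initial positions (x0, y0)
    present <- subset(sim$truth_frames, frame == f & in_field)$cell_id
    truth <- subset(sim$truth_cells, cell_id %in% present)
    found <- subset(an$cells, frame == f)
    d <- outer(seq_len(nrow(truth)), seq_len(nrow(found)), function(i, j)
      sqrt((truth$x0[i] - found$x[j])^2 + (truth$y0[i] - found$y[j])^2))
    hits <- apply(d, 1, min) < 2
    expect_gte(mean(hits), 0.95)
  }
  # cell-free frames yield zero detections
  blank_cfg <- imaging_sim_config(n_cells = 0, n_frames = 2, seed = 18)
  blank <- simulate_timelapse(blank_cfg)
  # empty expression masks warn; cell-free frames are the expected case
  an0 <- suppressWarnings(
    analyze_stack(blank$stack, blank_cfg$calibration, register = FALSE))
  expect_equal(nrow(an0$cells), 0)
})
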