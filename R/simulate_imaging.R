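# Synthetic multi-channel time-lapse microscopy with known ground truth.
#
# Cells are rendered as uniform ellipses that stay put (settled on glass)
# while the whole field drifts; each cell carries a true OxD trajectory
# that determines its i405/i488 intensities through the inverse OxD
# mapping, and its terminal fate by exact thresholding of the true OxD at
# the decision frame. Imaging nuisances: background offset, Gaussian (and
# optionally Poisson) pixel noise, per-cell ratio bias (illumination /
# focus variability), and optional chlorophyll-to-i405 autofluorescence
# leakage.

#' Configuration for the time-lapse simulator
#'
#' Defaults emulate a 20x-magnification microfluidics field: a 256x256
#' 16-bit field with 20 settled elliptical cells imaged every 20 min for
#' 30 frames (frame 1 is the pre-treatment baseline at t = 0), slow stage
#' drift, and Sytox staining rendered at the final frame. Cell OxD
#' trajectories follow three archetypes: 'reduced' cells oxidize mildly
#' (peak ~0.45-0.65 by 20 min) then recover to 0.05-0.25; 'oxidized'
#' cells rise to ~0.97 within 20-40 min and stay; a small 'intermediate'
#' fraction plateaus between 0.55 and 0.92. A cell dies iff its true OxD
#' at the decision frame exceeds `fate_threshold_oxd`.
#'
#' @param field_size `c(height, width)` pixels.
#' @param n_cells Number of cells placed (non-overlapping) in frame 1.
#' @param n_frames Number of frames.
#' @param frame_interval Minutes between frames.
#' @param major_axis_range,minor_axis_range Semi-axis ranges (px) of the
#'   cell ellipses.
#' @param frac_oxidized Probability that a cell belongs to the 'oxidized'
#'   archetype.
#' @param intermediate_fraction Probability of the 'intermediate'
#'   archetype (the rest are 'reduced').
#' @param oxd_frame_noise_sd Per-frame jitter of the true OxD trajectory.
#' @param expression_meanlog,expression_sdlog Per-cell log-normal roGFP
#'   expression (i488 counts at full reduction).
#' @param chl_meanlog,chl_sdlog Per-cell chlorophyll intensity.
#' @param background_level Additive background (counts, all channels).
#' @param noise_sd Gaussian pixel noise sd (counts).
#' @param poisson_noise If `TRUE`, Poisson-resample pixel signal.
#' @param cell_ratio_bias_sd Log-sd of a per-cell multiplicative bias on
#'   the rendered i405/i488 ratio (per-cell measurement bias; ~0.05 log
#'   units corresponds to ~0.03 OxD near the fate threshold).
#' @param drift_per_frame `c(dx, dy)` stage drift in px per frame
#'   (applied cumulatively to all cells).
#' @param af_leakage_coeff Fraction of the chlorophyll signal leaking
#'   additively into i405 (the mechanism behind >100% apparent OxD);
#'   default 0.
#' @param fate_threshold_oxd True OxD death threshold (default 0.74).
#' @param decision_time Minutes post treatment at which fate is decided
#'   (default 40).
#' @param sytox_frame Frame index at which Sytox staining is rendered
#'   (default: last frame).
#' @param division_probability_survivors Per-frame probability that a
#'   surviving 'reduced' cell divides (daughter placed beside the mother).
#' @param fixed_oxd If set, every cell holds this true OxD in all frames
#'   (plus per-frame jitter): used to render calibration reference
#'   stacks, emulating the DTT (OxD 0) and saturating-H2O2 (OxD 1)
#'   treatments imaged on the same setup.
#' @param bit_depth Camera bit depth.
#' @param calibration [calibration_set()] of the imaging instrument.
#' @param seed Integer seed.
#' @return An `imaging_sim_config` list.
#' @export
imaging_sim_config <- function(
    field_size = c(256, 256),
    n_cells = 20,
    n_frames = 30,
    frame_interval = 20,
    major_axis_range = c(7, 10),
    minor_axis_range = c(3.5, 5),
    frac_oxidized = 0.45,
    intermediate_fraction = 0.10,
    oxd_frame_noise_sd = 0.01,
    expression_meanlog = log(4000), expression_sdlog = 0.25,
    chl_meanlog = log(8000), chl_sdlog = 0.3,
    background_level = 300,
    noise_sd = 40,
    poisson_noise = FALSE,
    cell_ratio_bias_sd = 0.05,
    drift_per_frame = c(0.8, -0.5),
    af_leakage_coeff = 0,
    fate_threshold_oxd = 0.74,
    decision_time = 40,
    sytox_frame = n_frames,
    division_probability_survivors = 0,
    fixed_oxd = NULL,
    bit_depth = 16,
    calibration = calibration_set(1.0, 5.42, i488_red = 1.0, i488_ox = 0.55,
                                  provenance = "simulated imaging references"),
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(length(field_size) == 2, n_cells >= 0, n_frames >= 1,
            frac_oxidized >= 0, intermediate_fraction >= 0,
            frac_oxidized + intermediate_fraction <= 1,
            sytox_frame >= 1, sytox_frame <= n_frames,
            is_calibration_set(calibration))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "imaging_sim_config"
  cfg
}

# Pixel membership of an ellipse centred at (cx, cy) (0-based x = col,
# y = row), semi-axes (a, b), orientation theta. Returns index matrix
# rows/cols (1-based) clipped to the field.
ellipse_pixels <- function(cx, cy, a, b, theta, H, W) {
  x0 <- max(0L, floor(cx - a)); x1 <- min(W - 1L, ceiling(cx + a))
  y0 <- max(0L, floor(cy - a)); y1 <- min(H - 1L, ceiling(cy + a))
  if (x1 < x0 || y1 < y0)
    return(list(rows = integer(0), cols = integer(0), truncated = TRUE))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- (gx * ct + gy * st) / a
  v <- (-gx * st + gy * ct) / b
  inside <- u * u + v * v <= 1
  truncated <- (cx - a < 0) || (cx + a > W - 1) ||
               (cy - a < 0) || (cy + a > H - 1)
  list(rows = rep(ys, times = length(xs))[inside] + 1L,
       cols = rep(xs, each = length(ys))[inside] + 1L,
       truncated = truncated)
}

# Build a per-cell true OxD trajectory (piecewise linear over time).
make_trajectory <- function(type, t_max) {
  base <- stats::rnorm(1, 0.35, 0.04)
  if (type == "reduced") {
    peak <- stats::runif(1, 0.45, 0.65)
    final <- stats::runif(1, 0.05, 0.25)
    knots <- data.frame(time = c(0, 20, 60, 480, t_max),
                        oxd = c(base, peak, peak * 0.8, final, final))
  } else if (type == "oxidized") {
    plateau <- min(stats::rnorm(1, 0.97, 0.02), 1.05)
    knots <- data.frame(time = c(0, 20, 40, t_max),
                        oxd = c(base, plateau * 0.95, plateau, plateau))
  } else {  # intermediate
    plateau <- stats::runif(1, 0.55, 0.92)
    knots <- data.frame(time = c(0, 40, t_max),
                        oxd = c(base, plateau, plateau))
  }
  knots <- knots[!duplicated(knots$time), ]
  function(t) stats::approx(knots$time, knots$oxd, xout = t, rule = 2)$y
}

#' Simulate a multi-channel time-lapse stack
#'
#' Renders i405, i488, chlorophyll and Sytox channels for every frame,
#' applies cumulative stage drift, background, noise, optional
#' autofluorescence leakage, and Sytox staining at `sytox_frame` for
#' exactly those cells whose true OxD at the decision frame exceeded the
#' fate threshold.
#'
#' @param cfg An [imaging_sim_config()].
#' @return A list with `stack` (an [image_stack()]), `truth_cells`
#'   (per-cell tibble: archetype, ellipse geometry, expression, fate,
#'   true decision OxD), `truth_frames` (per cell and frame: true centroid
#'   after drift, true OxD, in-field flag) and `config`.
#' @export
simulate_timelapse <- function(cfg) {
  stopifnot(inherits(cfg, "imaging_sim_config"))
  H <- cfg$field_size[1]; W <- cfg$field_size[2]
  calib <- cfg$calibration
  times <- (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval
  decision_frame <- nearest_frame(times, cfg$decision_time)

  with_seed(cfg$seed, {
    # --- place non-overlapping cells -----------------------------------
    margin <- max(cfg$major_axis_range) + 2
    cells <- tibble::tibble(cell_id = integer(0), x0 = numeric(0),
                            y0 = numeric(0), a = numeric(0), b = numeric(0),
                            theta = numeric(0), birth_frame = integer(0))
    placed_x <- numeric(0); placed_y <- numeric(0)
    tries <- 0L
    while (nrow(cells) < cfg$n_cells && tries < 4000L) {
      tries <- tries + 1L
      cx <- stats::runif(1, margin, W - 1 - margin)
      cy <- stats::runif(1, margin, H - 1 - margin)
      if (length(placed_x) &&
          min((placed_x - cx)^2 + (placed_y - cy)^2) < (2 * margin)^2)
        next
      placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
      cells <- dplyr::bind_rows(cells, tibble::tibble(
        cell_id = nrow(cells) + 1L, x0 = cx, y0 = cy,
        a = stats::runif(1, cfg$major_axis_range[1], cfg$major_axis_range[2]),
        b = stats::runif(1, cfg$minor_axis_range[1], cfg$minor_axis_range[2]),
        theta = stats::runif(1, 0, pi),
        birth_frame = 1L))
    }
    if (nrow(cells) < cfg$n_cells)
      warning("could only place ", nrow(cells), " of ", cfg$n_cells,
              " cells without overlap")
    n0 <- nrow(cells)
    u <- stats::runif(n0)
    cells$archetype <- ifelse(u < cfg$frac_oxidized, "oxidized",
                        ifelse(u < cfg$frac_oxidized + cfg$intermediate_fraction,
                               "intermediate", "reduced"))
    cells$expression <- clamp(
      stats::rlnorm(n0, cfg$expression_meanlog, cfg$expression_sdlog),
      1500, 10000)
    cells$chl <- clamp(stats::rlnorm(n0, cfg$chl_meanlog, cfg$chl_sdlog),
                       2000, 50000)
    cells$ratio_bias <- exp(stats::rnorm(n0, 0, cfg$cell_ratio_bias_sd))
    if (!is.null(cfg$fixed_oxd)) {
      cells$archetype <- "reference"
      traj <- replicate(n0, local({
        v <- cfg$fixed_oxd
        function(t) rep(v, length(t))
      }), simplify = FALSE)
    } else {
      traj <- lapply(cells$archetype, make_trajectory, t_max = max(times))
    }

    # optional division of surviving reduced cells
    if (cfg$division_probability_survivors > 0) {
      for (f in 2:cfg$n_frames) {
        mothers <- which(cells$archetype == "reduced" & cells$birth_frame < f)
        for (m in mothers) {
          if (stats::runif(1) < cfg$division_probability_survivors) {
            ang <- stats::runif(1, 0, 2 * pi)
            d <- 2.2 * cells$b[m]
            cells <- dplyr::bind_rows(cells, tibble::tibble(
              cell_id = nrow(cells) + 1L,
              x0 = cells$x0[m] + d * cos(ang), y0 = cells$y0[m] + d * sin(ang),
              a = cells$a[m], b = cells$b[m],
              theta = stats::runif(1, 0, pi), birth_frame = f,
              archetype = "reduced", expression = cells$expression[m],
              chl = cells$chl[m], ratio_bias = cells$ratio_bias[m]))
            traj[[nrow(cells)]] <- traj[[m]]
          }
        }
      }
    }
    n_all <- nrow(cells)

    # --- true per-frame OxD (trajectory + frame jitter) ----------------
    oxd_true <- matrix(NA_real_, n_all, cfg$n_frames)
    for (i in seq_len(n_all)) {
      v <- traj[[i]](times) + stats::rnorm(cfg$n_frames, 0, cfg$oxd_frame_noise_sd)
      oxd_true[i, ] <- clamp(v, 0, 1.05)
    }
    decision_oxd <- oxd_true[, decision_frame]
    dead <- decision_oxd > cfg$fate_threshold_oxd

    # --- render --------------------------------------------------------
    channels <- c("i405", "i488", "chl", "sytox")
    px <- array(0, dim = c(cfg$n_frames, 4L, H, W))
    scale_max <- 2^cfg$bit_depth - 1
    truth_frames <- vector("list", cfg$n_frames)
    any_truncated <- FALSE
    for (f in seq_len(cfg$n_frames)) {
      drift <- (f - 1L) * cfg$drift_per_frame
      i405 <- matrix(0, H, W); i488 <- matrix(0, H, W)
      chl <- matrix(0, H, W); syt <- matrix(0, H, W)
      cx_f <- cells$x0 + drift[1]; cy_f <- cells$y0 + drift[2]
      present <- cells$birth_frame <= f
      in_field <- present & cx_f >= 0 & cx_f <= W - 1 & cy_f >= 0 & cy_f <= H - 1
      for (i in which(present)) {
        ep <- ellipse_pixels(cx_f[i], cy_f[i], cells$a[i], cells$b[i],
                             cells$theta[i], H, W)
        if (ep$truncated) any_truncated <- TRUE
        if (!length(ep$rows)) next
        idx <- cbind(ep$rows, ep$cols)
        R <- .oxd_to_ratio_unchecked(oxd_true[i, f], calib) * cells$ratio_bias[i]
        i488[idx] <- i488[idx] + cells$expression[i]
        i405[idx] <- i405[idx] + R * cells$expression[i]
        chl[idx] <- chl[idx] + cells$chl[i]
        if (f == cfg$sytox_frame && dead[i]) {
          np <- ellipse_pixels(cx_f[i], cy_f[i], 3, 3, 0, H, W)
          if (length(np$rows))
            syt[cbind(np$rows, np$cols)] <- 20000
        }
      }
      if (cfg$af_leakage_coeff > 0) i405 <- i405 + cfg$af_leakage_coeff * chl
      for (ch in seq_along(channels)) {
        img <- switch(channels[ch], i405 = i405, i488 = i488,
                      chl = chl, sytox = syt)
        if (cfg$poisson_noise) {
          pos <- img > 0
          img[pos] <- stats::rpois(sum(pos), img[pos])
        }
        img <- img + cfg$background_level +
          matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W)
        px[f, ch, , ] <- round(clamp(img, 0, scale_max))
      }
      truth_frames[[f]] <- tibble::tibble(
        frame = f, cell_id = cells$cell_id[present],
        x = cx_f[present], y = cy_f[present],
        oxd = oxd_true[present, f],
        in_field = in_field[present],
        truncated = !(cx_f[present] - cells$a[present] >= 0 &
                      cx_f[present] + cells$a[present] <= W - 1 &
                      cy_f[present] - cells$a[present] >= 0 &
                      cy_f[present] + cells$a[present] <= H - 1))
    }
    if (any_truncated)
      warning("some cells extend beyond the field after drift; ",
              "clipped at the border (recorded in ground truth)")

    truth_frames <- dplyr::bind_rows(truth_frames)

    stack <- image_stack(px, channels, times, bit_depth = cfg$bit_depth)
    truth_cells <- tibble::tibble(
      cell_id = cells$cell_id, archetype = cells$archetype,
      x0 = cells$x0, y0 = cells$y0, a = cells$a, b = cells$b,
      theta = cells$theta, birth_frame = cells$birth_frame,
      expression = cells$expression, chl = cells$chl,
      ratio_bias = cells$ratio_bias,
      decision_oxd = decision_oxd, dead = dead)
    list(stack = stack, truth_cells = truth_cells,
         truth_frames = truth_frames,
         decision_frame = decision_frame, config = cfg)
  })
}

# Index of the frame whose time is nearest to `t` (ties -> earlier frame).
nearest_frame <- function(frame_times, t) {
  d <- abs(frame_times - t)
  which(d == min(d))[1]
}
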