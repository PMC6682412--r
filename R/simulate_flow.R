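# Synthetic flow-cytometry experiments with known ground truth.
#
# The generator emulates the statistical structure of a chloroplast-roGFP
# oxidative-stress experiment: after an H2O2 pulse the population splits
# into a 'reduced' subpopulation that oxidizes mildly and then recovers,
# and an 'oxidized' subpopulation pinned at ~100% OxD; the oxidized
# fraction is dose dependent, and the dead fraction at the final
# timepoint follows a linear function of the oxidized fraction.

# Evaluate with a fixed seed and restore the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Configuration for the flow-cytometry simulator
#'
#' Defaults describe the emulated study conditions: H2O2 doses spanning
#' 0-200 uM with a monotone dose-to-oxidized-fraction map; a 'reduced'
#' subpopulation trajectory that starts at 35% OxD, peaks near 40% within
#' ~10-20 min and recovers to 15% by 8 h; an 'oxidized' subpopulation at
#' ~100% OxD; and a death line `dead = 1.09 * frac_oxidized - 0.16`
#' evaluated at the final timepoint. Between-replicate variability enters
#' through a jitter on the oxidized fraction (`frac_replicate_sd`) and an
#' additive noise on the realized dead fraction (`dead_replicate_sd`).
#'
#' @param doses H2O2 doses (uM) to simulate; each must appear in
#'   `frac_oxidized_by_dose`.
#' @param timepoints Minutes post treatment; the last is the terminal
#'   (Sytox-stained) timepoint.
#' @param n_events_per_sample Events per (dose, timepoint, replicate).
#' @param replicates Number of biological replicates.
#' @param frac_oxidized_by_dose Named numeric vector mapping dose (uM, as
#'   names) to the stationary oxidized fraction in \[0, 1\].
#' @param reduced_oxd_knots data.frame with columns `time` (min) and `oxd`:
#'   piecewise-linear OxD trajectory of the 'reduced' subpopulation.
#' @param oxidized_oxd Mean OxD of the 'oxidized' subpopulation (~1).
#' @param oxd_noise_sd Cell-to-cell OxD spread within a subpopulation.
#' @param overshoot_amp,overshoot_time,overshoot_width Transient excess of
#'   the oxidized fraction around `overshoot_time` min (some early-oxidized
#'   cells later recover), as a Gaussian bump multiplier
#'   `1 + amp * exp(-((t - time) / width)^2 / 2)`.
#' @param expression_meanlog,expression_sdlog Log-normal parameters of
#'   roGFP expression (scales both i405 and i488).
#' @param af_meanlog,af_sdlog Log-normal parameters of the
#'   autofluorescence-only (roGFP-negative) intensity cloud.
#' @param wt_af_fraction Fraction of autofluorescence-only events.
#' @param channel_noise_sd Multiplicative (log-normal sd) measurement noise
#'   per channel.
#' @param death_line `c(slope, intercept)` linking the stationary oxidized
#'   fraction to the terminal dead fraction.
#' @param frac_replicate_sd Between-replicate sd of the oxidized fraction.
#' @param dead_replicate_sd Between-replicate variability of the dead
#'   fraction, expressed as the sd at a dead fraction of 0.5; the
#'   realized sd scales as `2 * sqrt(p * (1 - p))` so it vanishes at the
#'   \[0, 1\] bounds (binomial-like), keeping the generating death line
#'   unbiased.
#' @param calibration A [calibration_set()] used to turn true OxD into
#'   (i405, i488) intensities.
#' @param seed Integer seed; a fixed seed reproduces the tables exactly.
#' @return A `flow_sim_config` list.
#' @export
flow_sim_config <- function(
    doses = c(0, 50, 80, 100),
    timepoints = c(2, 10, 20, 30, 60, 90, 120, 1440),
    n_events_per_sample = 2000,
    replicates = 3,
    frac_oxidized_by_dose = c("0" = 0.02, "30" = 0.10, "50" = 0.25,
                              "80" = 0.55, "100" = 0.75, "150" = 0.88,
                              "200" = 0.97),
    reduced_oxd_knots = data.frame(
      time = c(0, 10, 60, 480, 1440),
      oxd = c(0.35, 0.40, 0.30, 0.15, 0.15)),
    oxidized_oxd = 1.0,
    oxd_noise_sd = 0.03,
    overshoot_amp = 0.15, overshoot_time = 20, overshoot_width = 10,
    expression_meanlog = log(2000), expression_sdlog = 0.4,
    af_meanlog = log(30), af_sdlog = 0.5,
    wt_af_fraction = 0.10,
    channel_noise_sd = 0.01,
    death_line = c(slope = 1.09, intercept = -0.16),
    frac_replicate_sd = 0.03,
    dead_replicate_sd = 0.12,
    calibration = calibration_set(1.0, 5.57, i488_red = 1.0, i488_ox = 0.55,
                                  provenance = "simulated references"),
    seed = 1L) {
  cfg <- list(doses = doses, timepoints = sort(timepoints),
              n_events_per_sample = n_events_per_sample,
              replicates = replicates,
              frac_oxidized_by_dose = frac_oxidized_by_dose,
              reduced_oxd_knots = reduced_oxd_knots,
              oxidized_oxd = oxidized_oxd, oxd_noise_sd = oxd_noise_sd,
              overshoot_amp = overshoot_amp, overshoot_time = overshoot_time,
              overshoot_width = overshoot_width,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              af_meanlog = af_meanlog, af_sdlog = af_sdlog,
              wt_af_fraction = wt_af_fraction,
              channel_noise_sd = channel_noise_sd,
              death_line = death_line,
              frac_replicate_sd = frac_replicate_sd,
              dead_replicate_sd = dead_replicate_sd,
              calibration = calibration, seed = as.integer(seed))
  validate_flow_sim_config(cfg)
  class(cfg) <- "flow_sim_config"
  cfg
}

validate_flow_sim_config <- function(cfg) {
  miss <- setdiff(as.character(cfg$doses), names(cfg$frac_oxidized_by_dose))
  if (length(miss))
    stop("frac_oxidized_by_dose has no entry for dose(s): ",
         paste(miss, collapse = ", "))
  fr <- cfg$frac_oxidized_by_dose
  if (any(fr < 0 | fr > 1)) stop("oxidized fractions must lie in [0, 1]")
  if (cfg$n_events_per_sample <= 0) stop("n_events_per_sample must be > 0")
  if (cfg$wt_af_fraction < 0 || cfg$wt_af_fraction >= 1)
    stop("wt_af_fraction must lie in [0, 1)")
  stopifnot(is_calibration_set(cfg$calibration),
            all(c("time", "oxd") %in% names(cfg$reduced_oxd_knots)))
  invisible(cfg)
}

#' OxD of the 'reduced' subpopulation at a given time
#'
#' Piecewise-linear interpolation of the configured trajectory knots
#' (constant beyond the last knot).
#'
#' @param time_min Minutes post treatment (vectorized).
#' @param knots data.frame with columns `time`, `oxd`.
#' @return Numeric OxD fractions.
#' @export
reduced_oxd_at <- function(time_min, knots) {
  stats::approx(knots$time, knots$oxd, xout = time_min, rule = 2)$y
}

# Transient multiplier of the oxidized fraction: more cells are oxidized
# around ~20 min than at the stationary phase (some recover).
frac_time_shape <- function(t, cfg) {
  1 + cfg$overshoot_amp *
    exp(-0.5 * ((t - cfg$overshoot_time) / cfg$overshoot_width)^2)
}

#' Simulate a flow-cytometry oxidative-stress experiment
#'
#' Draws per-event intensities for every (dose, timepoint, replicate)
#' sample. roGFP-positive events belong to either the 'reduced' or
#' 'oxidized' subpopulation; their true OxD (trajectory or ~1, plus
#' cell-to-cell noise) is converted to a ratio via the inverse OxD mapping
#' and scaled by a log-normal expression level, so the intensities carry
#' the configured oxidation signal exactly. A configurable fraction of
#' events is an autofluorescence-only (roGFP-negative) cloud. At the final
#' timepoint events are Sytox-labelled so that the per-replicate dead
#' fraction follows the configured death line (dead cells drawn from the
#' 'oxidized' subpopulation first).
#'
#' @param cfg A [flow_sim_config()].
#' @return A list with elements `events` (tibble: event_id, sample_id,
#'   dose_uM, time_min, replicate, i405, i488, chl, sytox), `truth`
#'   (tibble: event_id plus subpopulation label, true OxD, true death
#'   label), `calibration` and `config`.
#' @export
simulate_flow_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "flow_sim_config"))
  validate_flow_sim_config(cfg)
  calib <- cfg$calibration
  t_final <- max(cfg$timepoints)
  with_seed(cfg$seed, {
    # per (dose, replicate) biological offsets, constant across timepoints
    grid_dr <- expand.grid(dose = cfg$doses, replicate = seq_len(cfg$replicates))
    grid_dr$frac_jit <- stats::rnorm(nrow(grid_dr), 0, cfg$frac_replicate_sd)
    grid_dr$dead_jit <- stats::rnorm(nrow(grid_dr), 0, cfg$dead_replicate_sd)

    out_e <- vector("list", 0L)
    out_t <- vector("list", 0L)
    next_id <- 1L
    for (i in seq_len(nrow(grid_dr))) {
      dose <- grid_dr$dose[i]; rep_i <- grid_dr$replicate[i]
      f_stat <- clamp(cfg$frac_oxidized_by_dose[[as.character(dose)]] +
                        grid_dr$frac_jit[i], 0, 0.99)
      dead_base <- clamp(cfg$death_line[[1]] * f_stat +
                           cfg$death_line[[2]], 0, 1)
      dead_target <- clamp(dead_base + grid_dr$dead_jit[i] *
                             2 * sqrt(dead_base * (1 - dead_base)), 0, 1)
      for (tp in cfg$timepoints) {
        n <- cfg$n_events_per_sample
        is_af <- stats::runif(n) < cfg$wt_af_fraction
        n_af <- sum(is_af); n_ro <- n - n_af
        f_t <- clamp(f_stat * frac_time_shape(tp, cfg), 0, 0.995)
        is_ox <- stats::runif(n_ro) < f_t
        true_oxd <- ifelse(
          is_ox,
          stats::rnorm(n_ro, cfg$oxidized_oxd, cfg$oxd_noise_sd),
          stats::rnorm(n_ro, reduced_oxd_at(tp, cfg$reduced_oxd_knots),
                       cfg$oxd_noise_sd))
        true_oxd <- clamp(true_oxd, 0, 1.08)
        R <- .oxd_to_ratio_unchecked(true_oxd, calib)
        expr <- stats::rlnorm(n_ro, cfg$expression_meanlog, cfg$expression_sdlog)
        i488 <- expr * stats::rlnorm(n_ro, 0, cfg$channel_noise_sd)
        i405 <- R * expr * stats::rlnorm(n_ro, 0, cfg$channel_noise_sd)
        af405 <- stats::rlnorm(n_af, cfg$af_meanlog, cfg$af_sdlog)
        af488 <- stats::rlnorm(n_af, cfg$af_meanlog, cfg$af_sdlog)
        chl <- stats::rlnorm(n, log(800), 0.3)

        # terminal fate: only realized (stained) at the final timepoint
        dead <- rep(NA, n_ro)
        if (tp == t_final) {
          n_dead <- round(dead_target * n_ro)
          ord <- order(!is_ox, -true_oxd)  # oxidized cells die first
          dead <- logical(n_ro)
          dead[ord[seq_len(n_dead)]] <- TRUE
        }
        sytox_ro <- stats::rlnorm(n_ro, log(5), 0.5)
        if (tp == t_final)
          sytox_ro[dead] <- stats::rlnorm(sum(dead), log(500), 0.3)
        sytox_af <- stats::rlnorm(n_af, log(5), 0.5)

        ids <- next_id:(next_id + n - 1L); next_id <- next_id + n
        sample_id <- sprintf("d%s_t%s_r%d", dose, tp, rep_i)
        out_e[[length(out_e) + 1L]] <- tibble::tibble(
          event_id = c(ids[!is_af], ids[is_af]),
          sample_id = sample_id, dose_uM = dose, time_min = tp,
          replicate = rep_i,
          i405 = c(i405, af405), i488 = c(i488, af488),
          chl = c(chl[!is_af], chl[is_af]),
          sytox = c(sytox_ro, sytox_af))
        out_t[[length(out_t) + 1L]] <- tibble::tibble(
          event_id = c(ids[!is_af], ids[is_af]),
          sample_id = sample_id, dose_uM = dose, time_min = tp,
          replicate = rep_i,
          subpopulation = c(ifelse(is_ox, "oxidized", "reduced"),
                            rep("af", n_af)),
          true_oxd = c(true_oxd, rep(NA_real_, n_af)),
          dead = c(dead, rep(NA, n_af)),
          frac_oxidized_true = f_t,
          frac_oxidized_stationary = f_stat,
          dead_fraction_true = if (tp == t_final) dead_target else NA_real_)
      }
    }
    events <- dplyr::arrange(dplyr::bind_rows(out_e), event_id)
    truth <- dplyr::arrange(dplyr::bind_rows(out_t), event_id)
    list(events = events, truth = truth, calibration = calib, config = cfg)
  })
}

#' Simulate fully reduced / fully oxidized reference samples
#'
#' Generates the DTT-like (OxD = 0) and saturating-H2O2-like (OxD = 1)
#' reference event sets used to estimate a [calibration_set()] and the
#' probe's dynamic range from data.
#'
#' @param calib True instrument calibration used for rendering.
#' @param n Events per reference sample.
#' @param expression_meanlog,expression_sdlog,channel_noise_sd As in
#'   [flow_sim_config()].
#' @param seed Integer seed.
#' @return A list of two tibbles, `reduced` and `oxidized`, with columns
#'   `i405`, `i488` and `ratio`.
#' @export
simulate_reference_samples <- function(calib, n = 5000,
                                       expression_meanlog = log(2000),
                                       expression_sdlog = 0.4,
                                       channel_noise_sd = 0.01,
                                       seed = 1L) {
  stopifnot(is_calibration_set(calib))
  with_seed(seed, {
    one <- function(oxd, i488_scale) {
      R <- .oxd_to_ratio_unchecked(oxd, calib)
      expr <- stats::rlnorm(n, expression_meanlog, expression_sdlog)
      i488 <- i488_scale * expr * stats::rlnorm(n, 0, channel_noise_sd)
      i405 <- R * (expr * i488_scale) * stats::rlnorm(n, 0, channel_noise_sd)
      tibble::tibble(i405 = i405, i488 = i488, ratio = i405 / i488)
    }
    list(reduced = one(0, calib$i488_red / calib$i488_red),
         oxidized = one(1, calib$i488_ox / calib$i488_red))
  })
}

# ---- ground-truth / table serialization --------------------------------

# Lossless CSV: doubles rendered with 17 significant digits so that
# write -> read reproduces the numeric values exactly.
write_table_lossless <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Write / read ground-truth tables
#'
#' Ground truth (and any other tidy table produced by the simulators) is
#' stored as CSV with full-precision numerics, so a write-then-read
#' round-trip reproduces the values exactly.
#'
#' @param truth A data.frame / tibble.
#' @param path CSV file path.
#' @return `export_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns a tibble.
#' @export
export_ground_truth <- function(truth, path) {
  write_table_lossless(truth, path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
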