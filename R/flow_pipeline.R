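# Flow-cytometry analysis: gating, per-event OxD, subpopulation
# splitting, dose/time courses, dead fractions, and the
# death-versus-oxidation linear model.

required_event_columns <- c("i405", "i488", "chl", "sample_id",
                            "dose_uM", "time_min", "replicate")

#' Read / write event tables
#'
#' Event tables are CSV files with one row per flow-cytometry event and
#' columns `i405`, `i488`, `chl`, optional `sytox`, `sample_id`,
#' `dose_uM`, `time_min`, `replicate` (extra columns are kept). Reading
#' validates the schema and that intensity columns are numeric and
#' non-negative.
#'
#' @param path CSV file path.
#' @param events A data.frame of events.
#' @return `read_event_table` returns a tibble; `write_event_table`
#'   returns `path` invisibly.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_event_columns, names(df))
  if (length(miss))
    stop("event table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in intersect(c("i405", "i488", "chl", "sytox"), names(df))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric values in intensity column '", col, "' (rows ",
           paste(utils::head(bad, 5), collapse = ", "), ")")
    }
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative intensities in column '", col, "'")
    df[[col]] <- as.numeric(df[[col]])
  }
  tibble::as_tibble(df)
}

#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  write_table_lossless(events, path)
}

#' Gate roGFP-positive events
#'
#' roGFP-positive cells are separated from the autofluorescence-only
#' cloud by the relative roGFP expression level, measured as the product
#' `i405 * i488`; events above `expr_threshold` are kept.
#'
#' @param events Event tibble.
#' @param expr_threshold Positive gate on `i405 * i488` (a.u. squared).
#' @return A list with `gated` and `rejected` event tibbles
#'   (a partition of the input).
#' @export
gate_rogfp_positive <- function(events, expr_threshold = 1e4) {
  stopifnot(is.data.frame(events), expr_threshold > 0)
  if (nrow(events) == 0)
    return(list(gated = events, rejected = events))
  keep <- events$i405 * events$i488 > expr_threshold
  list(gated = events[keep, , drop = FALSE],
       rejected = events[!keep, , drop = FALSE])
}

#' Per-event OxD
#'
#' Computes the roGFP ratio and oxidation degree for every event, adding
#' columns `ratio`, `oxd` and `oxd_flag`. Events with i488 at or below
#' the floor are flagged `"invalid"`; OxD above the over-range cutoff is
#' flagged `"excluded"`. Flagged events stay in the table but must be
#' dropped from summaries (all summary functions in this package do so).
#'
#' @param events Gated event tibble.
#' @param calib A [calibration_set()].
#' @param i488_floor Validity floor for i488.
#' @param over_range_cutoff OxD exclusion cutoff (default 1.10).
#' @return The events tibble with `ratio`, `oxd`, `oxd_flag` columns.
#' @export
oxd_per_event <- function(events, calib, i488_floor = 1e-9,
                          over_range_cutoff = 1.10) {
  stopifnot(is.data.frame(events))
  if (!is_calibration_set(calib)) stop("a calibration_set is required")
  r <- compute_ratio(events$i405, events$i488, i488_floor = i488_floor,
                     on_invalid = "na")
  ox <- compute_oxd(r, calib, over_range_cutoff = over_range_cutoff)
  events$ratio <- r
  events$oxd <- ox$value
  events$oxd_flag <- ox$flag
  events
}

# OxD values usable in summaries: finite and not excluded/invalid.
usable_oxd <- function(oxd, flag) {
  oxd[is.finite(oxd) & flag %in% c("in_range", "over_range")]
}

#' Split an OxD distribution into 'oxidized' and 'reduced' subpopulations
#'
#' Locates the boundary between the two modes of a bimodal OxD
#' distribution and reports the fraction of events on each side. The
#' default method fits a 2-component Gaussian mixture and places the
#' threshold where the weighted component densities cross between the two
#' means; `"valley"` uses the minimum of a kernel density estimate
#' between the two dominant modes; `"fixed"` applies a user cutoff.
#' A mixture/valley split is accepted only if the component separation
#' exceeds twice the pooled within-component sd and the minor component
#' weight exceeds 2%; otherwise the input is declared unimodal and a
#' degenerate split (fraction 0 or 1, by the side of `fixed_cutoff` the
#' bulk lies on) is returned with `unimodal = TRUE`.
#'
#' @param oxd Numeric vector of per-event OxD (already filtered of
#'   excluded/invalid values).
#' @param method `"mixture"` (default), `"valley"`, or `"fixed"`.
#' @param min_events Minimum number of events required (default 200);
#'   fewer is an error for mixture/valley (fixed still works).
#' @param fixed_cutoff Cutoff for `method = "fixed"`, and the fallback
#'   boundary used to orient degenerate splits (default 0.6).
#' @return A list: `threshold_oxd`, `frac_oxidized`, `frac_reduced`,
#'   `method`, `n_events`, `unimodal`.
#' @export
split_subpopulations <- function(oxd, method = c("mixture", "valley", "fixed"),
                                 min_events = 200, fixed_cutoff = 0.6) {
  method <- match.arg(method)
  oxd <- oxd[is.finite(oxd)]
  n <- length(oxd)
  res <- function(threshold, unimodal = FALSE) {
    fo <- mean(oxd > threshold)
    list(threshold_oxd = threshold, frac_oxidized = fo,
         frac_reduced = 1 - fo, method = method, n_events = n,
         unimodal = unimodal)
  }
  if (method == "fixed") {
    if (n == 0) stop("no OxD values to split")
    return(res(fixed_cutoff))
  }
  if (n < min_events)
    stop("too few events for subpopulation splitting (", n, " < ",
         min_events, ")")

  degenerate <- function() {
    thr <- fixed_cutoff
    fo <- if (stats::median(oxd) > thr) 1 else 0
    list(threshold_oxd = thr, frac_oxidized = fo, frac_reduced = 1 - fo,
         method = method, n_events = n, unimodal = TRUE)
  }

  if (method == "mixture") {
    fit <- tryCatch(
      mclust::Mclust(oxd, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(degenerate())
    mu <- fit$parameters$mean
    sd2 <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sd2) == 1) sd2 <- rep(sd2, 2)
    w <- fit$parameters$pro
    o <- order(mu)
    mu <- mu[o]; sd2 <- sd2[o]; w <- w[o]
    pooled_sd <- sqrt(sum(w * sd2^2))
    if ((mu[2] - mu[1]) <= 2 * pooled_sd || min(w) <= 0.02)
      return(degenerate())
    # threshold: crossing of the weighted component densities between means
    f <- function(x) w[1] * stats::dnorm(x, mu[1], sd2[1]) -
                     w[2] * stats::dnorm(x, mu[2], sd2[2])
    thr <- tryCatch(
      stats::uniroot(f, lower = mu[1], upper = mu[2])$root,
      error = function(e) mean(mu))
    return(res(thr))
  }

  # valley of the kernel density estimate between the two dominant modes
  d <- stats::density(oxd, n = 512)
  y <- d$y
  loc_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(loc_max) < 2) return(degenerate())
  top2 <- loc_max[order(y[loc_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  # reject shoulders: both modes must be meaningful
  if (y[top2[2]] < 0.02 * y[top2[1]]) return(degenerate())
  valley <- lo + which.min(y[lo:hi]) - 1
  thr <- d$x[valley]
  sep_sd <- stats::sd(oxd)
  if ((d$x[hi] - d$x[lo]) <= 0.5 * sep_sd) return(degenerate())
  res(thr)
}

#' Oxidized-fraction time and dose course
#'
#' Gates roGFP-positive events, computes per-event OxD, splits each
#' (dose, time, replicate) sample into subpopulations and tabulates the
#' oxidized fraction, then summarizes replicates as mean +/- SEM per
#' (dose, time).
#'
#' @param events Event tibble spanning one or more samples.
#' @param calib A [calibration_set()].
#' @param expr_threshold roGFP-positive gate on `i405 * i488`.
#' @param method,min_events,fixed_cutoff Passed to
#'   [split_subpopulations()].
#' @return A list with `samples` (one row per dose/time/replicate:
#'   `frac_oxidized`, `threshold_oxd`, `unimodal`, `n`) and `summary`
#'   (per dose/time: mean, SEM, n replicates).
#' @export
oxidized_fraction_timecourse <- function(events, calib, expr_threshold = 1e4,
                                         method = "mixture",
                                         min_events = 200,
                                         fixed_cutoff = 0.6) {
  if (!is_calibration_set(calib)) stop("a calibration_set is required")
  gated <- gate_rogfp_positive(events, expr_threshold)$gated
  gated <- oxd_per_event(gated, calib)
  samples <- gated |>
    dplyr::group_by(dose_uM, time_min, replicate) |>
    dplyr::group_modify(function(df, key) {
      ox <- usable_oxd(df$oxd, df$oxd_flag)
      sp <- split_subpopulations(ox, method = method,
                                 min_events = min(min_events, length(ox)),
                                 fixed_cutoff = fixed_cutoff)
      tibble::tibble(frac_oxidized = sp$frac_oxidized,
                     threshold_oxd = sp$threshold_oxd,
                     unimodal = sp$unimodal, n = sp$n_events)
    }) |>
    dplyr::ungroup()
  summary <- samples |>
    dplyr::group_by(dose_uM, time_min) |>
    dplyr::summarise(
      mean_frac_oxidized = mean(frac_oxidized),
      sem_frac_oxidized = stats::sd(frac_oxidized) /
        sqrt(dplyr::n()),
      n_replicates = dplyr::n(), .groups = "drop")
  list(samples = samples, summary = summary)
}

#' Sytox threshold from an unstained control
#'
#' The Sytox positivity threshold is the given quantile (default 99.9%)
#' of the unstained control sample's Sytox channel, so essentially no
#' background event is called dead.
#'
#' @param control_sytox Sytox intensities of the unstained control.
#' @param quantile Quantile used (default 0.999).
#' @return The threshold (a.u.).
#' @export
sytox_threshold_from_control <- function(control_sytox, quantile = 0.999) {
  stopifnot(length(control_sytox) > 0, quantile > 0, quantile < 1)
  as.numeric(stats::quantile(control_sytox, quantile, names = FALSE))
}

#' Dead fraction from Sytox staining
#'
#' @param events Event tibble with a `sytox` column (or a numeric vector
#'   of Sytox intensities).
#' @param sytox_threshold Positive intensity threshold above which an
#'   event is Sytox-positive (dead).
#' @return Fraction of events above the threshold, in \[0, 1\].
#' @export
dead_fraction <- function(events, sytox_threshold) {
  if (!is.numeric(sytox_threshold) || sytox_threshold <= 0)
    stop("sytox_threshold must be a positive intensity")
  s <- if (is.data.frame(events)) {
    if (!"sytox" %in% names(events)) stop("events have no 'sytox' column")
    events$sytox
  } else events
  if (length(s) == 0) stop("no events")
  mean(s > sytox_threshold)
}

#' Linear model of death versus early oxidation
#'
#' Ordinary least-squares fit of the terminal dead fraction against the
#' early (1-2 h) oxidized fraction across samples, the population-level
#' link between early chloroplast oxidation and subsequent cell death.
#'
#' @param frac_oxidized Early oxidized fractions (x).
#' @param frac_dead Terminal dead fractions (y).
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value` (of the
#'   slope), `n`, and the underlying `lm` fit.
#' @export
death_vs_oxidation_fit <- function(frac_oxidized, frac_dead) {
  stopifnot(length(frac_oxidized) == length(frac_dead))
  ok <- is.finite(frac_oxidized) & is.finite(frac_dead)
  x <- frac_oxidized[ok]; y <- frac_dead[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("degenerate x: zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = length(x), fit = fit)
}

#' CFU survival percentage
#'
#' Colony-forming-unit survival of sorted single cells: the number of
#' colonies divided by the number of sorted cells, as a percentage.
#'
#' @param n_colonies Number of colonies counted.
#' @param n_sorted Number of cells sorted (> 0).
#' @return Survival percentage in \[0, 100\].
#' @export
cfu_survival <- function(n_colonies, n_sorted) {
  stopifnot(length(n_colonies) == length(n_sorted))
  if (any(n_sorted <= 0)) stop("n_sorted must be positive")
  if (any(n_colonies < 0)) stop("n_colonies must be non-negative")
  if (any(n_colonies > n_sorted))
    stop("n_colonies exceeds n_sorted: impossible count")
  100 * n_colonies / n_sorted
}
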