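#' roGFP ratio from channel intensities
#'
#' The roGFP readout is the ratio of the 405 nm-excited to the 488
#' nm-excited emission, `R = i405 / i488`, which increases as the probe's
#' cysteines oxidize. Events or pixels whose i488 falls at or below a
#' positive floor give no stable ratio; they are either rejected with an
#' error or returned as `NA` depending on `on_invalid` (they are never
#' silently zero).
#'
#' @param i405,i488 Intensities (a.u.), vectorized.
#' @param i488_floor Positive floor under which i488 is considered too dim
#'   to divide by. Default `1e-9` (i.e. any non-positive i488 is invalid).
#' @param on_invalid `"error"` (default) to fail on any invalid i488,
#'   `"na"` to return `NA` for those entries.
#' @return Numeric vector of ratios.
#' @examples
#' compute_ratio(2, 1)            # 2
#' compute_ratio(0, 5)            # 0
#' compute_ratio(c(1, 1), c(0, 2), on_invalid = "na")  # NA 0.5
#' @export
compute_ratio <- function(i405, i488, i488_floor = 1e-9,
                          on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.numeric(i405), is.numeric(i488), i488_floor > 0)
  bad <- !is.finite(i488) | i488 <= i488_floor | !is.finite(i405)
  if (any(bad) && on_invalid == "error")
    stop("undefined ratio: i488 at or below floor (", i488_floor,
         ") for ", sum(bad), " value(s)")
  r <- i405 / i488
  r[bad] <- NA_real_
  r
}

#' Oxidation degree (OxD) of roGFP
#'
#' Maps a roGFP ratio onto the fraction of the probe pool in the oxidized
#' form:
#'
#' \deqn{OxD = \frac{R - R_{red}}{(i488_{ox}/i488_{red})\,(R_{ox} - R) + (R - R_{red})}}
#'
#' so that `OxD = 0` at the fully reduced anchor `R_red` and `OxD = 1` at
#' the fully oxidized anchor `R_ox`, with curvature set by the i488 ratio
#' of the two reference forms. On real data measured ratios can exceed
#' `R_ox` (e.g. autofluorescence leakage into i405), giving OxD above 1;
#' values above `over_range_cutoff` (default 1.10, i.e. 110%) are flagged
#' `"excluded"` and should be omitted from summaries, values in
#' (1, cutoff] are flagged `"over_range"` but retained. If the denominator
#' is non-positive (possible when `R > R_ox` with a small i488 quotient)
#' the value is undefined and returned as `NA` with flag `"excluded"` —
#' never an unflagged number.
#'
#' @param R Numeric vector of roGFP ratios (`NA` allowed; propagated with
#'   flag `"invalid"`).
#' @param calib A [calibration_set()].
#' @param over_range_cutoff OxD above which values are excluded
#'   (default 1.10).
#' @return A data.frame with columns `value` (numeric OxD, fraction) and
#'   `flag` (character: `"in_range"`, `"over_range"`, `"excluded"`,
#'   `"invalid"`).
#' @examples
#' calib <- calibration_set(1, 5, i488_red = 1, i488_ox = 0.5)
#' compute_oxd(3, calib)$value  # 0.6667
#' @export
compute_oxd <- function(R, calib, over_range_cutoff = 1.10) {
  stopifnot(is_calibration_set(calib), is.numeric(R),
            is.finite(over_range_cutoff), over_range_cutoff >= 1)
  k <- calib$i488_ox / calib$i488_red
  num <- R - calib$R_red
  den <- k * (calib$R_ox - R) + num
  value <- num / den
  flag <- rep("in_range", length(R))
  flag[!is.finite(R)] <- "invalid"
  value[!is.finite(R)] <- NA_real_
  bad_den <- is.finite(R) & den <= 0
  value[bad_den] <- NA_real_
  flag[bad_den] <- "excluded"
  ok <- is.finite(value)
  flag[ok & value > 1 & value <= over_range_cutoff] <- "over_range"
  flag[ok & value > over_range_cutoff] <- "excluded"
  data.frame(value = value, flag = flag, stringsAsFactors = FALSE)
}

# Inverse OxD -> ratio without the [0,1] domain guard; used internally by
# the simulator, which renders slightly over-oxidized cells (OxD up to
# ~1.1) to emulate leakage. Valid while 1 - x + k*x > 0.
.oxd_to_ratio_unchecked <- function(oxd, calib) {
  k <- calib$i488_ox / calib$i488_red
  den <- 1 - oxd + k * oxd
  (calib$R_red * (1 - oxd) + k * oxd * calib$R_ox) / den
}

#' Inverse mapping: OxD to roGFP ratio
#'
#' Algebraic inverse of [compute_oxd()] on the calibrated branch, used to
#' synthesize intensities with a known oxidation degree. For
#' `oxd` in \[0, 1\] the result lies in \[`R_red`, `R_ox`\] and round-trips
#' through [compute_oxd()] to machine precision.
#'
#' @param oxd Numeric vector of oxidation degrees in \[0, 1\].
#' @param calib A [calibration_set()].
#' @return Numeric vector of ratios.
#' @export
oxd_to_ratio <- function(oxd, calib) {
  stopifnot(is_calibration_set(calib), is.numeric(oxd))
  if (any(!is.finite(oxd) | oxd < 0 | oxd > 1))
    stop("oxd must lie in [0, 1]")
  .oxd_to_ratio_unchecked(oxd, calib)
}
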