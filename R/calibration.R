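#' Calibration of the roGFP ratio scale
#'
#' A calibration set holds the four scalars that anchor the mapping from
#' roGFP ratio to oxidation degree (OxD): the ratio of the fully reduced
#' probe (`R_red`, measured after DTT treatment), the ratio of the fully
#' oxidized probe (`R_ox`, measured after saturating H2O2), and the i488
#' intensities of the two reference forms (`i488_red`, `i488_ox`), whose
#' quotient sets the curvature of the OxD transform.
#'
#' @param R_red Ratio (i405/i488) of the fully reduced reference. Must be > 0.
#' @param R_ox Ratio of the fully oxidized reference. Must exceed `R_red`.
#' @param i488_red i488 intensity (a.u.) of the fully reduced reference.
#' @param i488_ox i488 intensity (a.u.) of the fully oxidized reference.
#' @param provenance Free-text note on how the references were obtained
#'   (e.g. "2 mM DTT 15-50 min / 200 uM H2O2 7-30 min").
#'
#' @return An object of class `calibration_set`.
#' @examples
#' calib <- calibration_set(R_red = 1, R_ox = 5.57, i488_red = 1, i488_ox = 0.55)
#' dynamic_range(calib)
#' @export
calibration_set <- function(R_red, R_ox, i488_red, i488_ox, provenance = "") {
  stopifnot(is.numeric(R_red), is.numeric(R_ox),
            is.numeric(i488_red), is.numeric(i488_ox),
            length(R_red) == 1L, length(R_ox) == 1L,
            length(i488_red) == 1L, length(i488_ox) == 1L)
  if (!is.finite(R_red) || R_red <= 0)
    stop("R_red must be a positive finite ratio")
  if (!is.finite(R_ox) || R_ox <= R_red)
    stop("R_ox must be finite and strictly greater than R_red")
  if (!is.finite(i488_red) || i488_red <= 0)
    stop("i488_red must be a positive finite intensity")
  if (!is.finite(i488_ox) || i488_ox <= 0)
    stop("i488_ox must be a positive finite intensity")
  structure(
    list(R_red = as.numeric(R_red), R_ox = as.numeric(R_ox),
         i488_red = as.numeric(i488_red), i488_ox = as.numeric(i488_ox),
         provenance = as.character(provenance)),
    class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("roGFP calibration set\n")
  cat(sprintf("  R_red    = %.4g   (fully reduced)\n", x$R_red))
  cat(sprintf("  R_ox     = %.4g   (fully oxidized)\n", x$R_ox))
  cat(sprintf("  i488_red = %.4g\n", x$i488_red))
  cat(sprintf("  i488_ox  = %.4g\n", x$i488_ox))
  cat(sprintf("  dynamic range R_ox/R_red = %.3f\n", dynamic_range(x)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

is_calibration_set <- function(x) inherits(x, "calibration_set")

#' Dynamic range of the probe
#'
#' The dynamic range is the ratio of the fully oxidized to the fully
#' reduced probe ratio, `R_ox / R_red`. It measures how responsive the
#' sensor is on this instrument; values well above 1 are required for a
#' usable OxD readout.
#'
#' @param calib A [calibration_set()].
#' @return The dynamic range (dimensionless, > 1).
#' @export
dynamic_range <- function(calib) {
  stopifnot(is_calibration_set(calib))
  calib$R_ox / calib$R_red
}

#' Estimate a calibration set from reference measurements
#'
#' Aggregates per-event (or per-pixel) ratios and i488 intensities of the
#' fully reduced (DTT) and fully oxidized (H2O2) reference samples into the
#' four calibration scalars. The default aggregate is the median, which is
#' robust to leakage-inflated pixels; the mean is available for
#' reproducing instrument-level dynamic-range figures computed from mean
#' ratios.
#'
#' @param red_ratio,ox_ratio Numeric vectors of i405/i488 ratios from the
#'   reduced and oxidized reference samples.
#' @param red_i488,ox_i488 Numeric vectors of i488 intensities of the same
#'   samples.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @param provenance Free-text note stored in the calibration set.
#' @return A [calibration_set()].
#' @export
estimate_calibration <- function(red_ratio, ox_ratio, red_i488, ox_i488,
                                 aggregate = c("median", "mean"),
                                 provenance = "") {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  calibration_set(
    R_red = agg(red_ratio, na.rm = TRUE),
    R_ox = agg(ox_ratio, na.rm = TRUE),
    i488_red = agg(red_i488, na.rm = TRUE),
    i488_ox = agg(ox_i488, na.rm = TRUE),
    provenance = if (nzchar(provenance)) provenance
                 else sprintf("estimated (%s aggregate)", aggregate))
}

#' Read / write calibration files
#'
#' Calibrations are serialized as small YAML key-value files carrying the
#' four scalars and the provenance string, shared by the flow-cytometry and
#' imaging pipelines.
#'
#' @param calib A [calibration_set()].
#' @param path File path of the YAML file.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a [calibration_set()].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(is_calibration_set(calib))
  yaml::write_yaml(unclass(calib), path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  x <- yaml::read_yaml(path)
  need <- c("R_red", "R_ox", "i488_red", "i488_ox")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("calibration file missing field(s): ", paste(miss, collapse = ", "))
  calibration_set(x$R_red, x$R_ox, x$i488_red, x$i488_ox,
                  provenance = if (is.null(x$provenance)) "" else x$provenance)
}
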