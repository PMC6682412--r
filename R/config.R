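# Run configuration: a single YAML file binding the pipeline parameters
# (calibration file, thresholds, ROI, filter criteria, tracking and fate
# settings, seed) so a whole analysis is reproducible from one document.

#' Default run configuration
#'
#' @return A nested list of all pipeline parameters with their defaults;
#'   see [image_analysis_config()] for the imaging entries.
#' @export
default_run_config <- function() {
  list(
    calibration_file = NULL,
    seed = 1L,
    flow = list(expr_threshold = 1e4,
                split_method = "mixture",
                min_events = 200,
                fixed_cutoff = 0.6,
                sytox_quantile = 0.999),
    imaging = image_analysis_config(),
    tracking = list(max_dist = 15, min_len = 6, dilation_px = 3,
                    decision_time = 40, sytox_threshold = 0.05))
}

#' Read / write a run configuration
#'
#' The YAML round-trips the structure of [default_run_config()]; missing
#' entries are filled with defaults, unknown top-level entries rejected,
#' and basic numeric ranges validated. If `calibration_file` is set it
#' must exist at load time.
#'
#' @param path YAML file path.
#' @param config A run-config list.
#' @return `read_run_config` returns the merged, validated list;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown run-config entr(ies): ", paste(unknown, collapse = ", "))
  merge2 <- function(b, u) {
    for (nm in names(u)) {
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(u[[nm]]))
        merge2(b[[nm]], u[[nm]]) else u[[nm]]
    }
    b
  }
  cfg <- merge2(base, user)
  if (!is.null(cfg$calibration_file) && !file.exists(cfg$calibration_file))
    stop("calibration file referenced by run config not found: ",
         cfg$calibration_file)
  stopifnot(cfg$flow$expr_threshold > 0,
            cfg$tracking$max_dist > 0,
            cfg$tracking$min_len >= 1,
            cfg$tracking$dilation_px >= 0,
            cfg$imaging$over_range_cutoff >= 1)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
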