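# Frame-to-frame centroid tracking, track assembly and quality filters,
# and terminal fate assignment by Sytox co-localization.

#' Optimal frame-to-frame linking
#'
#' Matches cell centroids of two adjacent frames by a one-to-one partial
#' assignment that, among assignments of maximum cardinality with all
#' pair distances below `max_dist`, minimizes the total centroid
#' distance. Solved as a maximum-weight bipartite matching (weight =
#' C - distance with C large enough that cardinality dominates), which is
#' the optimal-assignment reading of distance-minimizing particle
#' tracking; a greedy nearest-neighbour alternative is available for
#' comparison.
#'
#' @param cells_a,cells_b Data frames with columns `x`, `y` (px), one row
#'   per cell; rows are identified by index.
#' @param max_dist Maximum linking distance (px).
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return A data.frame with columns `a` and `b` (row indices into
#'   `cells_a` / `cells_b`) and `dist`; zero rows if nothing links.
#' @export
link_frames <- function(cells_a, cells_b, max_dist = 15,
                        method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(max_dist > 0)
  na <- nrow(cells_a); nb <- nrow(cells_b)
  empty <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (is.null(na) || is.null(nb) || na == 0 || nb == 0) return(empty)
  d <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((cells_a$x[i] - cells_b$x[j])^2 + (cells_a$y[i] - cells_b$y[j])^2))
  feas <- which(d <= max_dist, arr.ind = TRUE)
  if (!nrow(feas)) return(empty)

  if (method == "greedy") {
    ord <- order(d[feas])
    used_a <- logical(na); used_b <- logical(nb)
    out <- empty
    for (k in ord) {
      i <- feas[k, 1]; j <- feas[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        out <- rbind(out, data.frame(a = i, b = j, dist = d[i, j]))
      }
    }
    return(out[order(out$a), , drop = FALSE])
  }

  # optimal: max-weight bipartite matching on weights C - d
  C <- max_dist * (min(na, nb) + 1) + 1
  el <- data.frame(from = paste0("a", feas[, 1]),
                   to = paste0("b", feas[, 2]),
                   weight = C - d[feas])
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::V(g)$type <- grepl("^b", igraph::V(g)$name)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight,
                                   eps = 1e-8)
  mm <- m$matching
  a_names <- names(mm)[grepl("^a", names(mm)) & !is.na(mm)]
  if (!length(a_names)) return(empty)
  a_idx <- as.integer(sub("^a", "", a_names))
  b_idx <- as.integer(sub("^b", "", mm[a_names]))
  out <- data.frame(a = a_idx, b = b_idx,
                    dist = d[cbind(a_idx, b_idx)])
  out[order(out$a), , drop = FALSE]
}

#' Assemble tracks across frames
#'
#' Chains frame-to-frame links into tracks of strictly consecutive
#' frames; an unmatched cell starts a new track and a failed link ends
#' one (no gap closing). Tracks shorter than `min_len` consecutive
#' frames are marked unresolved, implementing the minimum-track-length
#' quality filter.
#'
#' @param cells Tibble of per-frame cell records with columns `frame`,
#'   `label`, `x`, `y` (e.g. from [analyze_stack()]).
#' @param max_dist Maximum linking distance (px).
#' @param min_len Minimum number of consecutive frames for a resolved
#'   track (default 6).
#' @param method Linking method, see [link_frames()].
#' @return A list: `cells` (input plus `track_id` column) and `tracks`
#'   (per track: id, start/end frame, length, `resolved`).
#' @export
build_tracks <- function(cells, max_dist = 15, min_len = 6,
                         method = "optimal") {
  stopifnot(all(c("frame", "label", "x", "y") %in% names(cells)))
  cells <- cells[order(cells$frame, cells$label), , drop = FALSE]
  cells$track_id <- NA_integer_
  frames <- sort(unique(cells$frame))
  next_track <- 1L
  prev_idx <- which(cells$frame == frames[1])
  cells$track_id[prev_idx] <- seq_len(length(prev_idx))
  next_track <- length(prev_idx) + 1L
  if (length(frames) > 1) {
    for (fi in 2:length(frames)) {
      cur_idx <- which(cells$frame == frames[fi])
      links <- link_frames(cells[prev_idx, , drop = FALSE],
                           cells[cur_idx, , drop = FALSE],
                           max_dist = max_dist, method = method)
      if (nrow(links))
        cells$track_id[cur_idx[links$b]] <- cells$track_id[prev_idx[links$a]]
      new <- cur_idx[is.na(cells$track_id[cur_idx])]
      if (length(new)) {
        cells$track_id[new] <- next_track:(next_track + length(new) - 1L)
        next_track <- next_track + length(new)
      }
      prev_idx <- cur_idx
    }
  }
  tr <- cells |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(start_frame = min(frame), end_frame = max(frame),
                     length = dplyr::n(), .groups = "drop")
  # consecutive by construction (a track never skips a frame)
  tr$resolved <- tr$length >= min_len
  list(cells = cells, tracks = tr)
}

#' Terminal fate of one track by Sytox co-localization
#'
#' A track is dead iff thresholded Sytox signal overlaps its cell region
#' at the Sytox frame, after dilating the region by `dilation_px` (the
#' "extended cell region": Sytox stains the nucleus, which may not
#' coincide with the segmented sensor region). Tracks absent from the
#' Sytox frame are unresolved.
#'
#' @param track_cells Rows of the per-frame cell table belonging to one
#'   track (columns `frame`, `label`).
#' @param sytox_image Numeric Sytox matrix at the Sytox frame
#'   (normalized, background-subtracted).
#' @param labels Label matrix of the Sytox frame.
#' @param sytox_frame Frame index of the Sytox image.
#' @param sytox_threshold Positivity threshold for the Sytox signal.
#' @param dilation_px Dilation radius (px) of the extended cell region
#'   (default 3).
#' @return `"dead"`, `"alive"`, or `"unresolved"`.
#' @export
assign_fate <- function(track_cells, sytox_image, labels, sytox_frame,
                        sytox_threshold, dilation_px = 3) {
  if (is.null(sytox_image)) stop("missing Sytox channel")
  row <- track_cells[track_cells$frame == sytox_frame, , drop = FALSE]
  if (nrow(row) == 0) return("unresolved")
  region <- labels == row$label[1]
  if (dilation_px > 0) {
    brush <- EBImage::makeBrush(2 * dilation_px + 1, shape = "disc")
    region <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(region * 1), brush)) > 0
    region <- matrix(region, nrow(labels), ncol(labels))
  }
  if (any(sytox_image[region] > sytox_threshold)) "dead" else "alive"
}

#' Per-track OxD at the decision time
#'
#' Returns the track's OxD at the frame nearest to `decision_time`
#' (ties broken toward the earlier frame). Unresolved if the track has
#' no record at that frame.
#'
#' @param track_cells Rows of one track (columns `frame` and the OxD
#'   column).
#' @param frame_times Frame times (minutes) of the stack.
#' @param decision_time Decision time in minutes (default 40).
#' @param oxd_column `"median_oxd"` (default) or `"mean_oxd"`.
#' @return OxD fraction, or `NA` if the track misses the decision frame.
#' @export
extract_decision_oxd <- function(track_cells, frame_times, decision_time = 40,
                                 oxd_column = "median_oxd") {
  f <- nearest_frame(frame_times, decision_time)
  row <- track_cells[track_cells$frame == f, , drop = FALSE]
  if (nrow(row) == 0) return(NA_real_)
  row[[oxd_column]][1]
}

#' Track cells and assign fates across a whole analyzed stack
#'
#' Convenience wrapper: builds tracks from [analyze_stack()] output,
#' extracts each resolved track's decision OxD and assigns its terminal
#' fate via Sytox co-localization. Tracks shorter than `min_len` frames
#' or absent at the Sytox frame are unresolved and excluded from the
#' returned fate table.
#'
#' @param analysis Result of [analyze_stack()] (needs `sytox` images).
#' @param max_dist,min_len,method Tracking parameters, see
#'   [build_tracks()].
#' @param decision_time Minutes post treatment of the fate predictor.
#' @param sytox_frame Frame index of the Sytox readout (default: last).
#' @param sytox_threshold Sytox positivity threshold (normalized scale).
#' @param dilation_px Extended-cell-region radius (px).
#' @param oxd_column Per-cell OxD summary used (`"median_oxd"` default).
#' @return A list: `cells` (with `track_id`), `tracks` (with `fate` and
#'   `decision_oxd` for every track), `fates` (resolved tracks only:
#'   `track_id`, `decision_oxd`, `died`).
#' @export
track_cells <- function(analysis, max_dist = 15, min_len = 6,
                        method = "optimal", decision_time = 40,
                        sytox_frame = length(analysis$labels),
                        sytox_threshold = 0.05, dilation_px = 3,
                        oxd_column = "median_oxd") {
  bt <- build_tracks(analysis$cells, max_dist = max_dist, min_len = min_len,
                     method = method)
  cells <- bt$cells
  tracks <- bt$tracks
  syt <- if (!is.null(analysis$sytox)) analysis$sytox[[sytox_frame]] else NULL
  labels <- analysis$labels[[sytox_frame]]
  tracks$decision_oxd <- NA_real_
  tracks$fate <- "unresolved"
  for (i in seq_len(nrow(tracks))) {
    tc <- cells[cells$track_id == tracks$track_id[i], , drop = FALSE]
    tracks$decision_oxd[i] <- extract_decision_oxd(
      tc, analysis$frame_times, decision_time, oxd_column)
    if (!tracks$resolved[i]) next  # length filter applied before fate
    f <- assign_fate(tc, syt, labels, sytox_frame, sytox_threshold,
                     dilation_px)
    tracks$fate[i] <- f
  }
  fates <- tracks[tracks$fate %in% c("dead", "alive") &
                    is.finite(tracks$decision_oxd), , drop = FALSE]
  fates <- tibble::tibble(track_id = fates$track_id,
                          decision_oxd = fates$decision_oxd,
                          died = fates$fate == "dead")
  list(cells = cells, tracks = tracks, fates = fates)
}
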