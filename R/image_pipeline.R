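# Time-lapse image analysis: translation registration, bit-depth
# normalization, background subtraction, channel and expression masks,
# pixel-wise OxD, watershed segmentation, shape filtering and per-cell
# measurements. The fixed order of operations is:
# register -> normalize -> background-subtract -> mask -> expression
# mask -> pixel OxD -> segment -> filter -> measure.

# ---- registration ------------------------------------------------------

#' Estimate the translation between two images
#'
#' Phase cross-correlation: the normalized cross-power spectrum of the
#' two images has its inverse-FFT peak at the translation of `img`
#' relative to `ref`. The integer peak is refined to subpixel precision
#' by a parabolic fit through the correlation surface around the peak.
#'
#' @param ref,img Numeric matrices of equal size.
#' @param max_shift Maximum |shift| considered per axis (px).
#' @param subpixel If `TRUE` (default), the integer peak is refined by
#'   evaluating the cross-correlation on an `1/upsample`-px grid around
#'   it with a matrix-multiply DFT.
#' @param upsample Upsampling factor of the refinement grid (default 20,
#'   i.e. 0.05 px resolution).
#' @return `c(dx, dy)`: the estimated offset of `img` relative to `ref`
#'   (x = columns, y = rows), with attribute `at_boundary` set when the
#'   estimate hits the search range.
#' @export
estimate_shift <- function(ref, img, max_shift = 48, subpixel = TRUE,
                           upsample = 20) {
  stopifnot(is.matrix(ref), is.matrix(img), all(dim(ref) == dim(img)))
  H <- nrow(ref); W <- ncol(ref)
  F1 <- stats::fft(ref - mean(ref))
  F2 <- stats::fft(img - mean(img))
  cp <- F1 * Conj(F2)
  mag <- Mod(cp)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(stats::fft(cp / mag, inverse = TRUE)) / (H * W)
  # admissible (wrapped) shifts
  sy <- c(0:(H - 1)); sy[sy > H / 2] <- sy[sy > H / 2] - H
  sx <- c(0:(W - 1)); sx[sx > W / 2] <- sx[sx > W / 2] - W
  ok <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift)
  r_ok <- r; r_ok[!ok] <- -Inf
  pk <- arrayInd(which.max(r_ok), dim(r_ok))
  py <- pk[1]; px <- pk[2]
  dy <- sy[py]; dx <- sx[px]
  at_boundary <- abs(dy) >= max_shift || abs(dx) >= max_shift
  if (subpixel && upsample > 1) {
    # evaluate the cross-correlation on a fine grid around the integer
    # peak by direct (matrix-multiply) DFT of the cross-power spectrum
    kfy <- 0:(H - 1); kfy[kfy > H / 2] <- kfy[kfy > H / 2] - H
    kfx <- 0:(W - 1); kfx[kfx > W / 2] <- kfx[kfx > W / 2] - W
    yy <- dy + seq(-1, 1, by = 1 / upsample)
    xx <- dx + seq(-1, 1, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(yy, kfy) / H)
    Ex <- exp(2i * pi * outer(kfx, xx) / W)
    r_up <- Re(Ey %*% (cp / mag) %*% Ex)
    pk2 <- arrayInd(which.max(r_up), dim(r_up))
    dy <- yy[pk2[1]]; dx <- xx[pk2[2]]
  }
  # the correlation peak sits at the negated translation; negate so the
  # return value is the offset of img relative to ref
  out <- c(dx = -dx, dy = -dy)
  attr(out, "at_boundary") <- at_boundary
  out
}

# Integer-translate an image by (dx, dy) (x = cols, y = rows), filling
# vacated pixels with `fill`.
shift_image <- function(img, dx, dy, fill = 0) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register a stack against its first frame
#'
#' Estimates each frame's XY drift relative to frame 1 on the reference
#' channel via phase cross-correlation, then translates every channel of
#' every frame by the negated, rounded offset. Pixels entering from
#' outside the field are filled with 0 and recorded as an invalid border
#' in the offsets table.
#'
#' @param stack An [image_stack()].
#' @param reference_channel Channel used for drift estimation
#'   (default `"chl"`: chlorophyll is present in every cell and frame).
#' @param max_shift Search range (px).
#' @return A list: `stack` (registered), `offsets` (tibble: frame,
#'   dx, dy estimated drift; applied integer correction; boundary flag).
#' @export
register_stack <- function(stack, reference_channel = "chl", max_shift = 48) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf < 2) stop("registration needs at least 2 frames")
  ref <- get_channel(stack, reference_channel, 1L)
  offsets <- tibble::tibble(frame = seq_len(nf), dx = 0, dy = 0,
                            applied_dx = 0L, applied_dy = 0L,
                            at_boundary = FALSE)
  out <- stack
  for (f in 2:nf) {
    sh <- estimate_shift(ref, get_channel(stack, reference_channel, f),
                         max_shift = max_shift)
    offsets$dx[f] <- sh[["dx"]]; offsets$dy[f] <- sh[["dy"]]
    offsets$at_boundary[f] <- isTRUE(attr(sh, "at_boundary"))
    adx <- as.integer(round(-sh[["dx"]])); ady <- as.integer(round(-sh[["dy"]]))
    offsets$applied_dx[f] <- adx; offsets$applied_dy[f] <- ady
    for (ch in seq_len(n_channels(stack)))
      out$pixels[f, ch, , ] <- shift_image(stack$pixels[f, ch, , ], adx, ady)
  }
  if (any(offsets$at_boundary))
    warning("drift estimate at search-range boundary for frame(s) ",
            paste(offsets$frame[offsets$at_boundary], collapse = ", "))
  list(stack = out, offsets = offsets)
}

# ---- per-frame image operations ---------------------------------------

#' Normalize an image by camera bit depth
#'
#' Divides raw counts by `2^bit_depth - 1`, mapping the camera range onto
#' \[0, 1\]. Saturated pixels (at or above the maximum representable
#' count) are counted in the `"n_saturated"` attribute; counts above the
#' representable range are an error.
#'
#' @param image Numeric matrix of raw counts.
#' @param bit_depth Camera bit depth (8, 12, 14 or 16).
#' @return The normalized matrix in \[0, 1\] with attribute
#'   `n_saturated`.
#' @export
normalize_bit_depth <- function(image, bit_depth) {
  stopifnot(bit_depth %in% c(8, 12, 14, 16))
  mx <- 2^bit_depth - 1
  if (any(image > mx, na.rm = TRUE))
    stop("pixel values exceed 2^bit_depth - 1 = ", mx)
  out <- image / mx
  attr(out, "n_saturated") <- sum(image >= mx, na.rm = TRUE)
  out
}

#' Subtract a background estimated from a cell-free ROI
#'
#' The background level is the mean intensity inside a user-defined
#' rectangular region of interest that contains no cells; it is
#' subtracted from the whole image and the result floored at 0. If a
#' label image is supplied the ROI is checked post hoc for segmented
#' cells and a warning is raised if any overlap.
#'
#' @param image Numeric matrix.
#' @param roi List with `x = c(x0, x1)` and `y = c(y0, y1)`, 0-based
#'   inclusive pixel ranges (x = columns, y = rows).
#' @param labels Optional label image used to validate the ROI.
#' @return The background-subtracted matrix with attribute `background`.
#' @export
subtract_background <- function(image, roi, labels = NULL) {
  stopifnot(is.matrix(image), is.list(roi),
            all(c("x", "y") %in% names(roi)))
  H <- nrow(image); W <- ncol(image)
  x <- as.integer(roi$x); y <- as.integer(roi$y)
  if (length(x) != 2 || length(y) != 2 || any(x < 0) || any(y < 0) ||
      x[2] >= W || y[2] >= H || x[1] > x[2] || y[1] > y[2])
    stop("roi out of bounds or empty")
  rows <- (y[1]:y[2]) + 1L; cols <- (x[1]:x[2]) + 1L
  if (!is.null(labels) && any(labels[rows, cols] > 0))
    warning("background ROI overlaps segmented cells")
  bg <- mean(image[rows, cols])
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}

#' Automatic fallback background ROI
#'
#' Scans the image in square tiles and returns the tile with the lowest
#' mean intensity, for use when no ROI was configured.
#'
#' @param image Numeric matrix.
#' @param tile Tile side (px).
#' @return An ROI list as accepted by [subtract_background()].
#' @export
auto_background_roi <- function(image, tile = 32) {
  H <- nrow(image); W <- ncol(image)
  stopifnot(tile <= H, tile <= W)
  best <- NULL; best_mean <- Inf
  for (r0 in seq(1, H - tile + 1, by = tile))
    for (c0 in seq(1, W - tile + 1, by = tile)) {
      m <- mean(image[r0:(r0 + tile - 1), c0:(c0 + tile - 1)])
      if (m < best_mean) {
        best_mean <- m
        best <- list(x = c(c0 - 1L, c0 + tile - 2L),
                     y = c(r0 - 1L, r0 + tile - 2L))
      }
    }
  best
}

#' Threshold an image into a binary mask
#'
#' @param image Numeric matrix (normalized to \[0, 1\]).
#' @param t Threshold in (0, 1).
#' @return Logical matrix, `TRUE` where `image > t`.
#' @export
threshold_mask <- function(image, t) {
  stopifnot(is.numeric(t), length(t) == 1, t > 0, t < 1)
  image > t
}

#' roGFP expression mask
#'
#' The pixel-wise roGFP expression level is the product `i405 * i488`,
#' evaluated only where both channel masks are positive; the expression
#' mask keeps pixels co-localized in both masks whose product exceeds
#' `t_expr`.
#'
#' @param i405,i488 Numeric matrices (background-subtracted, normalized).
#' @param t_expr Expression threshold on the product.
#' @param mask405,mask488 Optional precomputed channel masks; by default
#'   positivity (`> 0`) of each channel is used.
#' @return Logical matrix.
#' @export
expression_mask <- function(i405, i488, t_expr,
                            mask405 = NULL, mask488 = NULL) {
  stopifnot(all(dim(i405) == dim(i488)))
  if (is.null(mask405)) mask405 <- i405 > 0
  if (is.null(mask488)) mask488 <- i488 > 0
  mask405 & mask488 & (i405 * i488 > t_expr)
}

#' Pixel-wise OxD map
#'
#' Computes the roGFP ratio and OxD for every pixel inside the
#' expression mask; pixels outside the mask (or with i488 at the floor)
#' are set to `NaN`. Over-range pixels (OxD above the cutoff, typically
#' from autofluorescence leakage) are flagged and also set to `NaN` in
#' the returned map so they never enter per-cell summaries.
#'
#' @param i405,i488 Numeric matrices (registered, normalized,
#'   background-subtracted).
#' @param calib A [calibration_set()].
#' @param mask Logical expression mask.
#' @param i488_floor Validity floor for i488.
#' @param over_range_cutoff OxD exclusion cutoff (default 1.10).
#' @return A list: `oxd` (matrix, `NaN` outside the mask and at excluded
#'   pixels), `flags` (integer matrix: 0 outside mask / undefined,
#'   1 in-range, 2 over-range (kept), 3 excluded), `n_excluded`.
#' @export
pixel_oxd_map <- function(i405, i488, calib, mask, i488_floor = 1e-6,
                          over_range_cutoff = 1.10) {
  stopifnot(all(dim(i405) == dim(i488)), all(dim(mask) == dim(i405)))
  if (!is_calibration_set(calib)) stop("a calibration_set is required")
  if (!any(mask)) warning("empty expression mask: OxD map is empty")
  oxd <- matrix(NaN, nrow(i405), ncol(i405))
  flags <- matrix(0L, nrow(i405), ncol(i405))
  sel <- mask & i488 > i488_floor
  if (any(sel)) {
    r <- i405[sel] / i488[sel]
    res <- compute_oxd(r, calib, over_range_cutoff = over_range_cutoff)
    v <- res$value
    fl <- integer(length(v))
    fl[res$flag == "in_range"] <- 1L
    fl[res$flag == "over_range"] <- 2L
    fl[res$flag %in% c("excluded", "invalid")] <- 3L
    v[fl == 3L] <- NaN
    oxd[sel] <- v
    flags[sel] <- fl
  }
  list(oxd = oxd, flags = flags, n_excluded = sum(flags == 3L))
}

# ---- segmentation and measurement -------------------------------------

#' Watershed segmentation of cells
#'
#' Segments cells inside a binary mask using the watershed transform of
#' the (Gaussian-smoothed) seed-channel intensity, so touching cells are
#' split at the intensity saddle between them. Every labeled pixel lies
#' inside the mask.
#'
#' @param seed_image Numeric intensity matrix of the seeding channel
#'   (i405 for roGFP cells, chlorophyll for wild-type).
#' @param mask Logical mask of candidate cell pixels.
#' @param smoothing_sigma Gaussian sigma (px) applied before the
#'   watershed; default 1.
#' @param tolerance Watershed tolerance (minimum object height).
#' @param ext Watershed neighborhood radius.
#' @return Integer label matrix (0 = background).
#' @export
segment_cells <- function(seed_image, mask, smoothing_sigma = 1,
                          tolerance = 0.05, ext = 1) {
  stopifnot(all(dim(seed_image) == dim(mask)))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  img <- seed_image
  if (smoothing_sigma > 0)
    img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = smoothing_sigma)),
                  nrow(mask), ncol(mask))
  img[!mask] <- 0
  labels <- EBImage::watershed(EBImage::Image(img), tolerance = tolerance,
                               ext = ext)
  lab <- matrix(as.integer(EBImage::imageData(labels)),
                nrow(mask), ncol(mask))
  lab[!mask] <- 0L
  lab
}

# Region properties from raw and central image moments: area, centroid
# (0-based x = col, y = row), major/minor full axis lengths and
# eccentricity of the intensity-equivalent ellipse.
region_props <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(tibble::tibble(label = integer(0), area = numeric(0),
                          x = numeric(0), y = numeric(0),
                          major_axis = numeric(0), minor_axis = numeric(0),
                          eccentricity = numeric(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  x <- cols - 1; y <- rows - 1
  out <- lapply(ids, function(id) {
    s <- lab == id
    xs <- x[s]; ys <- y[s]
    n <- length(xs)
    cx <- mean(xs); cy <- mean(ys)
    # second central moments with the 1/12 pixel-variance correction
    mxx <- mean((xs - cx)^2) + 1 / 12
    myy <- mean((ys - cy)^2) + 1 / 12
    mxy <- mean((xs - cx) * (ys - cy))
    common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
    l1 <- (mxx + myy + common) / 2
    l2 <- (mxx + myy - common) / 2
    l2 <- max(l2, 1e-12)
    tibble::tibble(label = id, area = n, x = cx, y = cy,
                   major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2),
                   eccentricity = sqrt(pmax(0, 1 - l2 / l1)))
  })
  dplyr::bind_rows(out)
}

#' Filter segmented objects by shape
#'
#' Removes objects outside the configured bounds on area, axis lengths
#' and eccentricity — the standard guard against cell clumps, doublets
#' and debris. Removal reasons are recorded per object.
#'
#' @param labels Integer label matrix.
#' @param criteria List with any of `area_min`, `area_max` (px^2),
#'   `major_axis_max`, `minor_axis_min` (px), `eccentricity_max`.
#' @return A list: `labels` (filtered label matrix), `kept` (ids),
#'   `removed` (tibble: label, reason).
#' @export
filter_objects <- function(labels,
                           criteria = list(area_min = 30, area_max = 400,
                                           major_axis_max = 30,
                                           minor_axis_min = 2,
                                           eccentricity_max = 0.97)) {
  props <- region_props(labels)
  if (!nrow(props))
    return(list(labels = labels, kept = integer(0),
                removed = tibble::tibble(label = integer(0),
                                         reason = character(0))))
  reasons <- lapply(seq_len(nrow(props)), function(i) {
    p <- props[i, ]
    r <- character(0)
    if (!is.null(criteria$area_min) && p$area < criteria$area_min)
      r <- c(r, "area_below_min")
    if (!is.null(criteria$area_max) && p$area > criteria$area_max)
      r <- c(r, "area_above_max")
    if (!is.null(criteria$major_axis_max) &&
        p$major_axis > criteria$major_axis_max)
      r <- c(r, "major_axis_above_max")
    if (!is.null(criteria$minor_axis_min) &&
        p$minor_axis < criteria$minor_axis_min)
      r <- c(r, "minor_axis_below_min")
    if (!is.null(criteria$eccentricity_max) &&
        p$eccentricity > criteria$eccentricity_max)
      r <- c(r, "eccentricity_above_max")
    r
  })
  drop <- lengths(reasons) > 0
  removed <- tibble::tibble(
    label = rep(props$label, lengths(reasons)),
    reason = unlist(reasons))
  out <- labels
  out[out %in% props$label[drop]] <- 0L
  list(labels = out, kept = props$label[!drop], removed = removed)
}

#' Measure per-cell records
#'
#' One record per label: centroid, area, axis lengths, eccentricity,
#' mean/median OxD over the defined (non-NaN) pixels of the OxD map, the
#' number of such pixels, and per-channel mean intensities.
#'
#' @param labels Integer label matrix.
#' @param oxd_map OxD matrix (`NaN` where undefined), e.g. from
#'   [pixel_oxd_map()]; may be `NULL`.
#' @param channels Named list of intensity matrices to average per cell.
#' @return A tibble of cell records.
#' @export
measure_cells <- function(labels, oxd_map = NULL, channels = list()) {
  props <- region_props(labels)
  if (!nrow(props)) {
    props$mean_oxd <- numeric(0); props$median_oxd <- numeric(0)
    props$n_oxd_pixels <- integer(0)
    return(props)
  }
  mean_oxd <- rep(NA_real_, nrow(props))
  median_oxd <- rep(NA_real_, nrow(props))
  n_oxd <- integer(nrow(props))
  for (ch in names(channels))
    props[[paste0("mean_", ch)]] <- rep(NA_real_, nrow(props))
  for (i in seq_len(nrow(props))) {
    sel <- labels == props$label[i]
    if (!is.null(oxd_map)) {
      v <- oxd_map[sel]
      v <- v[is.finite(v)]
      n_oxd[i] <- length(v)
      if (length(v)) {
        mean_oxd[i] <- mean(v)
        median_oxd[i] <- stats::median(v)
      }
    }
    for (ch in names(channels))
      props[[paste0("mean_", ch)]][i] <- mean(channels[[ch]][sel])
  }
  props$mean_oxd <- mean_oxd
  props$median_oxd <- median_oxd
  props$n_oxd_pixels <- n_oxd
  props
}

# ---- full pipeline -----------------------------------------------------

#' Default image-analysis configuration
#'
#' Per-channel mask thresholds are on the bit-depth-normalized,
#' background-subtracted scale; defaults were chosen on synthetic stacks
#' rendered at the package's default imaging conditions.
#'
#' @return A list of pipeline parameters.
#' @export
image_analysis_config <- function() {
  list(reference_channel = "chl",
       max_shift = 48,
       background_roi = NULL,        # NULL -> auto lowest-intensity tile
       t_i405 = 0.01, t_i488 = 0.01, t_chl = 0.01,
       t_expr = 2e-4,
       i488_floor = 1e-6,
       over_range_cutoff = 1.10,
       smoothing_sigma = 1, watershed_tolerance = 0.02, watershed_ext = 3,
       filter_criteria = list(area_min = 30, area_max = 400,
                              major_axis_max = 30, minor_axis_min = 2,
                              eccentricity_max = 0.97),
       seed_channel = "i405",
       oxd_summary = "median")
}

#' Run the full image pipeline on a stack
#'
#' Applies the fixed stage order (register, normalize, background
#' subtract, mask, expression mask, pixel OxD, segment, filter, measure)
#' to every frame and returns per-frame cell records plus QC information.
#'
#' @param stack An [image_stack()] with channels i405, i488, chl (and
#'   optionally sytox).
#' @param calib A [calibration_set()] from imaged reference treatments.
#' @param config See [image_analysis_config()].
#' @param register If `FALSE`, skip registration (e.g. already-registered
#'   or single-frame stacks).
#' @return A list: `cells` (tibble of per-frame cell records), `offsets`
#'   (registration table or `NULL`), `labels` (list of per-frame label
#'   matrices), `sytox` (list of per-frame normalized sytox images, if
#'   present), `qc` (per-frame background levels, object counts, removal
#'   reasons).
#' @export
analyze_stack <- function(stack, calib, config = image_analysis_config(),
                          register = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  offsets <- NULL
  if (register && n_frames(stack) >= 2) {
    reg <- register_stack(stack, config$reference_channel,
                          max_shift = config$max_shift)
    stack <- reg$stack
    offsets <- reg$offsets
  }
  nf <- n_frames(stack)
  has_sytox <- "sytox" %in% stack$channel_names
  cells <- vector("list", nf)
  labels_out <- vector("list", nf)
  sytox_out <- if (has_sytox) vector("list", nf) else NULL
  qc <- vector("list", nf)
  for (f in seq_len(nf)) {
    i405 <- normalize_bit_depth(get_channel(stack, "i405", f), stack$bit_depth)
    i488 <- normalize_bit_depth(get_channel(stack, "i488", f), stack$bit_depth)
    chl <- normalize_bit_depth(get_channel(stack, "chl", f), stack$bit_depth)
    roi <- config$background_roi
    if (is.null(roi)) roi <- auto_background_roi(chl)
    bgs <- numeric(3)
    i405 <- subtract_background(i405, roi); bgs[1] <- attr(i405, "background")
    i488 <- subtract_background(i488, roi); bgs[2] <- attr(i488, "background")
    chl <- subtract_background(chl, roi); bgs[3] <- attr(chl, "background")
    m405 <- threshold_mask(i405, config$t_i405)
    m488 <- threshold_mask(i488, config$t_i488)
    mchl <- threshold_mask(chl, config$t_chl)
    mexpr <- expression_mask(i405, i488, config$t_expr, m405, m488)
    po <- pixel_oxd_map(i405, i488, calib, mexpr,
                        i488_floor = config$i488_floor,
                        over_range_cutoff = config$over_range_cutoff)
    seed_img <- switch(config$seed_channel, i405 = i405, i488 = i488,
                       chl = chl)
    seed_mask <- if (config$seed_channel == "chl") mchl else m405
    labs <- segment_cells(seed_img, seed_mask,
                          smoothing_sigma = config$smoothing_sigma,
                          tolerance = config$watershed_tolerance,
                          ext = config$watershed_ext)
    filt <- filter_objects(labs, config$filter_criteria)
    rec <- measure_cells(filt$labels, po$oxd,
                         channels = list(i405 = i405, i488 = i488, chl = chl))
    if (nrow(rec)) rec$frame <- f else rec$frame <- integer(0)
    cells[[f]] <- rec
    labels_out[[f]] <- filt$labels
    if (has_sytox) {
      syt <- normalize_bit_depth(get_channel(stack, "sytox", f),
                                 stack$bit_depth)
      sytox_out[[f]] <- subtract_background(syt, roi)
    }
    qc[[f]] <- tibble::tibble(frame = f, background_i405 = bgs[1],
                              background_i488 = bgs[2], background_chl = bgs[3],
                              n_objects = nrow(rec),
                              n_removed = length(unique(filt$removed$label)),
                              n_oxd_excluded_px = po$n_excluded)
  }
  list(cells = dplyr::bind_rows(cells), offsets = offsets,
       labels = labels_out, sytox = sytox_out,
       qc = dplyr::bind_rows(qc), frame_times = stack$frame_times,
       config = config)
}
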