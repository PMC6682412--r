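# Multi-channel time-lapse container and TIFF + JSON-sidecar IO.
#
# Pixel data live in a 4-D array indexed [frame, channel, y, x] holding
# raw camera counts (a.u., integers in [0, 2^bit_depth - 1]). The spatial
# convention throughout the package is 0-based (x, y) = (column, row)
# with the origin at the top-left pixel.

#' Construct an image stack
#'
#' @param pixels 4-D numeric array `[frame, channel, height, width]` of
#'   raw counts.
#' @param channel_names Character vector naming the channels (unique),
#'   e.g. `c("i405", "i488", "chl", "sytox")`.
#' @param frame_times Numeric vector of frame times (minutes post
#'   treatment), one per frame.
#' @param bit_depth Camera bit depth; one of 8, 12, 14, 16.
#' @param pixel_size Optional pixel size (micrometers per pixel).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channel_names, frame_times,
                        bit_depth = 16, pixel_size = NA_real_) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4)
  d <- dim(pixels)
  if (length(channel_names) != d[2])
    stop("channel_names length (", length(channel_names),
         ") != number of channels (", d[2], ")")
  if (anyDuplicated(channel_names)) stop("channel_names must be unique")
  if (length(frame_times) != d[1])
    stop("frame_times length (", length(frame_times),
         ") != number of frames (", d[1], ")")
  if (!bit_depth %in% c(8, 12, 14, 16))
    stop("bit_depth must be one of 8, 12, 14, 16")
  if (max(pixels, na.rm = TRUE) > 2^bit_depth - 1)
    stop("pixel values exceed 2^bit_depth - 1")
  structure(list(pixels = pixels,
                 channel_names = as.character(channel_names),
                 frame_times = as.numeric(frame_times),
                 bit_depth = as.integer(bit_depth),
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: %d frame(s) x %d channel(s) x %d x %d px, %d-bit\n",
              d[1], d[2], d[3], d[4], x$bit_depth))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("  frame times: %s ... %s min\n",
              format(x$frame_times[1]), format(x$frame_times[d[1]])))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[1]
n_channels <- function(stack) dim(stack$pixels)[2]

#' Extract one channel image
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param frame Frame index (1-based).
#' @return A numeric matrix `[height, width]`.
#' @export
get_channel <- function(stack, channel, frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) stop("no such channel: ", channel)
  } else ci <- as.integer(channel)
  stack$pixels[frame, ci, , ]
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are stored frame-major, channel-interleaved (frame 1 channel 1,
#' frame 1 channel 2, ..., frame 2 channel 1, ...). Raw counts are scaled
#' by `2^bit_depth - 1` into the unit interval for 16-bit TIFF storage;
#' integer counts round-trip exactly. The sidecar records channel names,
#' frame times, bit depth, pixel size and the expected page geometry.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path; the sidecar is written to
#'   `paste0(path, ".json")` unless `sidecar` is given.
#' @param sidecar Optional sidecar path.
#' @return `write_image_stack` returns `path` invisibly;
#'   `read_image_stack` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  scale <- 2^stack$bit_depth - 1
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (f in seq_len(d[1])) for (ch in seq_len(d[2])) {
    pages[[k]] <- stack$pixels[f, ch, , ] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(channel_names = stack$channel_names,
               frame_times = stack$frame_times,
               bit_depth = stack$bit_depth,
               pixel_size = stack$pixel_size,
               n_frames = d[1], n_channels = d[2],
               height = d[3], width = d[4],
               page_order = "frame-major, channel-interleaved")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  expected <- meta$n_frames * meta$n_channels
  if (length(pages) != expected)
    stop("TIFF page count mismatch: expected ", expected,
         " (", meta$n_frames, " frames x ", meta$n_channels,
         " channels), found ", length(pages))
  scale <- 2^meta$bit_depth - 1
  px <- array(0, dim = c(meta$n_frames, meta$n_channels,
                         meta$height, meta$width))
  k <- 1L
  for (f in seq_len(meta$n_frames)) for (ch in seq_len(meta$n_channels)) {
    px[f, ch, , ] <- round(pages[[k]] * scale)
    k <- k + 1L
  }
  image_stack(px, meta$channel_names, meta$frame_times,
              bit_depth = meta$bit_depth,
              pixel_size = if (is.null(meta$pixel_size)) NA_real_
                           else meta$pixel_size)
}
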