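#' Time-lapse movie container
#'
#' A `MovieStack` holds one or more channels of a 2D time-lapse movie as
#' `H x W x T` numeric arrays, together with the pixel size (micrometres per
#' pixel) and the frame interval (seconds). Pixel coordinates are 0-based
#' `(row, column)` throughout the package; row 0 / column 0 is the top-left
#' pixel.
#'
#' @param channels named list of `H x W x T` numeric arrays, all the same
#'   dimension.
#' @param pixel_size pixel size in um/px, positive.
#' @param frame_interval frame interval in seconds, positive.
#' @return an object of class `MovieStack`.
#' @export
movie_stack <- function(channels, pixel_size, frame_interval) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  dims <- lapply(channels, dim)
  d0 <- dims[[1]]
  if (length(d0) != 3L) stop("each channel must be an H x W x T array")
  for (d in dims) if (!identical(d, d0)) stop("channel dimensions differ")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(
    list(channels = channels, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "MovieStack"
  )
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "MovieStack: %d x %d px, %d frames, %d channel(s) [%s]\n  %.3f um/px, %.1f s/frame\n",
    d[1], d[2], d[3], length(x$channels),
    paste(names(x$channels), collapse = ", "),
    x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a [movie_stack()] object.
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$channels[[1]])[3]

#' Extract one frame of one channel
#' @param movie a [movie_stack()] object.
#' @param t frame index (1-based).
#' @param channel channel name or index.
#' @return numeric matrix.
#' @export
get_frame <- function(movie, t, channel = 1L) {
  movie$channels[[channel]][, , t]
}

#' Write a movie as a multi-page TIFF
#'
#' Pages are channel-interleaved: frame 1 channel 1, frame 1 channel 2, ...,
#' frame 2 channel 1, and so on. Intensities are scaled to the movie maximum
#' and stored as 32-bit float. A JSON sidecar (`<file>.json`) records pixel
#' size, frame interval, channel names and page order.
#'
#' @param movie a [movie_stack()] object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  nt <- n_frames(movie)
  nc <- length(movie$channels)
  pages <- vector("list", nt * nc)
  k <- 1L
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      pages[[k]] <- movie$channels[[c]][, , t]
      k <- k + 1L
    }
  }
  mn <- min(vapply(pages, min, 0))
  mx <- max(vapply(pages, max, 0))
  scale <- max(mx - mn, 1e-12)
  pages <- lapply(pages, function(p) (p - mn) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    pixel_size_um = movie$pixel_size,
    frame_interval_s = movie$frame_interval,
    n_frames = nt,
    channels = names(movie$channels),
    page_order = "channel-interleaved (t1c1, t1c2, ..., t2c1, ...)",
    intensity_offset = mn,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#' @param path TIFF path with its JSON sidecar alongside.
#' @return a [movie_stack()] object.
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(meta$channels)
  nt <- meta$n_frames
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  channels <- stats::setNames(
    lapply(seq_len(nc), function(c) {
      arr <- array(0, dim = c(h, w, nt))
      for (t in seq_len(nt)) arr[, , t] <- pages[[(t - 1L) * nc + c]]
      arr * meta$intensity_scale + meta$intensity_offset
    }),
    meta$channels)
  movie_stack(channels, meta$pixel_size_um, meta$frame_interval_s)
}

#' Write tracks or traced paths as CSV
#'
#' Standard columns: `entity_id, frame, y_px, x_px, arclen_um` (0-based pixel
#' coordinates, row/column order).
#'
#' @param tracks data frame with at least those columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Read a track table written by [write_tracks_csv()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write simulation ground truth as JSON
#' @param gt a `GroundTruth` list as returned by the simulators.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
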