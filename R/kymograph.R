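#' Kymograph container
#'
#' Rows are time frames, columns are arc-length bins along a traced path
#' with the soma at column 0 (leftmost); retrograde motion therefore runs
#' leftward. Column spacing is one pixel of arc length.
#'
#' @param data numeric matrix, rows = frames.
#' @param pixel_size um per column.
#' @param frame_interval seconds per row.
#' @param width_px sampling width used to build the kymograph.
#' @param path_id identifier of the source path.
#' @return object of class `Kymograph`.
#' @export
new_kymograph <- function(data, pixel_size, frame_interval, width_px = 11L,
                          path_id = 1L) {
  stopifnot(is.matrix(data), pixel_size > 0, frame_interval > 0)
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval, width_px = width_px,
                 path_id = path_id),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d positions (%.3f um/px, %.1f s/frame)\n",
              nrow(x$data), ncol(x$data), x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Sample a kymograph along a traced path
#'
#' For every frame and every path point, the kymograph value is the maximum
#' intensity over a `width_px`-long segment perpendicular to the local path
#' direction (tangent from a 5-point central difference), sampled at the
#' nearest pixel. Maximum-projection across the width makes the readout
#' robust to the path not running exactly down the neurite midline.
#'
#' @param movie a [movie_stack()] object.
#' @param path a `NeuriteBranch` (ordered soma-to-tip, 0-based pixel coords).
#' @param width_px odd sampling width in pixels (default 11).
#' @param channel channel name or index.
#' @return a `Kymograph`.
#' @export
sample_kymograph <- function(movie, path, width_px = 11L, channel = 1L) {
  stopifnot(width_px >= 1L, width_px %% 2L == 1L)
  arr <- movie$channels[[channel]]
  h <- dim(arr)[1]; w <- dim(arr)[2]; nt <- dim(arr)[3]
  np <- nrow(path)
  i0 <- pmax(seq_len(np) - 2L, 1L)
  i1 <- pmin(seq_len(np) + 2L, np)
  ty <- path$y_px[i1] - path$y_px[i0]
  tx <- path$x_px[i1] - path$x_px[i0]
  nrm <- sqrt(ty^2 + tx^2); nrm[nrm == 0] <- 1
  # perpendicular unit vector
  py <- -tx / nrm; px <- ty / nrm
  half <- (width_px - 1L) / 2L
  offs <- seq(-half, half)
  ys <- round(outer(path$y_px, rep(1, width_px)) + outer(py, offs)) + 1L
  xs <- round(outer(path$x_px, rep(1, width_px)) + outer(px, offs)) + 1L
  inb <- ys >= 1L & ys <= h & xs >= 1L & xs <= w
  if (!all(inb)) warning("sampling corridor clipped at the frame boundary")
  kdat <- matrix(NA_real_, nt, np)
  flat_base <- (xs - 1L) * h + ys
  for (t in seq_len(nt)) {
    fr <- arr[, , t]
    vals <- matrix(NA_real_, np, width_px)
    vals[inb] <- fr[flat_base[inb]]
    kdat[t, ] <- apply(vals, 1, max, na.rm = TRUE)
  }
  new_kymograph(kdat, movie$pixel_size, movie$frame_interval,
                width_px = width_px,
                path_id = attr(path, "neurite_id") %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neurite length over time from a kymograph
#'
#' Smooths (2x2 median, or 1x5 across position only, or none), thresholds,
#' forces the first and last time rows into the thresholded set so that
#' transient dimming becomes fillable holes, fills holes (optionally after
#' one binary dilation), then walks each row from the soma (column 0) and
#' stops one pixel before the first unthresholded pixel. Length is that
#' column index times the pixel size.
#'
#' @param kymo a `Kymograph`.
#' @param threshold manual intensity threshold; if `NULL`, Otsu's threshold
#'   on the kymograph is used (a supplied manual value always wins).
#' @param smooth_mode `"isotropic2"` (2x2 median), `"rowwise5"` (1x5 across
#'   position), or `"none"`.
#' @param dilate_first apply one binary dilation before hole filling.
#' @return numeric vector of lengths (um), one per frame.
#' @export
neurite_length_series <- function(kymo, threshold = NULL,
                                  smooth_mode = c("isotropic2", "rowwise5",
                                                  "none"),
                                  dilate_first = FALSE) {
  smooth_mode <- match.arg(smooth_mode)
  m <- kymo$data
  sm <- switch(smooth_mode,
               isotropic2 = median_filter_rect(m, c(2L, 2L)),
               rowwise5 = median_filter_rect(m, c(1L, 5L)),
               none = m)
  if (is.null(threshold)) threshold <- otsu_threshold(sm)
  bin <- sm >= threshold
  bin[1, ] <- TRUE
  bin[nrow(bin), ] <- TRUE
  if (dilate_first) bin <- binary_dilate3(bin, 1L)
  bin <- fill_holes(bin)
  lengths_px <- apply(bin, 1, function(row) {
    if (!row[1]) return(0L)
    firstF <- which(!row)[1]
    if (is.na(firstF)) length(row) - 1L else firstF - 2L
  })
  pmax(lengths_px, 0L) * kymo$pixel_size
}

# Otsu threshold on an arbitrary-range matrix (EBImage otsu expects [0,1]).
otsu_threshold <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (m - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Proximal and distal microtubule density from a kymograph
#'
#' Per frame, the mean thresholded-pixel intensity within the first 5 um of
#' the neurite (proximal) and within 5 to 10 um from the neurite tip
#' (distal). Each series is normalized to its own mean over the first
#' `norm_minutes` of the movie. The distal zone is undefined (NA) for frames
#' where the neurite is shorter than 10 um.
#'
#' @param kymo a `Kymograph`.
#' @param lengths per-frame neurite lengths in um
#'   (from [neurite_length_series()]).
#' @param threshold intensity threshold defining neurite pixels; `NULL` for
#'   Otsu.
#' @param norm_minutes normalisation window from movie start (default 22.5).
#' @return data frame with columns `frame, proximal, distal`.
#' @export
proximal_distal_density <- function(kymo, lengths, threshold = NULL,
                                    norm_minutes = 22.5) {
  m <- kymo$data
  if (is.null(threshold)) threshold <- otsu_threshold(m)
  ps <- kymo$pixel_size
  nt <- nrow(m)
  prox <- dist <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    len <- lengths[t]
    cols_um <- (seq_len(ncol(m)) - 1L) * ps
    sel_p <- cols_um <= 5 & cols_um <= len & m[t, ] >= threshold
    if (any(sel_p)) prox[t] <- mean(m[t, sel_p])
    if (len >= 10) {
      sel_d <- cols_um >= (len - 10) & cols_um <= (len - 5) & m[t, ] >= threshold
      if (any(sel_d)) dist[t] <- mean(m[t, sel_d])
    }
  }
  t_min <- (seq_len(nt) - 1L) * kymo$frame_interval / 60
  in_norm <- t_min < norm_minutes
  norm <- function(x) {
    base <- mean(x[in_norm], na.rm = TRUE)
    if (!is.finite(base) || base == 0) return(rep(NA_real_, length(x)))
    x / base
  }
  data.frame(frame = seq_len(nt), proximal = norm(prox), distal = norm(dist))
}

#' Soma fraction of total fluorescence over time
#'
#' Per frame, total fluorescence (background-subtracted mean of thresholded
#' pixels times their count) inside the soma region divided by the same
#' quantity over the whole cell region.
#'
#' @param movie a [movie_stack()] object.
#' @param soma_region,cell_region logical masks (`soma_region` must be a
#'   subset of `cell_region`).
#' @param threshold intensity threshold defining signal pixels.
#' @param background background level; default is the per-frame mean
#'   intensity outside `cell_region`.
#' @param channel channel name or index.
#' @return numeric vector of fractions in \[0, 1\] (NA where the cell total
#'   is zero).
#' @export
soma_fraction <- function(movie, soma_region, cell_region, threshold,
                          background = NULL, channel = 1L) {
  if (any(soma_region & !cell_region))
    stop("soma_region must lie inside cell_region")
  arr <- movie$channels[[channel]]
  nt <- dim(arr)[3]
  out <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    fr <- arr[, , t]
    bg <- if (is.null(background)) {
      if (any(!cell_region)) mean(fr[!cell_region]) else 0
    } else background
    total_in <- function(mask) {
      sel <- mask & fr >= threshold
      if (!any(sel)) return(0)
      (mean(fr[sel]) - bg) * sum(sel)
    }
    cell_tot <- total_in(cell_region)
    if (cell_tot > 0) out[t] <- min(max(total_in(soma_region) / cell_tot, 0), 1)
  }
  out
}
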