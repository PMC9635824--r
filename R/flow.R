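#' Flow-analysis configuration
#'
#' Printed analysis parameters of the MT-RF quantification, bundled with
#' their defaults: minimum patch-track duration 1 min, 200-min smoothing of
#' flow series, axon slowdown at 80% of the slowest other neurite for 95%
#' of time points over at least 180 min, a +/- 1.1 um stationary half-window
#' around the photoconversion start point, a 10% trim for patch spread, and
#' row-stop factors of 1.8 (no LatB) / 1.3 (LatB) times the neurite
#' background.
#'
#' @param min_track_duration_min minimum analysable track duration (min).
#' @param smoothing_window_min rolling-mean window for flow series (min).
#' @param slowdown_ratio axon/others ratio defining "slower" (0.8).
#' @param qualifying_fraction fraction of qualifying time points (0.95).
#' @param qualifying_duration_min required duration of slowdown (min).
#' @param stationary_halfwindow_um half-window of the stationary zone (um).
#' @param spread_trim_fraction edge-trim fraction for patch spread (0.10).
#' @param row_stop_factor_nolatb,row_stop_factor_latb row-stop multiples of
#'   the neurite background.
#' @param slowdown_compare `"min"` (strictest: axon vs the slowest other
#'   neurite) or `"mean"` of the others.
#' @return list of class `FlowConfig`.
#' @export
flow_config <- function(min_track_duration_min = 1,
                        smoothing_window_min = 200,
                        slowdown_ratio = 0.8,
                        qualifying_fraction = 0.95,
                        qualifying_duration_min = 180,
                        stationary_halfwindow_um = 1.1,
                        spread_trim_fraction = 0.10,
                        row_stop_factor_nolatb = 1.8,
                        row_stop_factor_latb = 1.3,
                        slowdown_compare = c("min", "mean")) {
  cfg <- list(
    min_track_duration_min = min_track_duration_min,
    smoothing_window_min = smoothing_window_min,
    slowdown_ratio = slowdown_ratio,
    qualifying_fraction = qualifying_fraction,
    qualifying_duration_min = qualifying_duration_min,
    stationary_halfwindow_um = stationary_halfwindow_um,
    spread_trim_fraction = spread_trim_fraction,
    row_stop_factor_nolatb = row_stop_factor_nolatb,
    row_stop_factor_latb = row_stop_factor_latb,
    slowdown_compare = match.arg(slowdown_compare)
  )
  stopifnot(all(unlist(cfg[1:9]) > 0),
            cfg$slowdown_ratio < 1, cfg$qualifying_fraction < 1,
            cfg$spread_trim_fraction < 1)
  class(cfg) <- "FlowConfig"
  cfg
}

#' Track a photoconverted patch along a neurite path
#'
#' Replaces the manual midpoint tracing of patch movies: per frame, the
#' converted-channel intensity is max-projected across a corridor around the
#' path ([sample_kymograph()]), background-subtracted (median of the
#' profile), and the patch position is the intensity-weighted centroid of
#' the contiguous region around the profile peak above 25% of the peak.
#' A tracking window of `window_um` around the previous position keeps the
#' track on one patch; `n_patches = 2` follows a proximal and a distal patch
#' simultaneously (two patches with `n_patches = 1` raise an error).
#'
#' The track ends at the first frame whose peak signal falls below
#' `stop_factor` times the background.
#'
#' @param movie a registered [movie_stack()] with a `converted` channel.
#' @param path the `NeuriteBranch` to track along.
#' @param n_patches 1 or 2.
#' @param width_px corridor width (odd, px).
#' @param window_um half-width of the per-frame search window around the
#'   previous position.
#' @param stop_factor track-ending peak/background ratio (default 1.3).
#' @param channel channel name or index.
#' @return for `n_patches = 1` a `Track` data frame
#'   `(frame, time_min, arclen_um)`; for 2, a list of two such tracks
#'   (proximal first).
#' @export
track_patch <- function(movie, path, n_patches = 1L, width_px = 11L,
                        window_um = 3, stop_factor = 1.3, channel = "converted") {
  kym <- sample_kymograph(movie, path, width_px = width_px, channel = channel)
  prof <- kym$data
  nt <- nrow(prof)
  arcs <- path$arclen_um
  bg <- apply(prof, 1, stats::median)
  peaks_of_row <- function(v, n) {
    # positions of the n highest well-separated local maxima
    ord <- order(v, decreasing = TRUE)
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) == n) break
      if (all(abs(arcs[i] - arcs[sel]) > 2 * window_um) || !length(sel))
        sel <- c(sel, i)
    }
    sort(sel)
  }
  first_row <- prof[1, ] - bg[1]
  if (max(prof[1, ]) < stop_factor * max(bg[1], 1e-9))
    stop("no patch signal above background in frame 1")
  # peak detection on a lightly smoothed profile so noise bumps do not
  # masquerade as patches
  first_sm <- as.numeric(stats::filter(first_row, rep(1 / 5, 5), sides = 2))
  first_sm[is.na(first_sm)] <- 0
  pk2 <- peaks_of_row(first_sm, 2L)
  if (n_patches == 1L && length(pk2) == 2L &&
      min(first_sm[pk2]) > 0.5 * max(first_sm)) {
    # a second candidate must persist over the next frames near the same
    # arc position: real patches are persistent structures, noise ridges
    # from the max-projection are not
    minor <- pk2[which.min(first_sm[pk2])]
    check_frames <- seq(2L, min(3L, nt))
    persists <- vapply(check_frames, function(t) {
      sm <- as.numeric(stats::filter(prof[t, ] - bg[t], rep(1 / 5, 5),
                                     sides = 2))
      sm[is.na(sm)] <- 0
      win <- which(abs(arcs - arcs[minor]) <= 1)
      length(win) > 0 && max(sm[win]) >= 0.4 * max(sm)
    }, TRUE)
    if (length(persists) && all(persists))
      stop("two patches in the corridor; use n_patches = 2")
  }
  starts <- peaks_of_row(first_sm, n_patches)
  if (length(starts) < n_patches) stop("fewer patches found than requested")
  centroid_near <- function(row_sig, s_prev) {
    # 5-column running mean: symmetric, so it cannot bias the centroid,
    # but it keeps noise columns out of the >25%-of-peak region
    row_sig <- as.numeric(stats::filter(row_sig, rep(1 / 5, 5), sides = 2))
    row_sig[is.na(row_sig)] <- 0
    win <- which(abs(arcs - s_prev) <= window_um)
    if (!length(win)) return(NA_real_)
    v <- row_sig[win]
    pk <- win[which.max(v)]
    thr <- 0.25 * row_sig[pk]
    # contiguous region around the peak above the threshold
    lo <- pk
    while (lo > 1 && row_sig[lo - 1] > thr) lo <- lo - 1
    hi <- pk
    while (hi < length(arcs) && row_sig[hi + 1] > thr) hi <- hi + 1
    idx <- lo:hi
    wgt <- pmax(row_sig[idx], 0)
    if (sum(wgt) == 0) return(NA_real_)
    sum(arcs[idx] * wgt) / sum(wgt)
  }
  dt_min <- movie$frame_interval / 60
  tracks <- vector("list", n_patches)
  for (p in seq_len(n_patches)) {
    pos <- rep(NA_real_, nt)
    pos[1] <- centroid_near(first_row, arcs[starts[p]])
    last <- pos[1]
    end_t <- nt
    for (t in 2:nt) {
      sig <- prof[t, ] - bg[t]
      win <- which(abs(arcs - last) <= window_um)
      if (max(prof[t, win]) < stop_factor * max(bg[t], 1e-9)) {
        end_t <- t - 1L
        break
      }
      pos[t] <- centroid_near(sig, last)
      if (is.na(pos[t])) { end_t <- t - 1L; break }
      last <- pos[t]
    }
    tt <- seq_len(end_t)
    tr <- data.frame(frame = tt, time_min = (tt - 1L) * dt_min,
                     arclen_um = pos[tt])
    class(tr) <- c("Track", "data.frame")
    tracks[[p]] <- tr
  }
  if (n_patches == 1L) tracks[[1]] else tracks
}

#' Drift speed and direction from a track
#'
#' Speed is the magnitude of the net displacement divided by the track
#' duration (`method = "net"`), or the summed point-to-point path length per
#' time for `method = "path"`; direction comes from the sign of the net
#' displacement (negative arc-length change = retrograde). Accepts arc-length
#' tracks (`arclen_um`) or 2D/3D point tracks (`x_um, y_um[, z_um]`), in
#' which case the displacement is the Euclidean point distance and the
#' direction label is `NA` unless arc length is present.
#'
#' @param track a `Track` data frame with `time_min` and either `arclen_um`
#'   or point columns.
#' @param config a [flow_config()].
#' @param method `"net"` or `"path"`.
#' @param immobile_tol_um displacements at or below this are labelled
#'   immobile.
#' @return a `FlowMeasurement` list: `speed_um_min` (>= 0), `direction`
#'   (`"retrograde"`, `"anterograde"`, `"immobile"` or NA), `duration_min`,
#'   `method`.
#' @export
speed_from_track <- function(track, config = flow_config(),
                             method = c("net", "path"),
                             immobile_tol_um = 1e-9) {
  method <- match.arg(method)
  tr <- track[stats::complete.cases(track), , drop = FALSE]
  if (nrow(tr) < 2L) stop("track too short")
  duration <- max(tr$time_min) - min(tr$time_min)
  if (duration <= config$min_track_duration_min)
    stop(sprintf("track duration %.2f min is not above the %g-min minimum",
                 duration, config$min_track_duration_min))
  if ("arclen_um" %in% names(tr)) {
    net <- tr$arclen_um[nrow(tr)] - tr$arclen_um[1]
    dist <- if (method == "net") abs(net) else sum(abs(diff(tr$arclen_um)))
    dirn <- if (abs(net) <= immobile_tol_um) "immobile"
            else if (net < 0) "retrograde" else "anterograde"
  } else {
    cols <- intersect(c("x_um", "y_um", "z_um"), names(tr))
    if (!length(cols)) stop("track has neither arclen_um nor point columns")
    P <- as.matrix(tr[, cols, drop = FALSE])
    net <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
    dist <- if (method == "net") net else
      sum(sqrt(rowSums(diff(P)^2)))
    dirn <- if (net <= immobile_tol_um) "immobile" else NA_character_
  }
  speed <- if (identical(dirn, "immobile")) 0 else dist / duration
  structure(list(speed_um_min = speed, direction = dirn,
                 duration_min = duration, method = method),
            class = "FlowMeasurement")
}

#' Synchrony of multiple patches in one neurite
#'
#' Relative distance difference: the traveled distance of the patch that
#' moved furthest minus that of the patch that moved least, divided by the
#' lesser distance.
#'
#' @param tracks list of >= 2 `Track`s from the same neurite, or a numeric
#'   vector of traveled distances (um).
#' @return relative distance difference (NA when the least-moved distance
#'   is 0).
#' @export
patch_synchrony <- function(tracks) {
  d <- if (is.numeric(tracks)) tracks else vapply(tracks, function(tr) {
    tr <- tr[stats::complete.cases(tr), , drop = FALSE]
    abs(tr$arclen_um[nrow(tr)] - tr$arclen_um[1])
  }, 0)
  if (length(d) < 2L) stop("need at least two patches")
  if (min(d) == 0) return(NA_real_)
  (max(d) - min(d)) / min(d)
}

#' Extract CAMSAP3 traces from a kymograph
#'
#' Automated stand-in for manual line tracing: each row is thresholded,
#' contiguous runs of above-threshold pixels become punctum detections
#' (intensity-weighted centroid column), and detections are linked frame to
#' frame to the nearest active trace within `max_step_px`. Traces shorter
#' than `min_len` frames are dropped.
#'
#' @param kymo a `Kymograph`.
#' @param threshold detection threshold; `NULL` for Otsu.
#' @param max_step_px maximum per-frame step for linking.
#' @param min_len minimum trace length in frames (default 3).
#' @return list of data frames `(frame, col)` with `col` the 0-based
#'   kymograph column.
#' @export
extract_camsap_traces <- function(kymo, threshold = NULL, max_step_px = 6,
                                  min_len = 3L) {
  m <- kymo$data
  if (is.null(threshold)) threshold <- otsu_threshold(m)
  active <- list()   # each: list(frames, cols, last_col, last_frame)
  done <- list()
  for (t in seq_len(nrow(m))) {
    above <- m[t, ] >= threshold
    dets <- numeric(0)
    if (any(above)) {
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        w <- m[t, idx] - min(m[t, ]) + 1e-9
        dets <- c(dets, sum((idx - 1L) * w) / sum(w))
      }
    }
    used <- rep(FALSE, length(dets))
    for (a in seq_along(active)) {
      if (!length(dets)) break
      gaps <- abs(dets - active[[a]]$last_col)
      gaps[used] <- Inf
      j <- which.min(gaps)
      if (is.finite(gaps[j]) && gaps[j] <= max_step_px) {
        active[[a]]$frames <- c(active[[a]]$frames, t)
        active[[a]]$cols <- c(active[[a]]$cols, dets[j])
        active[[a]]$last_col <- dets[j]
        active[[a]]$last_frame <- t
        used[j] <- TRUE
      }
    }
    # retire traces that missed this frame
    if (length(active)) {
      stale <- vapply(active, function(a) a$last_frame < t, TRUE)
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    for (j in which(!used)) {
      active[[length(active) + 1L]] <- list(frames = t, cols = dets[j],
                                            last_col = dets[j], last_frame = t)
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= min_len, done)
  lapply(done, function(a) data.frame(frame = a$frames, col = a$cols))
}

#' Per-frame MT-RF series from kymograph traces
#'
#' Per trace, speed = distance / time of the whole trace (kymograph slope);
#' anterograde and immobile traces are discarded; per frame the series is
#' the median speed over all retrograde traces covering that frame (NA when
#' none does). Retrograde speeds are positive.
#'
#' @param traces list of data frames `(frame, col)` from
#'   [extract_camsap_traces()] (or manual tracing).
#' @param pixel_size um per column.
#' @param frame_interval seconds per row.
#' @param n_frames length of the output series.
#' @return numeric vector of MT-RF speeds (um/min) per frame.
#' @export
camsap_flow_series <- function(traces, pixel_size, frame_interval, n_frames) {
  speeds <- vapply(traces, function(tr) {
    if (any(diff(tr$frame) <= 0)) stop("trace time must be monotone")
    dt_min <- (tr$frame[nrow(tr)] - tr$frame[1]) * frame_interval / 60
    if (dt_min <= 0) return(NA_real_)
    -(tr$col[nrow(tr)] - tr$col[1]) * pixel_size / dt_min  # retro positive
  }, 0)
  keep <- which(!is.na(speeds) & speeds > 0)
  out <- rep(NA_real_, n_frames)
  for (t in seq_len(n_frames)) {
    cov <- keep[vapply(traces[keep], function(tr)
      t >= tr$frame[1] && t <= tr$frame[nrow(tr)], TRUE)]
    if (length(cov)) out[t] <- stats::median(speeds[cov])
  }
  out
}

#' Detect MT-RF slowdown in the axon
#'
#' Each neurite's flow series is smoothed with a centered rolling mean of
#' `smoothing_window_min` (truncated at the series ends). A time point
#' qualifies when the smoothed axon flow is at most `slowdown_ratio` times
#' the minimum (or mean, per config) smoothed flow of all other neurites.
#' Slowdown is detected when some window of `qualifying_duration_min`
#' contains at least `qualifying_fraction` qualifying points; the onset is
#' the start of the earliest such window.
#'
#' @param flows named list of per-neurite flow series (equal length, common
#'   time grid), or a matrix with one column per neurite.
#' @param axon_id name or index of the axon series.
#' @param frame_interval seconds per time point.
#' @param config a [flow_config()].
#' @return a `SlowdownResult` list: `detected`, `onset_min` (NA unless
#'   detected), `axon_id`, `evaluable` (FALSE when the series span is below
#'   the qualifying duration, which is distinct from "not detected").
#' @export
detect_slowdown <- function(flows, axon_id, frame_interval,
                            config = flow_config()) {
  M <- if (is.matrix(flows)) flows else do.call(cbind, flows)
  if (ncol(M) < 2L) stop("need the axon and at least one other neurite")
  nt <- nrow(M)
  dt_min <- frame_interval / 60
  span <- (nt - 1L) * dt_min
  res <- function(det, onset, evaluable) {
    structure(list(detected = det, onset_min = onset, axon_id = axon_id,
                   evaluable = evaluable), class = "SlowdownResult")
  }
  if (span < config$qualifying_duration_min) return(res(FALSE, NA_real_, FALSE))
  half <- config$smoothing_window_min / 2
  t_min <- (seq_len(nt) - 1L) * dt_min
  smooth1 <- function(x) {
    vapply(seq_len(nt), function(i) {
      sel <- abs(t_min - t_min[i]) <= half
      mean(x[sel], na.rm = TRUE)
    }, 0)
  }
  S <- apply(M, 2, smooth1)
  ax <- if (is.character(axon_id)) which(colnames(M) == axon_id) else axon_id
  others <- S[, -ax, drop = FALSE]
  ref <- if (config$slowdown_compare == "min") {
    apply(others, 1, min, na.rm = TRUE)
  } else {
    rowMeans(others, na.rm = TRUE)
  }
  qual <- S[, ax] <= config$slowdown_ratio * ref
  qual[is.na(qual)] <- FALSE
  wlen <- config$qualifying_duration_min
  for (i in seq_len(nt)) {
    sel <- t_min >= t_min[i] & t_min < t_min[i] + wlen
    if (t_min[i] + wlen > span + dt_min / 2 + t_min[1]) break
    if (mean(qual[sel]) >= config$qualifying_fraction)
      return(res(TRUE, t_min[i], TRUE))
  }
  res(FALSE, NA_real_, TRUE)
}

#' Classify the polarization stage from neurite lengths
#'
#' Applies the printed three-way rule set: a neuron has an axon when its
#' longest neurite is at least 50 um and at least 10 um longer than the
#' second-longest; it lacks an axon when the longest neurite is (shorter
#' than 30 um or under 5 um longer than the second-longest) and shorter
#' than 50 um; otherwise it is at the transition (at least 30 um and at
#' least 5 um longer). Rules are evaluated in that order.
#'
#' @param lengths numeric vector of per-neurite lengths (um), >= 2 entries.
#' @return `"with_axon"`, `"no_axon"` or `"transition"`.
#' @export
classify_axon <- function(lengths) {
  if (length(lengths) < 2L) stop("need at least two neurites")
  s <- sort(lengths, decreasing = TRUE)
  longest <- s[1]; second <- s[2]
  if (longest >= 50 && longest - second >= 10) return("with_axon")
  if ((longest < 30 || longest - second < 5) && longest < 50) return("no_axon")
  "transition"
}

#' Neurite background of a photoconversion kymograph
#'
#' The minimum over the first five columns (neurite pixels next to the soma)
#' of the first and the last four rows, floored at the highest background of
#' previous photoconversions of the same neurite (converted tubulin only
#' accumulates over repeated conversions).
#'
#' @param kymo a `Kymograph`.
#' @param previous_backgrounds numeric vector of earlier background values
#'   (may be empty).
#' @return background intensity value.
#' @export
neurite_background <- function(kymo, previous_backgrounds = numeric(0)) {
  m <- kymo$data
  nr <- nrow(m)
  rows <- unique(c(1L, max(1L, nr - 3L):nr))
  cols <- seq_len(min(5L, ncol(m)))
  val <- min(m[rows, cols])
  if (length(previous_backgrounds)) val <- max(val, max(previous_backgrounds))
  val
}

#' Spread and edge speeds of a photoactivated patch
#'
#' Per analyzed row of a background-subtracted kymograph, the edge pixel
#' (retrograde or anterograde) with the lower value is removed until at
#' least `spread_trim_fraction` of the row's summed intensity is gone; the
#' spread is the distance between the surviving extremes. Edge speeds are
#' least-squares slopes of each surviving extreme's distance beyond the
#' +/- 1.1-um lines around the start point. Rows are analyzed up to the
#' last row whose peak is at least `stop_factor` times the background.
#'
#' @param kymo a `Kymograph` (raw intensities).
#' @param start 1-based start column; `NULL` to use the peak of the first
#'   row after smoothing with a 5-px window.
#' @param config a [flow_config()].
#' @param background neurite background; `NULL` to use
#'   [neurite_background()].
#' @param stop_factor row-stop multiple of background (default the LatB
#'   value 1.3, as in the spread experiments).
#' @return list with `spread_um` (per analyzed row), `retro_speed_um_min`,
#'   `antero_speed_um_min`, `rows_analyzed`.
#' @export
patch_spread <- function(kymo, start = NULL, config = flow_config(),
                         background = NULL, stop_factor = NULL) {
  if (is.null(background)) background <- neurite_background(kymo)
  if (is.null(stop_factor)) stop_factor <- config$row_stop_factor_latb
  m <- kymo$data
  if (is.null(start)) start <- find_start_column(m)
  sub <- m - background
  peaks <- apply(m, 1, max)
  ok <- peaks >= stop_factor * background
  if (!ok[1]) stop("first row already below the row-stop criterion")
  n_rows <- if (all(ok)) nrow(m) else which(!ok)[1] - 1L
  ps <- kymo$pixel_size
  zpx <- round(config$stationary_halfwindow_um / ps)
  spread <- retro_edge <- antero_edge <- rep(NA_real_, n_rows)
  for (r in seq_len(n_rows)) {
    v <- pmax(sub[r, ], 0)
    lo <- 1L; hi <- length(v)
    total <- sum(v)
    removed <- 0
    tie_left <- TRUE   # exact ties alternate sides to keep flat tops centred
    while (removed < config$spread_trim_fraction * total && lo < hi) {
      take_left <- if (v[lo] == v[hi]) {
        tie_left <- !tie_left
        !tie_left
      } else v[lo] < v[hi]
      if (take_left) {
        removed <- removed + v[lo]; lo <- lo + 1L
      } else {
        removed <- removed + v[hi]; hi <- hi - 1L
      }
    }
    spread[r] <- (hi - lo) * ps
    retro_edge[r] <- max(0, (start - zpx) - lo) * ps
    antero_edge[r] <- max(0, hi - (start + zpx)) * ps
  }
  t_min <- (seq_len(n_rows) - 1L) * kymo$frame_interval / 60
  slope <- function(y) {
    if (length(y) < 2L || stats::sd(t_min) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ t_min))[2])
  }
  list(spread_um = spread,
       retro_speed_um_min = slope(retro_edge),
       antero_speed_um_min = slope(antero_edge),
       rows_analyzed = n_rows)
}

# Start column: peak of the first row after smoothing with a 5-px window.
find_start_column <- function(m) {
  sm <- stats::filter(m[1, ], rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- -Inf
  which.max(sm)
}

#' Mass partition of a photoconverted patch kymograph
#'
#' Per analyzed row, the background-subtracted summed intensity
#' (microtubule mass) in three zones around the start point — more than
#' 1.1 um retrograde, within +/- 1.1 um (stationary), and more than 1.1 um
#' anterograde — divided by the whole-row mass, averaged over the analyzed
#' rows. Rows are analyzed up to one before the first row whose peak falls
#' below the row-stop factor (1.8x background, or 1.3x with LatB) times the
#' neurite background.
#'
#' @param kymo a `Kymograph` (raw intensities).
#' @param start 1-based start column; `NULL` uses the smoothed first-row
#'   peak ([find_start_column()]).
#' @param config a [flow_config()].
#' @param latb_mode use the 1.3x row-stop factor instead of 1.8x.
#' @param background neurite background; `NULL` for [neurite_background()].
#' @return list with `fractions` (`retro`, `stationary`, `antero`, summing
#'   to 1), `per_row` (matrix of per-row fractions), `rows_analyzed`,
#'   `background`, `start_col`.
#' @export
mass_distribution <- function(kymo, start = NULL, config = flow_config(),
                              latb_mode = FALSE, background = NULL) {
  if (is.null(background)) background <- neurite_background(kymo)
  m <- kymo$data
  if (is.null(start)) start <- find_start_column(m)
  factor <- if (latb_mode) config$row_stop_factor_latb
            else config$row_stop_factor_nolatb
  peaks <- apply(m, 1, max)
  below <- which(peaks < factor * background)
  n_rows <- if (!length(below)) nrow(m) else below[1] - 1L
  if (n_rows < 1L) stop("no rows above the row-stop criterion")
  ps <- kymo$pixel_size
  zpx <- round(config$stationary_halfwindow_um / ps)
  cols <- seq_len(ncol(m))
  zones <- list(retro = cols < start - zpx,
                stationary = abs(cols - start) <= zpx,
                antero = cols > start + zpx)
  per_row <- matrix(NA_real_, n_rows, 3,
                    dimnames = list(NULL, names(zones)))
  for (r in seq_len(n_rows)) {
    v <- m[r, ] - background
    tot <- sum(v)
    if (tot <= 0) next
    per_row[r, ] <- vapply(zones, function(z) sum(v[z]), 0) / tot
  }
  if (all(is.na(per_row[, 1]))) stop("zero total mass in every analyzed row")
  fr <- colMeans(per_row, na.rm = TRUE)
  fr <- fr / sum(fr)
  list(fractions = fr, per_row = per_row, rows_analyzed = n_rows,
       background = background, start_col = start)
}
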