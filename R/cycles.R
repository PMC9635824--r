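#' Fit the tubulin expression level over time
#'
#' The neuron-wide expression level is modeled as a polynomial (quadratic
#' for long overnight movies, linear for short drug-treatment movies) of the
#' average intensity over all neurites at each time point, fitted by least
#' squares.
#'
#' @param avg_intensity numeric series: per-frame mean intensity over all
#'   neurites.
#' @param degree 1 or 2.
#' @param time optional time axis (defaults to the frame index).
#' @return fitted expression series, same length as the input.
#' @export
expression_fit <- function(avg_intensity, degree = 2L, time = NULL) {
  stopifnot(degree %in% c(1L, 2L))
  n <- length(avg_intensity)
  if (n < degree + 2L) stop("need at least degree + 2 frames")
  if (is.null(time)) time <- seq_len(n)
  fit <- stats::lm(avg_intensity ~ stats::poly(time, degree, raw = TRUE))
  fitted <- unname(stats::fitted(fit))
  if (any(fitted <= 0))
    stop("fitted expression level is non-positive; normalization undefined")
  fitted
}

#' Normalize per-neurite intensity by the expression level
#'
#' Microtubule density of neurite i at time t = mean intensity of neurite i
#' at t divided by the fitted expression level at t (dimensionless, ~1).
#'
#' @param intensity per-neurite mean intensity series.
#' @param expression fitted expression series ([expression_fit()]).
#' @return numeric density series.
#' @export
normalize_density <- function(intensity, expression) {
  if (length(intensity) != length(expression))
    stop("series lengths differ")
  if (any(expression <= 0)) stop("expression level must be positive")
  intensity / expression
}

#' Smooth a density trace with a trailing 2-frame window
#'
#' Mean of the current and previous frame; the first frame is unchanged.
#'
#' @param trace numeric series.
#' @param window window size (only the default 2 is meaningful here).
#' @return smoothed series.
#' @export
smooth_trace <- function(trace, window = 2L) {
  n <- length(trace)
  if (n < 2L || window < 2L) return(trace)
  out <- trace
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    out[i] <- mean(trace[lo:i])
  }
  out
}

#' Count microtubule density cycles in a trace
#'
#' Hysteresis swing detector: track the running extremum; when the trace
#' departs from it by at least `delta` in the opposite direction, register a
#' half-swing and restart the extremum. A full cycle is an increase of
#' `delta` followed by a decrease of `delta` (or vice versa), so full
#' cycles = floor(half-swings / 2); the frequency divides full cycles by
#' the trace duration.
#'
#' @param trace numeric density series (smoothed).
#' @param delta swing threshold (default 0.2).
#' @param dt_hours time step between frames in hours (used for the
#'   frequency; NA gives an NA frequency).
#' @return a `CycleCount` list: `half_swings`, `full_cycles`,
#'   `cycles_per_hour`, `duration_h`.
#' @export
count_cycles <- function(trace, delta = 0.2, dt_hours = NA_real_) {
  x <- trace[!is.na(trace)]
  half <- 0L
  if (length(x) >= 2L) {
    ext_min <- ext_max <- x[1]
    dirn <- 0L   # 0 = no swing yet; +1 = last swing was a rise; -1 = a fall
    for (v in x[-1]) {
      if (dirn == 0L) {
        ext_min <- min(ext_min, v); ext_max <- max(ext_max, v)
        if (v - ext_min >= delta) {
          half <- half + 1L; dirn <- 1L; ext_max <- v
        } else if (ext_max - v >= delta) {
          half <- half + 1L; dirn <- -1L; ext_min <- v
        }
      } else if (dirn == 1L) {      # waiting for a fall from the running max
        ext_max <- max(ext_max, v)
        if (ext_max - v >= delta) {
          half <- half + 1L; dirn <- -1L; ext_min <- v
        }
      } else {                      # waiting for a rise from the running min
        ext_min <- min(ext_min, v)
        if (v - ext_min >= delta) {
          half <- half + 1L; dirn <- 1L; ext_max <- v
        }
      }
    }
  }
  full <- half %/% 2L
  duration_h <- if (is.na(dt_hours)) NA_real_ else
    (length(x) - 1L) * dt_hours
  freq <- if (!is.na(duration_h) && duration_h > 0) full / duration_h
          else NA_real_
  structure(list(half_swings = half, full_cycles = full,
                 cycles_per_hour = freq, duration_h = duration_h),
            class = "CycleCount")
}

#' Mean cycle frequency per cell
#'
#' Averages the per-neurite cycle frequency over the configured neurite set
#' of each cell: all neurites, or minor neurites only (axon excluded).
#'
#' @param traces data frame `(cell_id, neurite_id, frame, density)` with a
#'   constant frame interval, or list of numeric traces.
#' @param dt_hours frame interval in hours.
#' @param delta swing threshold.
#' @param smooth apply [smooth_trace()] (window 2) before counting.
#' @param exclude_neurites optional data frame `(cell_id, neurite_id)` of
#'   axons to exclude.
#' @return data frame `(cell_id, mean_cycles_per_hour, n_neurites)`.
#' @export
cycle_frequency_per_cell <- function(traces, dt_hours, delta = 0.2,
                                     smooth = TRUE,
                                     exclude_neurites = NULL) {
  if (is.list(traces) && !is.data.frame(traces)) {
    traces <- do.call(rbind, lapply(seq_along(traces), function(i) {
      data.frame(cell_id = 1L, neurite_id = i,
                 frame = seq_along(traces[[i]]), density = traces[[i]])
    }))
  }
  keys <- unique(traces[, c("cell_id", "neurite_id")])
  if (!is.null(exclude_neurites)) {
    drop <- paste(exclude_neurites$cell_id, exclude_neurites$neurite_id)
    keys <- keys[!(paste(keys$cell_id, keys$neurite_id) %in% drop), ,
                 drop = FALSE]
  }
  freqs <- mapply(function(ci, ni) {
    tr <- traces$density[traces$cell_id == ci & traces$neurite_id == ni]
    tr <- tr[order(traces$frame[traces$cell_id == ci &
                                  traces$neurite_id == ni])]
    if (smooth) tr <- smooth_trace(tr)
    count_cycles(tr, delta = delta, dt_hours = dt_hours)$cycles_per_hour
  }, keys$cell_id, keys$neurite_id)
  out <- stats::aggregate(freqs,
                          by = list(cell_id = keys$cell_id), FUN = mean)
  names(out)[2] <- "mean_cycles_per_hour"
  counts <- stats::aggregate(freqs, by = list(cell_id = keys$cell_id),
                             FUN = length)
  out$n_neurites <- counts$x
  out
}

#' Correlate MT-RF with cycle frequency
#'
#' Pearson correlation with a two-sided p-value over per-neurite pairs of
#' flow speed and cycle frequency; incomplete pairs are dropped.
#'
#' @param flow numeric vector of MT-RF speeds.
#' @param cycles numeric vector of cycle frequencies, same length.
#' @return list with `r`, `p`, `n` (`r` and `p` NA when either variable is
#'   constant or fewer than 3 pairs remain).
#' @export
correlate_flow_cycles <- function(flow, cycles) {
  ok <- stats::complete.cases(flow, cycles)
  x <- flow[ok]; y <- cycles[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
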