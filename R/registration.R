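#' Cap movie intensities at a multiple of the global SD
#'
#' Clips every pixel above `mean + k_sd * SD`, both statistics taken over all
#' frames and pixels of a channel. Capping stops a few very bright pixels
#' (e.g. relocalising signal) from dominating the correlation used for
#' registration. The per-pixel variant computes the statistics per pixel
#' over time instead.
#'
#' @param movie a [movie_stack()] object; all channels are capped.
#' @param k_sd cap multiple, > 0 (default 6).
#' @param per_pixel compute mean/SD per pixel over time rather than globally.
#' @return the capped [movie_stack()].
#' @export
cap_intensities <- function(movie, k_sd = 6, per_pixel = FALSE) {
  stopifnot(inherits(movie, "MovieStack"), k_sd > 0)
  if (n_frames(movie) < 1L) stop("empty movie")
  movie$channels <- lapply(movie$channels, function(arr) {
    if (per_pixel) {
      mu <- apply(arr, c(1, 2), mean)
      sd_ <- apply(arr, c(1, 2), stats::sd)
      cap <- mu + k_sd * sd_
      for (t in seq_len(dim(arr)[3])) arr[, , t] <- pmin(arr[, , t], cap)
    } else {
      cap <- mean(arr) + k_sd * stats::sd(as.vector(arr))
      arr[arr > cap] <- cap
    }
    arr
  })
  movie
}

#' Find the translation aligning a frame to a reference
#'
#' Two-stage integer-shift search maximising the Pearson correlation between
#' the reference and the cyclically rolled frame. Coarse stage: starting from
#' `start_shift`, the 8 compass directions are probed at radius 1, 2, ...
#' pixels; the search stops once the same best direction has won five
#' consecutive radii (or `max_radius` is reached). Refinement: from the best
#' shift seen so far, each dimension in turn is walked in 1-px steps in the
#' improving direction, looking ahead up to `lookahead` px past a
#' non-improving step, until no dimension improves.
#'
#' @param reference,frame numeric matrices of identical dimension.
#' @param start_shift integer `c(dy, dx)` starting shift.
#' @param lookahead refinement look-ahead in px (default 2).
#' @param max_radius largest coarse-stage radius probed.
#' @param stop_count consecutive identical best directions that end the
#'   coarse stage (default 5).
#' @return list with `shift` (integer `c(dy, dx)`), `correlation`, and
#'   `degenerate` (TRUE when a zero-variance frame made the correlation
#'   undefined, in which case `start_shift` is returned).
#' @export
find_shift <- function(reference, frame, start_shift = c(0L, 0L),
                       lookahead = 2L, max_radius = 15L, stop_count = 5L) {
  if (!all(dim(reference) == dim(frame))) stop("frames must have equal shape")
  if (stats::sd(as.vector(reference)) == 0 ||
      stats::sd(as.vector(frame)) == 0) {
    return(list(shift = as.integer(round(start_shift)), correlation = NA_real_,
                degenerate = TRUE))
  }
  memo <- new.env(parent = emptyenv())
  score <- function(s) {
    key <- paste(s[1], s[2])
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- mat_cor(reference, roll_matrix(frame, s[1], s[2]))
    memo[[key]] <- v
    v
  }
  dirs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  start_shift <- as.integer(round(start_shift))
  best_shift <- start_shift
  best_val <- score(start_shift)
  prev_dir <- NA_integer_
  run <- 0L
  for (r in seq_len(max_radius)) {
    vals <- numeric(8)
    for (d in 1:8) {
      s <- start_shift + r * dirs[d, ]
      vals[d] <- score(s)
      if (!is.na(vals[d]) && vals[d] > best_val) {
        best_val <- vals[d]; best_shift <- s
      }
    }
    bd <- which.max(vals)   # ties: fixed row-major scan order
    run <- if (!is.na(prev_dir) && bd == prev_dir) run + 1L else 1L
    prev_dir <- bd
    if (run >= stop_count) break
  }
  # refinement: coordinate walk with look-ahead
  cur <- best_shift
  cur_val <- best_val
  repeat {
    improved <- FALSE
    for (dim_i in 1:2) {
      for (sgn in c(-1L, 1L)) {
        repeat {
          stepped <- FALSE
          for (k in seq_len(lookahead)) {
            cand <- cur
            cand[dim_i] <- cand[dim_i] + sgn * k
            v <- score(cand)
            if (!is.na(v) && v > cur_val) {
              cur <- cand; cur_val <- v
              stepped <- TRUE; improved <- TRUE
              break
            }
          }
          if (!stepped) break
        }
      }
    }
    if (!improved) {
      # the per-dimension walk cannot take simultaneous diagonal steps;
      # re-probe the 8 compass neighbours (the coarse stage's move set at
      # radius 1) and resume if one improves
      diag_gain <- FALSE
      for (d in 1:8) {
        cand <- cur + dirs[d, ]
        v <- score(cand)
        if (!is.na(v) && v > cur_val) {
          cur <- cand; cur_val <- v; diag_gain <- TRUE
          break
        }
      }
      if (!diag_gain) break
    }
  }
  list(shift = as.integer(cur), correlation = cur_val, degenerate = FALSE)
}

#' Register a time-lapse movie by translation
#'
#' Implements iterative correlation hill-climbing with adaptive reference
#' frames. The movie is intensity-capped ([cap_intensities()]) for the
#' search; the first frame is the initial reference; each frame's best shift
#' seeds the next frame's search (gradual drifts stay cheap). The reference
#' is replaced by the current registered frame when its correlation falls at
#' least `switch_sd` SDs below the running mean of accepted correlations
#' (a drop typically signals a morphology change), and additionally every
#' three frames in `slice_mode` (brain-slice movies). Output frames are
#' shifted by cyclic rolling with the wrapped margins zero-filled.
#'
#' @param movie a [movie_stack()] object (raw; capping is applied
#'   internally for the search only).
#' @param k_sd cap multiple passed to [cap_intensities()].
#' @param register_channel channel name or index used for the search; the
#'   resulting shifts are applied to all channels.
#' @param slice_mode logical; renew the reference every three frames.
#' @param switch_sd reference-switch threshold in SDs (default 2).
#' @param switch_both_directions if `TRUE`, switch on absolute deviation from
#'   the running mean rather than only on drops below it.
#' @param lookahead,max_radius,stop_count passed to [find_shift()].
#' @return list with `movie` (registered [movie_stack()]) and `shifts`, a
#'   `ShiftSeries` data frame with columns
#'   `frame, dy_px, dx_px, correlation, reference_frame`.
#' @export
register_movie <- function(movie, k_sd = 6, register_channel = 1L,
                           slice_mode = FALSE, switch_sd = 2,
                           switch_both_directions = FALSE,
                           lookahead = 2L, max_radius = 15L,
                           stop_count = 5L) {
  stopifnot(inherits(movie, "MovieStack"))
  nt <- n_frames(movie)
  capped <- cap_intensities(movie, k_sd = k_sd)
  arr <- capped$channels[[register_channel]]
  shifts <- matrix(0L, nt, 2)
  corrs <- rep(NA_real_, nt)
  ref_idx <- rep(1L, nt)
  if (nt > 1L) {
    ref <- arr[, , 1]
    cur_ref <- 1L
    accepted <- numeric(0)
    prev_shift <- c(0L, 0L)
    for (t in 2:nt) {
      fs <- find_shift(ref, arr[, , t], start_shift = prev_shift,
                       lookahead = lookahead, max_radius = max_radius,
                       stop_count = stop_count)
      shifts[t, ] <- fs$shift
      corrs[t] <- fs$correlation
      ref_idx[t] <- cur_ref
      prev_shift <- fs$shift
      switch_now <- FALSE
      if (!fs$degenerate && length(accepted) >= 3L) {
        mu <- mean(accepted); s <- stats::sd(accepted)
        if (is.finite(s) && s > 0) {
          dev <- fs$correlation - mu
          switch_now <- if (switch_both_directions) abs(dev) >= switch_sd * s
                        else dev <= -switch_sd * s
        }
      }
      if (slice_mode && (t - cur_ref) >= 3L) switch_now <- TRUE
      if (!fs$degenerate) accepted <- c(accepted, fs$correlation)
      if (switch_now) {
        ref <- roll_matrix(arr[, , t], shifts[t, 1], shifts[t, 2])
        cur_ref <- t
        accepted <- numeric(0)
      }
    }
  }
  out <- movie
  out$channels <- lapply(movie$channels, function(a) {
    for (t in seq_len(nt)) {
      a[, , t] <- translate_zero(a[, , t], shifts[t, 1], shifts[t, 2])
    }
    a
  })
  shift_series <- data.frame(
    frame = seq_len(nt), dy_px = shifts[, 1], dx_px = shifts[, 2],
    correlation = corrs, reference_frame = ref_idx)
  class(shift_series) <- c("ShiftSeries", "data.frame")
  list(movie = out, shifts = shift_series)
}
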