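#' Simulate EB3 comet tracks with known orientation
#'
#' Comets travel along the configured neurite paths at polymerisation speeds
#' of 12-18 um/min. Each comet moves tip-ward (plus-end-out microtubule) with
#' probability `fraction_plus_end_out`, otherwise soma-ward. No images are
#' rendered: the output is a track table as an external tracker would
#' produce, plus the true orientation labels.
#'
#' @param config a [sim_config()] object (`frame_interval` is the comet-movie
#'   interval, typically a few seconds).
#' @param fraction_plus_end_out probability in \[0, 1\] that a comet moves
#'   tip-ward.
#' @param n_comets number of comets.
#' @param speed_range_um_min range of comet speeds, default `c(12, 18)`.
#' @param lifetime_frames integer range of comet lifetimes in frames.
#' @param position_noise_px SD of isotropic localisation noise added to the
#'   track points (0 = noiseless).
#' @return list with `tracks` (data frame `comet_id, frame, y_px, x_px`),
#'   `paths`, and `ground_truth` (logical `plus_end_out` per comet, speeds,
#'   neurite assignment).
#' @export
simulate_comet_tracks <- function(config, fraction_plus_end_out,
                                  n_comets = 100L,
                                  speed_range_um_min = c(12, 18),
                                  lifetime_frames = c(6L, 15L),
                                  position_noise_px = 0) {
  validate_sim_config(config)
  if (fraction_plus_end_out < 0 || fraction_plus_end_out > 1)
    stop("fraction_plus_end_out must be in [0, 1]")
  set.seed(config$seed)
  paths <- sim_neurite_paths(config)
  dt_min <- config$frame_interval / 60
  rows <- list()
  plus_out <- logical(n_comets)
  speeds <- numeric(n_comets)
  neurite <- integer(n_comets)
  for (k in seq_len(n_comets)) {
    ni <- sample.int(config$n_neurites, 1L)
    path <- paths[[ni]]
    L <- max(path$arclen_um)
    plus_out[k] <- stats::runif(1) < fraction_plus_end_out
    sp <- stats::runif(1, speed_range_um_min[1], speed_range_um_min[2])
    life <- sample(seq(lifetime_frames[1], lifetime_frames[2]), 1L)
    s0 <- stats::runif(1, 0.5, 0.85 * L)
    dirn <- if (plus_out[k]) 1 else -1
    s <- s0 + dirn * sp * dt_min * (seq_len(life) - 1L)
    s <- s[s >= 0 & s <= L]
    if (length(s) < 3L) s <- s0 + dirn * sp * dt_min * (0:2) * 0.5
    s <- pmin(pmax(s, 0), L)
    pts <- t(vapply(s, function(si) path_point_at(path, si), c(y = 0, x = 0)))
    if (position_noise_px > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, position_noise_px),
                          ncol = 2)
    }
    rows[[k]] <- data.frame(comet_id = k, frame = seq_along(s),
                            y_px = pts[, 1], x_px = pts[, 2])
    speeds[k] <- sp
    neurite[k] <- ni
  }
  list(
    tracks = do.call(rbind, rows),
    paths = paths,
    ground_truth = new_ground_truth(
      plus_end_out = plus_out,
      speed_um_min = speeds,
      neurite = neurite,
      fraction_plus_end_out = fraction_plus_end_out
    )
  )
}
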