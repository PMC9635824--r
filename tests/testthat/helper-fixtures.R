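# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# A soft neuron fixture: bright disk soma plus a horizontal bar neurite.
make_disk_frame <- function(h = 120, w = 120, cy = 60, cx = 30, r = 12,
                            soma_val = 100, bg = 10) {
  yy <- matrix(seq_len(h) - 1, h, w)
  xx <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  soma_val * (sqrt((yy - cy)^2 + (xx - cx)^2) <= r) + bg
}

make_bar_neuron <- function(bar_rows = 59:61, bar_cols = 43:110,
                            bar_val = 80, ...) {
  fr <- make_disk_frame(...)
  fr[bar_rows, bar_cols] <- bar_val
  fr
}

# Random multi-blob scene for registration trials.
random_blob_scene <- function(h = 64, w = 64, n_blobs = 6) {
  sc <- matrix(0, h, w)
  yy <- matrix(seq_len(h) - 1, h, w)
  xx <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 0.2 * h, 0.8 * h); cx <- runif(1, 0.2 * w, 0.8 * w)
    s <- runif(1, 2, 5)
    sc <- sc + runif(1, 20, 60) * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * s^2))
  }
  sc
}

# Exhaustive correlation search over a +/- window: the registration oracle.
exhaustive_shift <- function(ref, frame, window = 10L) {
  best <- c(0L, 0L); bv <- -2
  for (dy in -window:window) {
    for (dx in -window:window) {
      v <- cor(as.vector(ref), as.vector(roll_matrix(frame, dy, dx)))
      if (!is.na(v) && v > bv) { bv <- v; best <- c(dy, dx) }
    }
  }
  list(shift = best, correlation = bv)
}

# Dynamic-programming oracle for the swing counter: maximum number of
# alternating half-swings of size >= delta, independent of the greedy
# hysteresis implementation.
cycle_oracle <- function(x, delta = 0.2) {
  n <- length(x)
  if (n < 2L) return(0L)
  up <- dn <- rep(0L, n)
  for (i in 2:n) {
    up[i] <- up[i - 1L]; dn[i] <- dn[i - 1L]
    j <- seq_len(i - 1L)
    rise <- x[i] - x[j] >= delta
    fall <- x[j] - x[i] >= delta
    if (any(rise)) up[i] <- max(up[i], max(dn[j][rise]) + 1L)
    if (any(fall)) dn[i] <- max(dn[i], max(up[j][fall]) + 1L)
  }
  max(up[n], dn[n])
}

# Recover a signed patch speed through the full pipeline (positive value =
# retrograde drift recovered).
recover_patch_speed <- function(cfg, n_patches = 1L) {
  sim <- simulate_patch_movie(cfg)
  reg <- register_movie(sim$movie, register_channel = "tubulin")
  signed <- function(tr) {
    fm <- speed_from_track(tr)
    if (fm$direction == "retrograde") fm$speed_um_min else -fm$speed_um_min
  }
  if (n_patches == 1L) {
    signed(track_patch(reg$movie, sim$ground_truth$paths[[1]]))
  } else {
    vapply(track_patch(reg$movie, sim$ground_truth$paths[[1]],
                       n_patches = n_patches), signed, 0)
  }
}

# Intensity-weighted centroid of a frame, in pixel coordinates (0-based).
frame_centroid <- function(frame) {
  w <- frame - min(frame)
  yy <- matrix(seq_len(nrow(frame)) - 1, nrow(frame), ncol(frame))
  xx <- matrix(rep(seq_len(ncol(frame)) - 1, each = nrow(frame)), nrow(frame))
  c(sum(yy * w), sum(xx * w)) / sum(w)
}
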