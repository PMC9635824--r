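# Rendering primitives shared by the movie simulators. All coordinates are
# 0-based (row, column) pixel positions; matrices are indexed 1-based.

# Distance of every pixel to the nearest path pixel, via EBImage's
# Euclidean distance map on the inverted path mask.
path_distance_map <- function(h, w, paths) {
  mask <- matrix(1, h, w)
  for (p in paths) {
    yy <- pmin(pmax(round(p$y_px) + 1L, 1L), h)
    xx <- pmin(pmax(round(p$x_px) + 1L, 1L), w)
    mask[cbind(yy, xx)] <- 0
  }
  d <- EBImage::distmap(EBImage::Image(mask))
  matrix(as.numeric(EBImage::imageData(d)), h, w)
}

# Static scene of the tubulin channel: soft-edged soma disk plus neurites
# with Gaussian cross-section, no background offset.
render_scene <- function(config, paths) {
  h <- config$image_size[1]; w <- config$image_size[2]
  ctr <- soma_center_px(config)
  yy <- matrix(seq_len(h) - 1L, h, w)
  xx <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  d_soma <- sqrt((yy - ctr[1])^2 + (xx - ctr[2])^2)
  r0 <- config$soma_radius_um / config$pixel_size
  soma <- config$soma_amp * pmin(pmax((r0 + 1.5 - d_soma) / 1.5, 0), 1)
  d_path <- path_distance_map(h, w, paths)
  neur <- config$neurite_amp * exp(-d_path^2 / (2 * config$neurite_sigma_px^2))
  matrix(pmax(soma, neur), h, w)
}

# Splat a 2D Gaussian of the given sigma (px) and total weight at a
# (possibly fractional) 0-based position into `img`. The kernel is
# normalised so a line of unit impulses spaced 1 px has ridge value ~1.
splat_gaussian <- function(img, y0, x0, sigma, weight) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  ys <- max(1L, floor(y0) + 1L - r):min(h, floor(y0) + 1L + r)
  xs <- max(1L, floor(x0) + 1L - r):min(w, floor(x0) + 1L + r)
  if (!length(ys) || !length(xs)) return(img)
  dy <- (ys - 1L) - y0
  dx <- (xs - 1L) - x0
  k <- outer(dy^2, dx^2, "+")
  img[ys, xs] <- img[ys, xs] +
    weight * exp(-k / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  img
}

# Render a patch (Gaussian profile in arc length) onto an empty frame by
# splatting weighted impulses along the path.
render_patch <- function(h, w, path, center_um, sigma_um, amp, sigma_px) {
  img <- matrix(0, h, w)
  wgt <- amp * exp(-(path$arclen_um - center_um)^2 / (2 * sigma_um^2))
  keep <- which(wgt > amp * 1e-5)
  for (k in keep) {
    img <- splat_gaussian(img, path$y_px[k], path$x_px[k], sigma_px, wgt[k])
  }
  img
}

# Render a point-like punctum (isotropic Gaussian spot of peak `amp`).
render_spot <- function(img, y0, x0, sigma, amp) {
  splat_gaussian(img, y0, x0, sigma, amp * sigma * sqrt(2 * pi))
}

# Poisson shot noise (photons per unit = scaling) then Gaussian read noise.
apply_noise <- function(frame, gaussian_sd, poisson_scaling) {
  out <- frame
  if (poisson_scaling > 0) {
    lam <- pmax(out, 0) * poisson_scaling
    out <- matrix(stats::rpois(length(lam), lam), nrow(out)) / poisson_scaling
  }
  if (gaussian_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), 0, gaussian_sd), nrow(out))
  }
  out
}

# Integer (or continuous) jitter random walk; returns n_frames x 2 matrix of
# absolute (dy, dx) shifts, first frame zero.
sim_jitter <- function(config) {
  nt <- config$n_frames
  J <- matrix(0, nt, 2)
  if (config$jitter_max_px > 0 && nt > 1L) {
    m <- config$jitter_max_px
    if (config$jitter_subpixel) {
      steps <- matrix(stats::runif(2 * (nt - 1L), -m, m), ncol = 2)
    } else {
      steps <- matrix(sample(seq(-m, m), 2 * (nt - 1L), replace = TRUE),
                      ncol = 2)
    }
    J[-1, ] <- apply(steps, 2, cumsum)
  }
  colnames(J) <- c("dy", "dx")
  J
}

# Apply an absolute jitter shift to a frame (integer: zero-filled translate;
# subpixel: bilinear shift via the two straddling integer translations).
apply_jitter <- function(frame, dy, dx) {
  if (dy == round(dy) && dx == round(dx)) {
    return(translate_zero(frame, dy, dx))
  }
  fy <- floor(dy); fx <- floor(dx)
  wy <- dy - fy; wx <- dx - fx
  (1 - wy) * (1 - wx) * translate_zero(frame, fy, fx) +
    (1 - wy) * wx * translate_zero(frame, fy, fx + 1) +
    wy * (1 - wx) * translate_zero(frame, fy + 1, fx) +
    wy * wx * translate_zero(frame, fy + 1, fx + 1)
}

new_ground_truth <- function(...) {
  structure(list(...), class = "GroundTruth")
}
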