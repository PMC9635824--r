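#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-microscopy generator. The defaults
#' describe the imaging regime the package targets: a developing neuron at
#' 0.22 um/px, 30-s frames, 10 min of imaging, photoconverted patches
#' drifting somatally at 0.53 um/min against ~5:1 signal-to-noise, and
#' integer frame-to-frame stage jitter of up to 3 px.
#'
#' Patch drift speeds are signed: negative values move toward the soma
#' (retrograde), positive away from it.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval seconds between frames (> 0).
#' @param n_frames number of frames (>= 2).
#' @param n_neurites number of neurites emerging from the soma.
#' @param neurite_length_um neurite length(s) in um, recycled over neurites.
#' @param neurite_curvature path curvature in radians per pixel step.
#' @param neurite_sigma_px Gaussian cross-section sigma of rendered neurites
#'   (px); emulates the diffraction-limited appearance.
#' @param neurite_amp peak intensity of the neurite shaft.
#' @param soma_radius_um soma radius in um.
#' @param soma_amp peak soma intensity.
#' @param background additive background offset of the tubulin channel.
#' @param patch_start_um initial arc-length position(s) of photoconverted
#'   patches (um from the soma); one entry per patch.
#' @param patch_speed_um_min signed drift speed(s) in um/min, recycled to the
#'   number of patches.
#' @param patch_neurite neurite index carrying each patch.
#' @param patch_sigma_um Gaussian half-width of the patch along the neurite.
#' @param patch_amp peak patch intensity in the converted channel.
#' @param jitter_max_px maximum per-frame jitter step (pixels, integer walk).
#' @param jitter_subpixel if `TRUE`, jitter steps are continuous rather than
#'   integer (robustness testing only; registration is integer-shift).
#' @param noise_gaussian_sd SD of additive Gaussian read noise.
#' @param poisson_scaling photons per intensity unit for shot noise
#'   (0 disables the Poisson component).
#' @param bleach_rate_per_min exponential bleaching rate (1/min) applied to
#'   all fluorescent signal (not the camera offset).
#' @param seed integer seed; identical configs produce identical movies.
#' @return a validated list of class `SimConfig`.
#' @export
sim_config <- function(image_size = c(160L, 160L),
                       pixel_size = 0.22,
                       frame_interval = 30,
                       n_frames = 21L,
                       n_neurites = 1L,
                       neurite_length_um = 25,
                       neurite_curvature = 0.003,
                       neurite_sigma_px = 1.5,
                       neurite_amp = 60,
                       soma_radius_um = 2.2,
                       soma_amp = 100,
                       background = 20,
                       patch_start_um = 15,
                       patch_speed_um_min = -0.53,
                       patch_neurite = 1L,
                       patch_sigma_um = 0.8,
                       patch_amp = 50,
                       jitter_max_px = 3L,
                       jitter_subpixel = FALSE,
                       noise_gaussian_sd = 10,
                       poisson_scaling = 0.1,
                       bleach_rate_per_min = 0.01,
                       seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    n_neurites = as.integer(n_neurites),
    neurite_length_um = neurite_length_um,
    neurite_curvature = neurite_curvature,
    neurite_sigma_px = neurite_sigma_px, neurite_amp = neurite_amp,
    soma_radius_um = soma_radius_um, soma_amp = soma_amp,
    background = background,
    patch_start_um = patch_start_um,
    patch_speed_um_min = patch_speed_um_min,
    patch_neurite = as.integer(patch_neurite),
    patch_sigma_um = patch_sigma_um, patch_amp = patch_amp,
    jitter_max_px = jitter_max_px, jitter_subpixel = isTRUE(jitter_subpixel),
    noise_gaussian_sd = noise_gaussian_sd,
    poisson_scaling = poisson_scaling,
    bleach_rate_per_min = bleach_rate_per_min,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$image_size) == 2L, all(cfg$image_size >= 16L),
    cfg$pixel_size > 0, cfg$frame_interval > 0, cfg$n_frames >= 2L,
    cfg$n_neurites >= 1L, all(cfg$neurite_length_um > 0),
    cfg$neurite_sigma_px > 0, cfg$soma_radius_um > 0,
    cfg$jitter_max_px >= 0, cfg$noise_gaussian_sd >= 0,
    cfg$poisson_scaling >= 0, cfg$bleach_rate_per_min >= 0,
    length(cfg$seed) == 1L, is.finite(cfg$seed)
  )
  invisible(cfg)
}

# Soma centre in 0-based pixel coordinates. A single neurite gets an
# off-centre soma so the default 25-um neurite fits diagonally; several
# neurites radiate from the image centre.
soma_center_px <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  if (config$n_neurites == 1L) c(0.25 * h, 0.25 * w) else c(h / 2, w / 2)
}

#' Generate the true neurite paths of a configuration
#'
#' Paths step one pixel at a time from the soma edge outward along a gently
#' curving heading. Coordinates are 0-based (row, column); arc length is the
#' cumulative step length in um.
#'
#' @param config a [sim_config()] object.
#' @return list of `NeuriteBranch` data frames with columns
#'   `y_px, x_px, arclen_um`.
#' @export
sim_neurite_paths <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  ctr <- soma_center_px(config)
  r0 <- config$soma_radius_um / config$pixel_size
  lens <- rep_len(config$neurite_length_um, config$n_neurites)
  margin <- 5
  headings <- if (config$n_neurites == 1L) {
    pi / 4
  } else {
    seq(0, 2 * pi, length.out = config$n_neurites + 1L)[-1] + pi / 7
  }
  paths <- vector("list", config$n_neurites)
  for (i in seq_len(config$n_neurites)) {
    n_px <- max(2L, round(lens[i] / config$pixel_size) + 1L)
    th <- headings[i] + config$neurite_curvature * (seq_len(n_px) - 1L)
    y <- ctr[1] + r0 * sin(headings[i]) + cumsum(c(0, sin(th[-n_px])))
    x <- ctr[2] + r0 * cos(headings[i]) + cumsum(c(0, cos(th[-n_px])))
    if (any(y < margin | y > h - 1 - margin | x < margin | x > w - 1 - margin))
      stop(sprintf("neurite %d exits the frame; enlarge image_size or shorten neurite_length_um", i))
    paths[[i]] <- new_neurite_branch(y, x, config$pixel_size,
                                     neurite_id = i, branch_id = 1L)
  }
  paths
}

# NeuriteBranch constructor: ordered path from soma outward.
new_neurite_branch <- function(y, x, pixel_size, neurite_id = 1L,
                               branch_id = 1L, intensity = NULL) {
  df <- data.frame(
    y_px = y, x_px = x,
    arclen_um = path_arclength(y, x, pixel_size)
  )
  if (!is.null(intensity)) df$intensity <- intensity
  attr(df, "pixel_size") <- pixel_size
  attr(df, "neurite_id") <- neurite_id
  attr(df, "branch_id") <- branch_id
  class(df) <- c("NeuriteBranch", "data.frame")
  df
}

#' Interpolate the (y, x) position at an arc length along a path
#' @param path a `NeuriteBranch`.
#' @param arclen_um arc length in um (clamped to the path range).
#' @return named vector `c(y, x)` in 0-based pixels.
#' @export
path_point_at <- function(path, arclen_um) {
  a <- path$arclen_um
  s <- pmin(pmax(arclen_um, a[1]), a[length(a)])
  y <- stats::approx(a, path$y_px, xout = s, ties = "ordered")$y
  x <- stats::approx(a, path$x_px, xout = s, ties = "ordered")$y
  c(y = y, x = x)
}
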