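#' Simulate a photoconversion pulse-chase movie
#'
#' Renders a two-channel time-lapse movie of a neuron whose photoconverted
#' tubulin patches drift along a neurite at a configured signed speed
#' (negative = retrograde, toward the soma). The `tubulin` channel carries
#' the whole-tubulin scene (soma, neurites, background); the `converted`
#' channel carries the patches over a small offset. Global stage jitter,
#' exponential bleaching, and Poisson + Gaussian noise are applied to both
#' channels; the ground truth records the exact per-frame patch arc-length
#' positions and jitter shifts.
#'
#' @param config a [sim_config()] object; `patch_start_um`,
#'   `patch_speed_um_min` and `patch_neurite` define one patch per entry.
#' @return list with elements `movie` (a [movie_stack()]) and `ground_truth`.
#' @export
simulate_patch_movie <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  paths <- sim_neurite_paths(config)
  n_patches <- max(length(config$patch_start_um),
                   length(config$patch_speed_um_min))
  s0 <- rep_len(config$patch_start_um, n_patches)
  v <- rep_len(config$patch_speed_um_min, n_patches)
  pn <- rep_len(config$patch_neurite, n_patches)
  for (p in seq_len(n_patches)) {
    L <- max(paths[[pn[p]]]$arclen_um)
    if (s0[p] < 0 || s0[p] > L)
      stop(sprintf("patch %d initial position %.2f um is beyond neurite length %.2f um",
                   p, s0[p], L))
  }
  nt <- config$n_frames
  h <- config$image_size[1]; w <- config$image_size[2]
  t_min <- (seq_len(nt) - 1L) * config$frame_interval / 60
  pos <- outer(t_min, v) + matrix(s0, nt, n_patches, byrow = TRUE)
  for (p in seq_len(n_patches)) {
    L <- max(paths[[pn[p]]]$arclen_um)
    if (any(pos[, p] < 0 | pos[, p] > L))
      stop(sprintf("patch %d drifts beyond the neurite during the movie", p))
  }
  scene <- render_scene(config, paths)
  jit <- sim_jitter(config)
  bleach <- exp(-config$bleach_rate_per_min * t_min)
  tub <- array(0, c(h, w, nt))
  conv <- array(0, c(h, w, nt))
  conv_offset <- config$background / 4
  for (t in seq_len(nt)) {
    patch_img <- matrix(0, h, w)
    for (p in seq_len(n_patches)) {
      patch_img <- patch_img + render_patch(
        h, w, paths[[pn[p]]], pos[t, p], config$patch_sigma_um,
        config$patch_amp, config$neurite_sigma_px)
    }
    ft <- bleach[t] * scene + config$background
    fc <- bleach[t] * patch_img + conv_offset
    ft <- apply_jitter(ft, jit[t, 1], jit[t, 2])
    fc <- apply_jitter(fc, jit[t, 1], jit[t, 2])
    tub[, , t] <- apply_noise(ft, config$noise_gaussian_sd,
                              config$poisson_scaling)
    conv[, , t] <- apply_noise(fc, config$noise_gaussian_sd,
                               config$poisson_scaling)
  }
  movie <- movie_stack(list(tubulin = tub, converted = conv),
                       config$pixel_size, config$frame_interval)
  gt <- new_ground_truth(
    paths = paths,
    patch_neurite = pn,
    patch_speed_um_min = v,
    patch_positions_um = pos,
    jitter_px = jit,
    bleach_factor = bleach,
    time_min = t_min
  )
  list(movie = movie, ground_truth = gt)
}

#' Simulate a CAMSAP3 punctum movie
#'
#' Point-like minus-end puncta appear along each neurite and drift somatally
#' at the configured speed; a per-neurite speed change at a configured frame
#' supports slowdown-detection tests. Puncta that reach the soma disappear.
#'
#' @param config a [sim_config()] object.
#' @param puncta_per_neurite number of puncta per neurite (>= 1).
#' @param punctum_speed_um_min signed drift speed per neurite (recycled);
#'   negative = retrograde.
#' @param slowdown optional `list(neurite =, frame =, factor =)`: from frame
#'   `frame` on, the named neurite's speed is multiplied by `factor`.
#' @param punctum_sigma_px spot sigma in px.
#' @return list with `movie` (single channel `camsap`) and `ground_truth`
#'   (per-punctum per-frame arc positions, speeds, slowdown onset).
#' @export
simulate_camsap_movie <- function(config, puncta_per_neurite = 3L,
                                  punctum_speed_um_min = -0.4,
                                  slowdown = NULL,
                                  punctum_sigma_px = 1.2) {
  validate_sim_config(config)
  stopifnot(puncta_per_neurite >= 1L)
  set.seed(config$seed)
  paths <- sim_neurite_paths(config)
  nn <- config$n_neurites
  nt <- config$n_frames
  h <- config$image_size[1]; w <- config$image_size[2]
  speeds <- rep_len(punctum_speed_um_min, nn)
  t_min <- (seq_len(nt) - 1L) * config$frame_interval / 60
  dt_min <- config$frame_interval / 60
  ids <- list(); pos_list <- list()
  for (i in seq_len(nn)) {
    L <- max(paths[[i]]$arclen_um)
    starts <- sort(stats::runif(puncta_per_neurite, 0.25 * L, 0.95 * L))
    v_t <- rep(speeds[i], nt)
    if (!is.null(slowdown) && slowdown$neurite == i) {
      v_t[seq_len(nt) >= slowdown$frame] <- speeds[i] * slowdown$factor
    }
    disp <- cumsum(c(0, v_t[-nt])) * dt_min
    for (p in seq_len(puncta_per_neurite)) {
      s <- starts[p] + disp
      s[s < 0.5] <- NA  # reached the soma
      ids[[length(ids) + 1L]] <- c(neurite = i, punctum = p)
      pos_list[[length(pos_list) + 1L]] <- s
    }
  }
  pos <- do.call(cbind, pos_list)
  scene <- render_scene(config, paths) * 0.15  # faint cytosolic context
  jit <- sim_jitter(config)
  bleach <- exp(-config$bleach_rate_per_min * t_min)
  cam <- array(0, c(h, w, nt))
  for (t in seq_len(nt)) {
    img <- scene * 0
    for (k in seq_len(ncol(pos))) {
      if (is.na(pos[t, k])) next
      ni <- ids[[k]]["neurite"]
      pt <- path_point_at(paths[[ni]], pos[t, k])
      img <- render_spot(img, pt["y"], pt["x"], punctum_sigma_px,
                         config$patch_amp)
    }
    f <- bleach[t] * (img + scene) + config$background / 4
    f <- apply_jitter(f, jit[t, 1], jit[t, 2])
    cam[, , t] <- apply_noise(f, config$noise_gaussian_sd,
                              config$poisson_scaling)
  }
  movie <- movie_stack(list(camsap = cam), config$pixel_size,
                       config$frame_interval)
  gt <- new_ground_truth(
    paths = paths,
    punctum_neurite = vapply(ids, function(z) z[["neurite"]], 0),
    punctum_speed_um_min = speeds[vapply(ids, function(z) z[["neurite"]], 0)],
    punctum_positions_um = pos,
    slowdown = slowdown,
    slowdown_onset_min = if (is.null(slowdown)) NA_real_ else
      (slowdown$frame - 1L) * dt_min,
    jitter_px = jit,
    time_min = t_min
  )
  list(movie = movie, ground_truth = gt)
}
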