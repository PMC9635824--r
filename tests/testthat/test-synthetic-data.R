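test_that("identical configs give bit-identical movies, different seeds differ", {
  cfg <- sim_config(seed = 3)
  a <- simulate_patch_movie(cfg)
  b <- simulate_patch_movie(cfg)
  expect_identical(a$movie$channels, b$movie$channels)
  expect_identical(a$ground_truth$patch_positions_um,
                   b$ground_truth$patch_positions_um)
  c <- simulate_patch_movie(sim_config(seed = 4))
  expect_false(identical(a$movie$channels$tubulin, c$movie$channels$tubulin))
})

test_that("patch kinematics follow speed x time and degenerate cases", {
  # stationary, clean: the converted-channel centroid is identical in all
  # frames, and matches the recorded true position within 0.25 px
  cfg0 <- sim_config(seed = 1, patch_speed_um_min = 0, jitter_max_px = 0,
                     noise_gaussian_sd = 0, poisson_scaling = 0,
                     bleach_rate_per_min = 0, neurite_curvature = 0)
  sim0 <- simulate_patch_movie(cfg0)
  cents <- t(sapply(seq_len(n_frames(sim0$movie)), function(t)
    frame_centroid(get_frame(sim0$movie, t, "converted"))))
  expect_lt(max(abs(sweep(cents, 2, cents[1, ]))), 1e-9)
  p0 <- path_point_at(sim0$ground_truth$paths[[1]], 15)
  expect_lt(max(abs(cents[1, ] - p0)), 0.25)

  # -0.5 um/min for 10 min at 30-s frames ends 5 um closer to the soma
  cfg1 <- sim_config(seed = 1, patch_speed_um_min = -0.5)
  sim1 <- simulate_patch_movie(cfg1)
  pos <- sim1$ground_truth$patch_positions_um[, 1]
  expect_equal(pos[1] - pos[length(pos)], 5)

  # conservation: without bleaching, noise or jitter the summed converted
  # intensity is constant
  tot <- sapply(seq_len(n_frames(sim0$movie)), function(t)
    sum(get_frame(sim0$movie, t, "converted")))
  expect_lt(diff(range(tot)) / tot[1], 1e-6)

  # patch starting beyond the neurite is rejected
  expect_error(simulate_patch_movie(sim_config(patch_start_um = 40)),
               "beyond neurite length")
})

test_that("tracked drift speed matches a least-squares fit on noisy movies", {
  cfg <- sim_config(seed = 8, jitter_max_px = 0)
  sim <- simulate_patch_movie(cfg)
  tr <- track_patch(sim$movie, sim$ground_truth$paths[[1]])
  fit <- lm(arclen_um ~ time_min, data = tr)
  se <- summary(fit)$coefficients["time_min", "Std. Error"]
  expect_lt(abs(coef(fit)["time_min"] - (-0.53)), 3 * se)
})

test_that("CAMSAP3 movie kinematics and slowdown bookkeeping are exact", {
  cfg <- sim_config(seed = 2, n_frames = 15, noise_gaussian_sd = 0,
                    poisson_scaling = 0, jitter_max_px = 0,
                    bleach_rate_per_min = 0)
  sim <- simulate_camsap_movie(cfg, puncta_per_neurite = 1,
                               punctum_speed_um_min = -0.4)
  # kymograph trace of the single punctum has slope -0.4 um/min
  kym <- sample_kymograph(sim$movie, sim$ground_truth$paths[[1]],
                          width_px = 11, channel = "camsap")
  flow <- camsap_flow_series(extract_camsap_traces(kym), kym$pixel_size,
                             kym$frame_interval, n_frames = 15)
  expect_equal(stats::median(flow, na.rm = TRUE), 0.4, tolerance = 0.08)

  sl <- simulate_camsap_movie(cfg, slowdown = list(neurite = 1, frame = 8,
                                                   factor = 0.5))
  expect_equal(sl$ground_truth$slowdown_onset_min, 7 * cfg$frame_interval / 60)

  # mixed speeds: ground-truth trace slopes reproduce the configured median
  cfgm <- sim_config(seed = 6, n_neurites = 5, neurite_length_um = 14,
                     image_size = c(220, 220), n_frames = 11,
                     noise_gaussian_sd = 0, poisson_scaling = 0,
                     jitter_max_px = 0, bleach_rate_per_min = 0)
  speeds <- c(-0.2, -0.3, -0.4, -0.6, -0.8)
  simm <- simulate_camsap_movie(cfgm, puncta_per_neurite = 2,
                                punctum_speed_um_min = speeds)
  gt <- simm$ground_truth
  slopes <- apply(gt$punctum_positions_um, 2, function(s) {
    ok <- !is.na(s)
    unname(coef(lm(s[ok] ~ gt$time_min[ok]))[2])
  })
  expect_equal(median(slopes), median(speeds), tolerance = 1e-9)
})

test_that("comet track orientation sampling is Bernoulli with the set rate", {
  cfg <- sim_config(seed = 5, n_neurites = 3, neurite_length_um = 14,
                    image_size = c(200, 200), frame_interval = 2)
  all_out <- simulate_comet_tracks(cfg, 1, n_comets = 40)
  expect_true(all(all_out$ground_truth$plus_end_out))
  all_in <- simulate_comet_tracks(cfg, 0, n_comets = 40)
  expect_false(any(all_in$ground_truth$plus_end_out))
  # tip-ward comets gain arc length
  tr1 <- all_out$tracks[all_out$tracks$comet_id == 1, ]
  path <- all_out$paths[[all_out$ground_truth$neurite[1]]]
  arcs <- vapply(seq_len(nrow(tr1)), function(i) {
    d2 <- (path$y_px - tr1$y_px[i])^2 + (path$x_px - tr1$x_px[i])^2
    path$arclen_um[which.min(d2)]
  }, 0)
  expect_true(all(diff(arcs) >= 0))

  st <- simulate_comet_tracks(cfg, 0.7, n_comets = 200)
  phat <- mean(st$ground_truth$plus_end_out)
  ci <- 2.576 * sqrt(0.7 * 0.3 / 200)
  expect_lt(abs(phat - 0.7), ci)
})

test_that("density traces carry the configured waveform and ground truth", {
  cfg <- sim_config(seed = 1, n_frames = 201, frame_interval = 180,
                    n_neurites = 2)
  flat <- simulate_density_traces(cfg, period_h = 2, amplitude = 0,
                                  noise_sd = 0)
  expect_true(all(abs(flat$traces$density - 1) < 1e-12))

  tri <- simulate_density_traces(cfg, period_h = 2, amplitude = 0.25,
                                 noise_sd = 0)
  expect_equal(tri$ground_truth$total_cycles, 5)
  expect_equal(tri$ground_truth$cycles_per_hour, 0.5)
  expect_equal(max(abs(tri$traces$density - 1)), 0.25, tolerance = 0.03)

  # sub-threshold amplitude yields zero counted cycles after smoothing
  low <- simulate_density_traces(cfg, period_h = 2, amplitude = 0.1,
                                 noise_sd = 0)
  tr <- low$traces$density[low$traces$neurite_id == 1]
  cc <- count_cycles(smooth_trace(tr), delta = 0.2, dt_hours = 0.05)
  expect_identical(cc$full_cycles, 0L)
})

test_that("mass kymographs place the requested fractions in their zones", {
  cfg <- sim_config(seed = 2, n_frames = 18)
  pure <- list(c(1, 0, 0), c(0, 1, 0))
  for (fr in pure) {
    mk <- simulate_mass_kymograph(cfg, fr, noise_sd = 0)
    expect_equal(unname(mk$ground_truth$realized_fractions), fr,
                 tolerance = 1e-5)
  }
  mk <- simulate_mass_kymograph(cfg, c(0.84, 0.06, 0.10), noise_sd = 0)
  # within the discretization of one pixel column
  expect_lt(max(abs(mk$ground_truth$realized_fractions -
                      c(0.84, 0.06, 0.10))), 0.01)
  expect_error(simulate_mass_kymograph(cfg, c(0.5, 0.5, 0.5)), "summing to 1")
})
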