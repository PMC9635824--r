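test_that("patch tracking follows the truth and flags two-patch corridors", {
  # stationary noiseless patch: constant arc-length
  cfg0 <- sim_config(seed = 1, patch_speed_um_min = 0, jitter_max_px = 0,
                     noise_gaussian_sd = 0, poisson_scaling = 0,
                     bleach_rate_per_min = 0)
  sim0 <- simulate_patch_movie(cfg0)
  tr0 <- track_patch(sim0$movie, sim0$ground_truth$paths[[1]])
  expect_lt(diff(range(tr0$arclen_um)), 0.1)

  # drifting noiseless patch: per-frame centroid within 0.5 px of truth
  cfg1 <- sim_config(seed = 1, jitter_max_px = 0, noise_gaussian_sd = 0,
                     poisson_scaling = 0, bleach_rate_per_min = 0)
  sim1 <- simulate_patch_movie(cfg1)
  tr1 <- track_patch(sim1$movie, sim1$ground_truth$paths[[1]])
  err <- tr1$arclen_um - sim1$ground_truth$patch_positions_um[tr1$frame, 1]
  expect_lt(max(abs(err)), 0.5 * cfg1$pixel_size)

  # two patches in the corridor: rejected unless dual-track mode is used
  cfg2 <- sim_config(seed = 2, patch_start_um = c(10, 20),
                     patch_speed_um_min = c(-0.4, -0.4))
  sim2 <- simulate_patch_movie(cfg2)
  expect_error(track_patch(sim2$movie, sim2$ground_truth$paths[[1]]),
               "n_patches = 2")
  trs <- track_patch(sim2$movie, sim2$ground_truth$paths[[1]], n_patches = 2)
  expect_length(trs, 2L)
  expect_lt(abs(trs[[1]]$arclen_um[1] - 10), 1)
  expect_lt(abs(trs[[2]]$arclen_um[1] - 20), 1)
})

test_that("speed_from_track: arithmetic, direction, rejection, reversal", {
  tr <- data.frame(frame = 1:21, time_min = seq(0, 10, by = 0.5),
                   arclen_um = seq(20, 15, length.out = 21))
  fm <- speed_from_track(tr)
  expect_equal(fm$speed_um_min, 0.5)
  expect_identical(fm$direction, "retrograde")
  expect_equal(fm$duration_min, 10)

  fm0 <- speed_from_track(transform(tr, arclen_um = 12))
  expect_identical(fm0$direction, "immobile")
  expect_equal(fm0$speed_um_min, 0)

  short <- tr[1:3, ]
  expect_error(speed_from_track(short), "minimum")

  # time reversal flips the direction, not the magnitude
  rev_tr <- data.frame(frame = 1:21, time_min = tr$time_min,
                       arclen_um = rev(tr$arclen_um))
  fmr <- speed_from_track(rev_tr)
  expect_identical(fmr$direction, "anterograde")
  expect_equal(fmr$speed_um_min, fm$speed_um_min)

  # 3D point tracks work through the Euclidean route
  p3 <- data.frame(time_min = seq(0, 10, length.out = 11),
                   x_um = seq(0, 3, length.out = 11),
                   y_um = seq(0, 4, length.out = 11),
                   z_um = 0)
  expect_equal(speed_from_track(p3)$speed_um_min, 0.5)

  # noisy recovery: the regression oracle agrees with the net estimate to
  # within 3x the fit standard error
  set.seed(7)
  tt <- seq(0, 10, by = 0.5)
  noisy <- data.frame(frame = seq_along(tt), time_min = tt,
                      arclen_um = 15 - 0.53 * tt + rnorm(length(tt), 0, 0.2))
  fit <- lm(arclen_um ~ time_min, data = noisy)
  sigma <- summary(fit)$sigma
  se_net <- sqrt(2) * sigma / 10        # SE of the endpoint estimator
  fmn <- speed_from_track(noisy)
  expect_lt(abs(fmn$speed_um_min - 0.53), 3 * se_net)
})

test_that("patch synchrony is (max - min) / min of traveled distances", {
  expect_equal(patch_synchrony(c(5, 4)), 0.25)
  expect_equal(patch_synchrony(c(3, 3, 3)), 0)
  expect_equal(patch_synchrony(c(6, 5, 4)), 0.5)
  expect_true(is.na(patch_synchrony(c(2, 0))))
  mk <- function(d) data.frame(time_min = c(0, 5), arclen_um = c(10, 10 - d))
  expect_equal(patch_synchrony(list(mk(5), mk(4))), 0.25)
})

test_that("CAMSAP trace extraction and the median flow series", {
  # single noiseless ridge: one trace with the exact slope
  nt <- 12; nc <- 60
  m <- matrix(0, nt, nc)
  for (t in seq_len(nt)) m[t, 40 - 2 * (t - 1)] <- 10
  kym <- new_kymograph(m, 0.22, 30)
  traces <- extract_camsap_traces(kym, threshold = 5)
  expect_length(traces, 1L)
  expect_equal(nrow(traces[[1]]), nt)
  slope_px <- (traces[[1]]$col[nt] - traces[[1]]$col[1]) / (nt - 1)
  expect_equal(slope_px, -2)

  # two parallel ridges 10 px apart -> two traces
  m2 <- m; for (t in seq_len(nt)) m2[t, 50 - 2 * (t - 1)] <- 10
  expect_length(extract_camsap_traces(new_kymograph(m2, 0.22, 30),
                                      threshold = 5), 2L)
  # empty kymograph -> none
  expect_length(extract_camsap_traces(new_kymograph(matrix(0, 5, 9), 0.22, 30),
                                      threshold = 5), 0L)

  # median over retained retrograde traces; anterograde discarded
  ps <- 1; fi <- 60   # 1 um/px, 1-min frames for round numbers
  tr_retro1 <- data.frame(frame = 1:6, col = seq(30, 30 - 5 * 0.3, length.out = 6))
  tr_retro2 <- data.frame(frame = 1:6, col = seq(40, 40 - 5 * 0.5, length.out = 6))
  tr_antero <- data.frame(frame = 1:6, col = seq(10, 10 + 5 * 0.2, length.out = 6))
  flow <- camsap_flow_series(list(tr_retro1, tr_retro2, tr_antero),
                             pixel_size = ps, frame_interval = fi,
                             n_frames = 8)
  expect_equal(flow[3], 0.4)
  expect_true(all(is.na(flow[7:8])))
})

test_that("slowdown detection: criteria, onset, scale invariance", {
  fi <- 120                        # 2-min frames
  nt <- 200                        # ~6.6 h
  t_min <- (seq_len(nt) - 1) * 2
  axon <- rep(0.25, nt); others <- cbind(rep(0.5, nt), rep(0.6, nt))
  M <- cbind(axon = axon, n2 = others[, 1], n3 = others[, 2])
  res <- detect_slowdown(M, "axon", fi)
  expect_true(res$detected)
  expect_equal(res$onset_min, 0)

  # equal flows: evaluable but not detected
  Me <- cbind(axon = rep(0.5, nt), n2 = rep(0.5, nt))
  rese <- detect_slowdown(Me, "axon", fi)
  expect_false(rese$detected)
  expect_true(rese$evaluable)

  # short span: not evaluable (distinct from not detected)
  resx <- detect_slowdown(Me[1:30, ], "axon", fi)
  expect_false(resx$evaluable)

  # a step to 40% at t0 is found within one smoothing window
  t0 <- 150                        # minutes
  ax2 <- ifelse(t_min < t0, 0.5, 0.2)
  M2 <- cbind(axon = ax2, n2 = rep(0.5, nt), n3 = rep(0.55, nt))
  res2 <- detect_slowdown(M2, "axon", fi)
  expect_true(res2$detected)
  expect_lte(abs(res2$onset_min - t0), 200)

  # scale invariance
  res3 <- detect_slowdown(M2 * 3.7, "axon", fi)
  expect_identical(res3$detected, res2$detected)
  expect_identical(res3$onset_min, res2$onset_min)
})

test_that("axon classification applies the three printed rules in order", {
  expect_identical(classify_axon(c(60, 20, 15)), "with_axon")
  expect_identical(classify_axon(c(25, 20)), "no_axon")
  expect_identical(classify_axon(c(35, 28)), "transition")
  expect_identical(classify_axon(c(60, 58)), "transition")
  expect_identical(classify_axon(c(49, 20)), "transition")
  expect_error(classify_axon(55), "two neurites")
})

test_that("neurite background: stated cells, monotone floor, brute force", {
  m <- matrix(7, 10, 20)
  kym <- new_kymograph(m, 0.22, 30)
  expect_equal(neurite_background(kym), 7)
  expect_equal(neurite_background(kym, previous_backgrounds = c(3, 9)), 9)

  set.seed(11)
  m2 <- matrix(runif(10 * 20, 5, 50), 10, 20)
  kym2 <- new_kymograph(m2, 0.22, 30)
  stated <- m2[c(1, 7:10), 1:5]
  expect_equal(neurite_background(kym2), min(stated))
})

test_that("patch spread trims edges by the 10% rule and stays symmetric", {
  # ten equal pixels: exactly one edge pixel removed
  kym <- new_kymograph(rbind(c(rep(0, 5), rep(1, 10), rep(0, 5))) + 0,
                       0.22, 30)
  sp <- patch_spread(kym, start = 10, background = 0, stop_factor = 0)
  expect_equal(sp$spread_um, (10 - 1 - 1) * 0.22)

  # symmetric triangle: spread symmetric about the start
  prof <- c(rep(0, 4), 1:8, 7:1, rep(0, 4))
  nt <- 6
  m <- do.call(rbind, replicate(nt, prof, simplify = FALSE))
  kyms <- new_kymograph(m, 0.22, 30)
  sps <- patch_spread(kyms, start = 12, background = 0, stop_factor = 0)
  expect_equal(sps$retro_speed_um_min, sps$antero_speed_um_min,
               tolerance = 1e-9)

  # widening symmetric profile: equal retro and antero edge speeds > 0
  m2 <- do.call(rbind, lapply(1:8, function(t) {
    w <- 3 + t
    p <- rep(0, 41); p[(21 - w):(21 + w)] <- 5
    p
  }))
  sp2 <- patch_spread(new_kymograph(m2, 0.22, 30), start = 21,
                      background = 0, stop_factor = 0)
  expect_gt(sp2$retro_speed_um_min, 0)
  # equal up to one pixel of edge discretization over the analyzed rows
  elapsed_min <- 7 * 0.5
  expect_lt(abs(sp2$retro_speed_um_min - sp2$antero_speed_um_min),
            1.2 * 0.22 / elapsed_min)
})

test_that("mass distribution: zones, invariances and simulator recovery", {
  cfgf <- flow_config()
  # all mass beyond 1.1 um retrograde of the start
  nc <- 60; start <- 40
  m <- matrix(0, 8, nc); m[, 10:20] <- 5
  kym <- new_kymograph(m + 2, 0.22, 30)    # +2 background everywhere
  md <- mass_distribution(kym, start = start, background = 2)
  expect_equal(unname(md$fractions), c(1, 0, 0), tolerance = 1e-9)

  # point mass at the start
  m2 <- matrix(0, 8, nc); m2[, start] <- 5
  md2 <- mass_distribution(new_kymograph(m2 + 2, 0.22, 30), start = start,
                           background = 2)
  expect_equal(unname(md2$fractions), c(0, 1, 0), tolerance = 1e-9)

  # fractions sum to one and are invariant to adding a constant
  cfg <- sim_config(seed = 6, n_frames = 18)
  mk <- simulate_mass_kymograph(cfg, c(0.84, 0.06, 0.10))
  mda <- mass_distribution(mk$kymograph, start = mk$ground_truth$start_col)
  expect_equal(sum(mda$fractions), 1, tolerance = 1e-9)
  kshift <- mk$kymograph; kshift$data <- kshift$data + 13.7
  mdb <- mass_distribution(kshift, start = mk$ground_truth$start_col)
  expect_equal(unname(mda$fractions), unname(mdb$fractions),
               tolerance = 1e-9)
  # recovery close to the construction (one-column discretization scale)
  expect_lt(max(abs(mda$fractions - mk$ground_truth$fractions)), 0.03)
  # the row-stop rule cuts the analysis where the simulator says it should
  expect_equal(mda$rows_analyzed, mk$ground_truth$n_analyzed_rows)
})

test_that("mean recovered drift over seeded simulations tracks the truth", {
  set.seed(0)
  drifts <- runif(10, 0.2, 1.0)
  err <- vapply(seq_along(drifts), function(i) {
    v <- recover_patch_speed(sim_config(seed = 2000 + i,
                                        patch_speed_um_min = -drifts[i]))
    abs(v - drifts[i])
  }, 0)
  expect_lte(mean(err), 0.05)
})
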