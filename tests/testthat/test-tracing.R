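test_that("soma extraction recovers a disk and excludes thin neurites", {
  fr <- make_disk_frame()
  soma <- extract_soma(fr)
  expect_lt(abs(soma$area - pi * 12^2) / (pi * 12^2), 0.10)
  expect_equal(soma$centroid, c(60, 30), tolerance = 1)

  expect_error(extract_soma(matrix(5, 50, 50)), "no soma")

  fr2 <- make_bar_neuron()
  soma2 <- extract_soma(fr2)
  bar_px <- sum(soma2$mask[59:61, 46:110])
  expect_lte(bar_px, 0.10 * length(59:61) * length(46:110))
})

test_that("threshold search separates levels and fails on uniform frames", {
  fr <- make_bar_neuron()
  soma <- extract_soma(fr)
  thr <- find_neuron_threshold(fr, soma)
  expect_gt(thr, 10)
  expect_lte(thr, 100)
  expect_error(find_neuron_threshold(matrix(5, 60, 60), soma), "uniform")

  # intensity taper along the neurite (locally flat blocks, as in real
  # shafts): the returned threshold keeps >= 95% of the true path
  fr3 <- make_disk_frame()
  taper <- rep(seq(80, 40, by = -5), each = 9)[1:68]
  for (i in seq_along(taper)) fr3[59:61, 42 + i] <- taper[i]
  soma3 <- extract_soma(fr3)
  thr3 <- find_neuron_threshold(fr3, soma3)
  covered <- sum(fr3[60, 43:110] >= thr3)
  expect_gte(covered / 68, 0.95)
})

test_that("gap closing bridges collinear segments but respects direction", {
  base <- matrix(FALSE, 60, 100)
  base[28:32, 5:25] <- TRUE                      # soma blob
  soma <- structure(list(mask = base, centroid = c(29, 14),
                         area = sum(base)), class = "SomaMask")
  bin <- base
  bin[30, 26:50] <- TRUE                          # attached neurite
  bin[30, 54:80] <- TRUE                          # collinear, 3-px gap
  n0 <- max(mtflow:::label_components(bin))
  out <- close_gaps(bin, soma)
  expect_equal(max(mtflow:::label_components(out)), n0 - 1L)

  # a horizontal segment directly above the soma is not bridged: every
  # anchor bearing is roughly perpendicular to the segment's own axis
  bin2 <- base
  bin2[5, 5:25] <- TRUE
  out2 <- close_gaps(bin2, soma)
  expect_equal(max(mtflow:::label_components(out2)), 2L)

  # of two candidate anchors the on-axis one wins even if farther
  bin3 <- base
  bin3[30, 26:44] <- TRUE                        # on-axis anchor arm
  bin3[31:45, 40] <- TRUE                        # off-axis anchor arm (near)
  bin3[30, 50:70] <- TRUE                        # detached collinear segment
  out3 <- close_gaps(bin3, soma)
  expect_true(all(out3[30, 45:49]))              # bridge runs along the axis
  expect_false(any(out3[32:44, 41:49] & !bin3[32:44, 41:49]))
})

test_that("branch construction: geometry, filters and arc length", {
  # straight bar -> one branch whose arc length matches the polyline oracle
  fr <- make_bar_neuron()
  tf <- trace_frame(fr, 0.22)
  expect_length(tf$branches, 1L)
  b <- tf$branches[[1]]
  steps <- sqrt(diff(b$y_px)^2 + diff(b$x_px)^2)
  expect_equal(max(b$arclen_um), sum(steps) * 0.22, tolerance = 1e-9)
  expect_equal(max(b$arclen_um), (nrow(b) - 1) * 0.22, tolerance = 1e-9)

  # Y-shaped neuron: two branches sharing the stem
  fy <- make_bar_neuron()
  for (k in 0:35) fy[(59:61) + k, 80 + k] <- 80
  tfy <- trace_frame(fy, 0.22)
  expect_length(tfy$branches, 2L)
  shared <- branch_overlap(tfy$branches[[1]][1:30, ], tfy$branches[[2]])
  expect_gt(shared, 0.9)

  # a 30-point neurite is dropped by the 40-point filter
  f30 <- make_disk_frame()
  f30[59:61, 43:72] <- 80
  tf30 <- trace_frame(f30, 0.22)
  expect_length(tf30$branches, 0L)
})

test_that("tracing a synthetic neuron recovers the true path", {
  cfg <- sim_config(seed = 2, noise_gaussian_sd = 0, poisson_scaling = 0,
                    jitter_max_px = 0)
  sim <- simulate_patch_movie(cfg)
  fr <- get_frame(sim$movie, 1, "tubulin")
  tf <- trace_frame(fr, cfg$pixel_size)
  expect_gte(length(tf$branches), 1L)
  b <- tf$branches[[which.max(vapply(tf$branches, nrow, 0L))]]
  truth <- sim$ground_truth$paths[[1]]
  # every traced point lies within 1 px of the true path (Hausdorff one way)
  d <- vapply(seq_len(nrow(b)), function(i)
    min(sqrt((truth$y_px - b$y_px[i])^2 + (truth$x_px - b$x_px[i])^2)), 0)
  expect_lte(max(d), 1.5)
  # and at least 95% of the true path length is recovered
  expect_gte(max(b$arclen_um) + cfg$soma_radius_um * 0 + 2,
             0.95 * max(truth$arclen_um))
})

test_that("cross-frame overlapping branches with different origins are excluded", {
  fr <- make_bar_neuron()
  tf <- trace_frame(fr, 0.22)
  b <- tf$branches[[1]]
  # context branch with the same shape but a displaced origin
  ctx <- b
  ctx$y_px <- ctx$y_px + 0.5; ctx$y_px[1] <- ctx$y_px[1] + 10
  ctx$x_px[1] <- ctx$x_px[1] + 10
  soma <- extract_soma(fr)
  thr <- find_neuron_threshold(fr, soma)
  out <- build_branches(fr >= thr, soma, 0.22, intensity = fr,
                        context_branches = list(ctx))
  expect_length(out, 0L)
})
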