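test_that("track accumulation builds a skeletonizable neuron image", {
  # tracks along one straight line -> a single-branch skeleton on the line
  tr <- data.frame(comet_id = rep(1:12, each = 5),
                   frame = rep(1:5, 12),
                   y_px = 30,
                   x_px = rep(seq(8, 74, length.out = 12), each = 5) +
                     rep(0:4, 12))
  img <- tracks_to_neuron_image(tr)
  expect_true(any(img))
  ctx <- comet_skeleton_context(tr, 0.22, soma_center = c(30, 8))
  expect_gte(length(ctx$branches), 1L)
  expect_lte(max(abs(ctx$points$y_px - 30)), 1.5)

  expect_error(tracks_to_neuron_image(tr[0, ]), "empty")

  # two disjoint neurites connected at the soma are both recovered
  cfg <- sim_config(seed = 3, n_neurites = 2, neurite_length_um = 14,
                    image_size = c(200, 200), frame_interval = 2)
  st <- simulate_comet_tracks(cfg, 1, n_comets = 120)
  ctx2 <- comet_skeleton_context(st$tracks, cfg$pixel_size,
                                 soma_center = c(100, 100))
  expect_equal(length(ctx2$branches), 2L)
})

test_that("comet classification is exact on noiseless straight neurites", {
  cfg <- sim_config(seed = 5, n_neurites = 3, neurite_length_um = 14,
                    image_size = c(200, 200), frame_interval = 2,
                    neurite_curvature = 0)
  st <- simulate_comet_tracks(cfg, 0.7, n_comets = 150)
  ctx <- comet_skeleton_context(st$tracks, cfg$pixel_size,
                                soma_center = c(100, 100))
  calls <- classify_comets(st$tracks, ctx)
  truth <- ifelse(st$ground_truth$plus_end_out, "plus_end_out",
                  "minus_end_out")
  det <- calls$label %in% c("plus_end_out", "minus_end_out")
  expect_gt(mean(det), 0.9)
  expect_equal(mean(calls$label[det] == truth[calls$comet_id][det]), 1)

  # recovered plus-end-out fraction within the binomial 99% interval
  os <- orientation_summary(calls)
  expect_lt(abs(os$fraction_plus_end_out - 0.7),
            2.576 * sqrt(0.7 * 0.3 / os$n_determined) + 0.02)

  # time reversal swaps the two determined labels exactly
  rev_tracks <- do.call(rbind, lapply(split(st$tracks, st$tracks$comet_id),
                                      function(tr) {
                                        tr$y_px <- rev(tr$y_px)
                                        tr$x_px <- rev(tr$x_px)
                                        tr
                                      }))
  calls_r <- classify_comets(rev_tracks, ctx)
  expect_identical(sum(calls$label == "plus_end_out"),
                   sum(calls_r$label == "minus_end_out"))
  expect_identical(sum(calls$label == "minus_end_out"),
                   sum(calls_r$label == "plus_end_out"))
  expect_identical(sum(calls$label == "undetermined"),
                   sum(calls_r$label == "undetermined"))
})

test_that("the 65% consensus rule leaves split votes undetermined", {
  # hand-built straight-line context
  n <- 80
  b <- data.frame(y_px = rep(30, n), x_px = seq(10, 10 + n - 1),
                  arclen_um = seq(0, (n - 1)) * 0.22)
  ctx <- list(points = data.frame(y_px = b$y_px, x_px = b$x_px,
                                  arclen_um = b$arclen_um, branch = 1L,
                                  idx = seq_len(n)),
              branches = list(b), soma_center = c(30, 0),
              soma_radius_px = 0)
  # zig-zag track returning to its start: endpoint tie, 3 tip-ward vs 2
  # soma-ward votes = 60% < 65%
  xs <- c(40, 42, 44, 46, 48, 50, 48, 46, 44, 40)
  tr <- data.frame(frame = seq_along(xs), y_px = 30, x_px = xs)
  cc <- classify_comet(tr, ctx)
  expect_identical(cc$method, "angle")
  expect_identical(cc$label, "undetermined")

  # a strongly one-sided vote is called
  xs2 <- c(40, 42, 44, 46, 48, 50, 52, 54, 56, 40)
  cc2 <- classify_comet(data.frame(frame = seq_along(xs2), y_px = 30,
                                   x_px = xs2), ctx)
  expect_identical(cc2$label, "plus_end_out")

  # a track far from any skeleton point is unassigned
  far <- data.frame(frame = 1:4, y_px = 90, x_px = c(10, 12, 14, 16))
  expect_identical(classify_comet(far, ctx)$label, "unassigned")
})

test_that("orientation summaries report fractions over the three labels", {
  calls <- data.frame(comet_id = 1:10,
                      label = c(rep("plus_end_out", 7),
                                rep("minus_end_out", 3)),
                      vote_share = 1, method = "endpoint")
  os <- orientation_summary(calls)
  expect_equal(os$fraction_plus_end_out, 0.7)
  expect_equal(sum(os$fractions), 1)
  os_all <- orientation_summary(rep("plus_end_out", 5))
  expect_equal(os_all$fraction_plus_end_out, 1)
})
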