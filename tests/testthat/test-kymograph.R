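test_that("kymograph sampling: uniform movies, point sources, scaling", {
  cfg <- sim_config(seed = 1, noise_gaussian_sd = 0, poisson_scaling = 0,
                    jitter_max_px = 0, bleach_rate_per_min = 0)
  path <- sim_neurite_paths(cfg)[[1]]
  arr <- array(3.5, c(160, 160, 4))
  mv <- movie_stack(list(a = arr), cfg$pixel_size, 30)
  kym <- sample_kymograph(mv, path, width_px = 11)
  expect_true(all(kym$data == 3.5))
  expect_equal(dim(kym$data), c(4L, nrow(path)))

  # single bright pixel on the path lights up exactly its (frame, position)
  arr2 <- array(0, c(160, 160, 4))
  i <- 40
  arr2[round(path$y_px[i]) + 1, round(path$x_px[i]) + 1, 3] <- 9
  kym2 <- sample_kymograph(movie_stack(list(a = arr2), cfg$pixel_size, 30),
                           path, width_px = 11)
  pk <- which(kym2$data == max(kym2$data), arr.ind = TRUE)
  expect_equal(unname(pk[1, 1]), 3L)
  expect_lt(abs(pk[1, 2] - i), 3)

  # intensity-monotone: scaling the movie scales the kymograph
  kym3 <- sample_kymograph(movie_stack(list(a = arr2 * 2.5),
                                       cfg$pixel_size, 30), path, 11)
  expect_equal(kym3$data, kym2$data * 2.5)
})

test_that("a drifting patch appears as a ridge with the true slope", {
  cfg <- sim_config(seed = 3, noise_gaussian_sd = 0, poisson_scaling = 0,
                    jitter_max_px = 0, bleach_rate_per_min = 0)
  sim <- simulate_patch_movie(cfg)
  kym <- sample_kymograph(sim$movie, sim$ground_truth$paths[[1]],
                          width_px = 11, channel = "converted")
  ridge <- apply(kym$data, 1, which.max)
  t_min <- (seq_len(nrow(kym$data)) - 1) * cfg$frame_interval / 60
  slope <- unname(coef(lm(ridge * cfg$pixel_size ~ t_min))[2])
  expect_equal(slope, -0.53, tolerance = 0.05)
})

test_that("neurite length series implements the stop-at-gap walk", {
  ps <- 0.22
  # gap open to the tip-side border truncates the row at the gap
  m <- rbind(c(5, 5, 5, 5, 5), c(5, 5, 5, 0, 0), c(5, 5, 5, 5, 5))
  kym <- new_kymograph(m, ps, 30)
  lens <- neurite_length_series(kym, threshold = 1, smooth_mode = "none")
  expect_equal(lens[2], 2 * ps)
  # fully thresholded rows span (ncol - 1) pixels
  expect_equal(lens[1], 4 * ps)

  # an enclosed one-pixel dropout is treated as a hole and filled
  m2 <- rbind(rep(5, 6), c(5, 5, 5, 0, 5, 5), rep(5, 6))
  lens2 <- neurite_length_series(new_kymograph(m2, ps, 30), threshold = 1,
                                 smooth_mode = "none")
  expect_equal(lens2[2], 5 * ps)

  # all-background row gives length zero
  m3 <- rbind(rep(5, 5), rep(0, 5), rep(5, 5))
  lens3 <- neurite_length_series(new_kymograph(m3, ps, 30), threshold = 1,
                                 smooth_mode = "none")
  expect_equal(lens3[2], 0)

  # scaling invariance when the threshold scales along
  set.seed(4)
  m4 <- matrix(runif(200, 0, 10), 10, 20)
  k4 <- new_kymograph(m4, ps, 30)
  k4s <- new_kymograph(m4 * 3, ps, 30)
  expect_equal(neurite_length_series(k4, threshold = 5),
               neurite_length_series(k4s, threshold = 15))
  # lengths bounded by the kymograph width
  expect_true(all(neurite_length_series(k4, threshold = 5) <= 19 * ps))
})

test_that("a simulated retraction shortens the length series accordingly", {
  ps <- 0.22
  nt <- 30; nc <- 80
  m <- matrix(0, nt, nc)
  len_px <- round(seq(70, 70 - 5 / ps, length.out = nt))
  for (t in seq_len(nt)) m[t, 1:len_px[t]] <- 8
  lens <- neurite_length_series(new_kymograph(m, ps, 30), threshold = 4,
                                smooth_mode = "none")
  # first and last rows are forced into the thresholded set, so compare the
  # interior of the series
  expect_equal(lens[2] - lens[nt - 1], 5, tolerance = 2.5 * ps)
})

test_that("proximal and distal densities normalize and handle short neurites", {
  ps <- 0.5; nt <- 60
  m <- matrix(10, nt, 60)                      # 30-um uniform neurite
  kym <- new_kymograph(m, ps, 30)
  lens <- rep(29.5, nt)
  pd <- proximal_distal_density(kym, lens, threshold = 1)
  expect_true(all(abs(pd$proximal - 1) < 1e-9))
  expect_true(all(abs(pd$distal - 1) < 1e-9))

  # distal zone doubles after the 22.5-min normalization window
  m2 <- m
  late <- (seq_len(nt) - 1) * 60 / 60 >= 22.5   # 60-s frames
  m2[late, 40:50] <- 20                         # 19.5..24.5 um: inside distal
  pd2 <- proximal_distal_density(new_kymograph(m2, ps, 60), lens,
                                 threshold = 1)
  expect_equal(mean(pd2$distal[late] / pd2$proximal[late]), 2,
               tolerance = 0.05)

  # 8-um neurite: distal undefined, proximal present
  pd3 <- proximal_distal_density(kym, rep(8, nt), threshold = 1)
  expect_true(all(is.na(pd3$distal)))
  expect_false(any(is.na(pd3$proximal)))
})

test_that("soma fraction spans [0, 1] and crosses 0.25 at relocalization", {
  h <- 40; w <- 40; nt <- 20; k <- 11
  soma <- matrix(FALSE, h, w); soma[15:25, 15:25] <- TRUE
  cell <- matrix(FALSE, h, w); cell[5:35, 5:35] <- TRUE
  arr <- array(0, c(h, w, nt))
  for (t in seq_len(nt)) {
    fr <- matrix(0, h, w)
    w_soma <- min(1, max(0, (t - k + 3) / 6))   # ramps through 0.25 near k
    fr[soma] <- 100 * w_soma
    fr[cell & !soma] <- 100 * (1 - w_soma) * sum(soma) / sum(cell & !soma)
    arr[, , t] <- fr
  }
  mv <- movie_stack(list(a = arr), 0.22, 60)
  fr_series <- soma_fraction(mv, soma, cell, threshold = 1e-6, background = 0)
  expect_true(all(fr_series >= 0 & fr_series <= 1, na.rm = TRUE))
  cross <- which(fr_series >= 0.25)[1]
  expect_lte(abs(cross - k), 1)

  # all fluorescence in the soma -> 1; half/half -> 0.5
  arr1 <- array(0, c(h, w, 1)); arr1[15:25, 15:25, 1] <- 50
  expect_equal(soma_fraction(movie_stack(list(a = arr1), 0.22, 60),
                             soma, cell, threshold = 1, background = 0), 1)
  arr2 <- arr1
  n_out <- sum(cell & !soma)
  arr2[, , 1][cell & !soma] <- sum(arr1) / n_out
  expect_equal(soma_fraction(movie_stack(list(a = arr2), 0.22, 60),
                             soma, cell, threshold = 1e-6, background = 0),
               0.5, tolerance = 1e-6)
})
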