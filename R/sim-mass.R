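#' Simulate a photoconversion mass-partition kymograph
#'
#' Builds a kymograph (rows = time, columns = arc position, soma at column 0)
#' whose background-subtracted converted-tubulin mass is split between three
#' zones around a declared start column: retrograde (more than 1.1 um toward
#' the soma), stationary (within +/- 1.1 um) and anterograde (more than
#' 1.1 um tip-ward), in the requested proportions. The stationary mass sits
#' at the start point; the retrograde and anterograde components drift away
#' from it over time, staying inside their zones. Rows after
#' `n_analyzed_rows` decay below the row-stop criterion (signal <
#' `stop_factor` x background) so the analysis stop rule is exercised.
#'
#' @param config a [sim_config()] object (`n_frames`, `pixel_size`,
#'   `neurite_length_um`, `background`, `frame_interval` are used).
#' @param fractions numeric `c(retro, stationary, antero)`, summing to 1.
#' @param row_mass total signal mass per analyzed row (intensity units).
#' @param noise_sd additive Gaussian noise SD on the kymograph.
#' @param tail_rows number of trailing low-signal rows.
#' @param stop_factor the row-stop multiple of background the tail rows
#'   must stay under (1.8 without LatB, 1.3 with).
#' @return list with `kymograph` (a `Kymograph`) and `ground_truth`
#'   (requested and realized noiseless zone fractions, start column,
#'   background, number of analyzable rows).
#' @export
simulate_mass_kymograph <- function(config, fractions, row_mass = 3000,
                                    noise_sd = 1, tail_rows = 3L,
                                    stop_factor = 1.8) {
  validate_sim_config(config)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be c(retro, stationary, antero) summing to 1")
  set.seed(config$seed)
  ps <- config$pixel_size
  nc <- max(40L, round(config$neurite_length_um[1] / ps))
  nr <- config$n_frames
  n_analyzed <- max(1L, nr - tail_rows)
  bg <- config$background
  zpx <- round(1.1 / ps)          # stationary half-window in columns
  sc <- round(0.7 * nc)           # start column (1-based)
  sig_stat <- 1.1
  sig_move <- 2
  # drift such that the moving blobs stay inside their zones and the frame
  retro_c0 <- sc - zpx - 4 * ceiling(sig_move) - 1
  retro_v <- -min(1.5, (retro_c0 - 4 * sig_move - 2) / max(1, n_analyzed - 1))
  antero_c0 <- sc + zpx + 4 * ceiling(sig_move) + 1
  antero_v <- min(0.8, (nc - antero_c0 - 4 * sig_move - 2) /
                    max(1, n_analyzed - 1))
  gauss_row <- function(center, sigma, mass) {
    x <- seq_len(nc)
    prof <- exp(-(x - center)^2 / (2 * sigma^2))
    prof * mass / sum(prof)
  }
  clean <- matrix(bg, nr, nc)
  for (r in seq_len(nr)) {
    if (r <= n_analyzed) {
      row <- gauss_row(sc, sig_stat, fractions[2] * row_mass) +
        gauss_row(retro_c0 + retro_v * (r - 1L), sig_move,
                  fractions[1] * row_mass) +
        gauss_row(antero_c0 + antero_v * (r - 1L), sig_move,
                  fractions[3] * row_mass)
    } else {
      # residual signal well below the stop criterion
      row <- gauss_row(sc, sig_stat, 0.05 * bg)
    }
    clean[r, ] <- clean[r, ] + row
  }
  data <- clean
  if (noise_sd > 0) data <- data + matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                          nr, nc)
  kym <- new_kymograph(data, pixel_size = ps,
                       frame_interval = config$frame_interval,
                       width_px = 1L, path_id = 1L)
  # realized noiseless zone fractions (discrete sums)
  sig <- clean[seq_len(n_analyzed), , drop = FALSE] - bg
  cols <- seq_len(nc)
  zr <- cols < sc - zpx
  zs <- abs(cols - sc) <= zpx
  za <- cols > sc + zpx
  zone_sum <- c(sum(sig[, zr]), sum(sig[, zs]), sum(sig[, za]))
  list(
    kymograph = kym,
    ground_truth = new_ground_truth(
      fractions = fractions,
      realized_fractions = zone_sum / sum(sig),
      start_col = sc,
      background = bg,
      n_analyzed_rows = n_analyzed,
      stop_factor = stop_factor
    )
  )
}
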