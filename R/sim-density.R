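#' Simulate normalized microtubule density traces
#'
#' Per-neurite dimensionless density oscillating around 1.0 as a triangle
#' (default) or sine wave of the given swing amplitude and period, with
#' additive Gaussian noise. Each neurite gets an independent uniform-random
#' phase: density cycles of different neurites are not phase-locked in real
#' neurons. The ground-truth cycle frequency is `1 / period_h`.
#'
#' @param config a [sim_config()] object; `n_frames` and `frame_interval`
#'   set the trace grid, `n_neurites` the neurites per cell.
#' @param period_h oscillation period in hours.
#' @param amplitude swing amplitude (peak deviation from 1.0); 0 gives a
#'   flat trace.
#' @param n_cells number of cells.
#' @param noise_sd SD of additive noise on the density values.
#' @param waveform `"triangle"` or `"sine"`.
#' @return list with `traces` (data frame `cell_id, neurite_id, frame,
#'   time_h, density`) and `ground_truth` (true `cycles_per_hour`, per-trace
#'   phases, amplitude, period, and total cycles over the trace).
#' @export
simulate_density_traces <- function(config, period_h, amplitude,
                                    n_cells = 1L, noise_sd = 0.03,
                                    waveform = c("triangle", "sine")) {
  validate_sim_config(config)
  waveform <- match.arg(waveform)
  stopifnot(period_h > 0, amplitude >= 0, noise_sd >= 0, n_cells >= 1L)
  set.seed(config$seed)
  nt <- config$n_frames
  time_h <- (seq_len(nt) - 1L) * config$frame_interval / 3600
  duration_h <- time_h[nt]
  out <- list(); phases <- numeric(0)
  for (ci in seq_len(n_cells)) {
    for (ni in seq_len(config$n_neurites)) {
      phi <- stats::runif(1)
      phases <- c(phases, phi)
      u <- (time_h / period_h + phi) %% 1
      wave <- if (waveform == "triangle") {
        # triangle in [-1, 1]: rises over the first half-period
        4 * abs(u - 0.5) - 1
      } else {
        sin(2 * pi * u)
      }
      dens <- 1 + amplitude * wave
      if (noise_sd > 0) dens <- dens + stats::rnorm(nt, 0, noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = ci, neurite_id = ni, frame = seq_len(nt),
        time_h = time_h, density = dens)
    }
  }
  list(
    traces = do.call(rbind, out),
    ground_truth = new_ground_truth(
      cycles_per_hour = 1 / period_h,
      period_h = period_h,
      amplitude = amplitude,
      duration_h = duration_h,
      total_cycles = duration_h / period_h,
      phases = phases
    )
  )
}
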