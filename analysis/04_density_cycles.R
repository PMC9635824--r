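#!/usr/bin/env Rscript
# Microtubule density-cycle counting: recover the control cycle frequency
# (0.56 cycles/hour) from triangle-wave density traces, and the population
# correlation between MT-RF and cycle frequency (r = 0.46) from bivariate
# cohorts.

suppressMessages(library(mtflow))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 77, n_frames = 201, frame_interval = 180,
                  n_neurites = 4)
dens <- simulate_density_traces(cfg, period_h = 1 / 0.56, amplitude = 0.25,
                                noise_sd = 0.03, n_cells = 27)
pc <- cycle_frequency_per_cell(dens$traces, dt_hours = 0.05)
write.csv(pc, "results/cycle_frequency_per_cell.csv", row.names = FALSE)
cat(sprintf("mean cycle frequency: %.3f cycles/h (truth 0.56)\n",
            mean(pc$mean_cycles_per_hour)))

set.seed(78)
rho <- 0.46
rs <- vapply(1:200, function(k) {
  x <- rnorm(95)
  correlate_flow_cycles(x, rho * x + sqrt(1 - rho^2) * rnorm(95))$r
}, 0)
cat(sprintf("mean Pearson r over 200 cohorts of 95: %.3f (truth 0.46)\n",
            mean(rs)))
write.csv(data.frame(cohort = seq_along(rs), r = rs),
          "results/flow_cycle_correlation.csv", row.names = FALSE)
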