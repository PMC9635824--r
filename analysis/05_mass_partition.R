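#!/usr/bin/env Rscript
# Pulse-chase mass partitioning: rebuild kymographs at the dynein-
# recruitment partition (84% retrograde / 6% stationary / 10% anterograde)
# and recover the zone fractions with background subtraction and the
# 1.8x row-stop rule.

suppressMessages(library(mtflow))
dir.create("results", showWarnings = FALSE)

fr <- t(vapply(1:20, function(i) {
  mk <- simulate_mass_kymograph(sim_config(seed = 500 + i, n_frames = 18),
                                c(0.84, 0.06, 0.10))
  mass_distribution(mk$kymograph,
                    start = mk$ground_truth$start_col)$fractions
}, c(retro = 0, stationary = 0, antero = 0)))
out <- data.frame(zone = colnames(fr),
                  true_fraction = c(0.84, 0.06, 0.10),
                  recovered_mean = colMeans(fr),
                  recovered_sd = apply(fr, 2, sd))
write.csv(out, "results/mass_partition.csv", row.names = FALSE)
print(out, row.names = FALSE)
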