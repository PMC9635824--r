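# mtflow

Quantification of **microtubule retrograde flow (MT-RF)** in time-lapse
fluorescence movies of developing neurons.

In cultured hippocampal neurons, the microtubule array inside a neurite is
not stationary: photoconverted tubulin patches drift toward the soma at a
few tenths of a micrometre per minute. This bulk retrograde flow removes
microtubule mass from neurites, fuels cycles of microtubule density, and
slows down specifically in the axon shortly after polarization. Measuring
it requires a chain of quantitative image analyses, each individually
simple but easy to get subtly wrong: registration of very low-intensity
movies, automated neurite tracing, kymograph quantification, patch and
punctum tracking, density-cycle counting and comet-orientation calling.
`mtflow` implements that chain as a tested R package for anyone analysing
pulse-chase (photoconversion/photoactivation), CAMSAP3 or EB3 movies of
neurites — together with a synthetic-microscopy generator with exact
ground truth, so every stage can be validated end to end without any raw
imaging data.

## What is implemented

| Stage | Functions |
|---|---|
| Synthetic microscopy with ground truth | `sim_config()`, `simulate_patch_movie()`, `simulate_camsap_movie()`, `simulate_comet_tracks()`, `simulate_density_traces()`, `simulate_mass_kymograph()` |
| Translation registration of low-SNR movies | `cap_intensities()`, `find_shift()`, `register_movie()` |
| Automated neurite tracing | `extract_soma()`, `find_neuron_threshold()`, `close_gaps()`, `build_branches()`, `trace_frame()` |
| Kymographs and readouts | `sample_kymograph()`, `neurite_length_series()`, `proximal_distal_density()`, `soma_fraction()` |
| Flow quantification | `track_patch()`, `speed_from_track()`, `patch_synchrony()`, `extract_camsap_traces()`, `camsap_flow_series()`, `detect_slowdown()`, `classify_axon()`, `neurite_background()`, `patch_spread()`, `mass_distribution()` |
| Density cycles | `expression_fit()`, `normalize_density()`, `smooth_trace()`, `count_cycles()`, `cycle_frequency_per_cell()`, `correlate_flow_cycles()` |
| Comet orientation | `tracks_to_neuron_image()`, `comet_skeleton_context()`, `classify_comet()`, `orientation_summary()` |
| Orchestration and statistics | `run_pipeline()`, `group_compare()`, `dunn_test()` |

Key quantitative conventions: kymographs are oriented soma-left (rows =
time, columns = arc length, one pixel per column), retrograde speeds are
reported positive, pixel coordinates are 0-based `(row, column)`.

The flow statistic itself is elementary — a patch traced over time gives
`speed = |net arc-length displacement| / duration` — but the value of the
package is everything that makes that number trustworthy at 0.2–1 um/min
on noisy movies: the intensity-capped correlation hill-climb that
registers frames to the pixel, the corridor max-projection and
background-subtracted centroid that tracks the patch, and the swing
detector (hysteresis `delta = 0.2` on expression-normalized density) that
turns density traces into cycle counts.

## Worked example

Simulate a 10-min photoconversion movie (0.22 um/px, 30-s frames, SNR ~5,
stage jitter up to ±3 px/frame) with a patch drifting retrogradely at
0.53 um/min, then recover the speed through the full pipeline:

```r
library(mtflow)

cfg <- sim_config(seed = 7, patch_speed_um_min = -0.53)
sim <- simulate_patch_movie(cfg)
reg <- register_movie(sim$movie, register_channel = "tubulin")
max(abs(cbind(reg$shifts$dy_px, reg$shifts$dx_px) +
        sim$ground_truth$jitter_px))
#> [1] 1            # residual registration error, pixels

track <- track_patch(reg$movie, sim$ground_truth$paths[[1]])
fm <- speed_from_track(track)
fm$speed_um_min; fm$direction
#> [1] 0.5148865
#> [1] "retrograde"
```

The recovered 0.51 um/min is the true 0.53 um/min drift re-measured
through registration, corridor tracking and the net-displacement speed
rule; across 30 seeded movies the mean recovery is within a few percent
of the truth (see `analysis/03_flow_recovery.R`).

The numbered scripts under `analysis/` run the same analyses as short
narrative drivers and write their tables under `results/`:
`01_simulate.R` (reference movie), `02_register.R` (shift recovery),
`03_flow_recovery.R` (three flow regimes), `04_density_cycles.R`
(cycle-frequency and correlation recovery), `05_mass_partition.R`
(pulse-chase mass zones), `06_orientation.R` (comet orientation calls).

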