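# emgrid

Designing electrode grids for high-density surface electromyography
(HD-EMG): how many motor units can a montage of a given size, electrode
count and interelectrode distance (IED) actually resolve?

`emgrid` is an R toolkit for answering that question computationally,
aimed at neurophysiologists and biomedical engineers who design EMG
montages or validate decomposition pipelines. It provides:

* **Anatomy** — a 200-unit motor pool in a layered cylindrical muscle
  (25.4-mm muscle radius, 5-mm fat, 1-mm skin), territory centers by
  farthest-point sampling, innervation numbers on the exponential law
  `n_i = 15·100^((i−1)/(N−1))` (15–1500 fibers), 20 fibers/mm²
  territories.
* **Volume conductor** — analytic line-source MUAP forward model:
  Rosenfalck intracellular potential `ψ(z) = 96 z³ e^(−z) − 90` mV,
  two depolarization zones with end-plate and end-of-fiber effects,
  anisotropy-scaled inverse-power distance weighting.
* **Montages** — the composite 26×10 / 4-mm grid (256 electrodes,
  10 × 3.6 cm) and its decimations (64/35/20), centered crops
  (63/34/19), quadrant splits, the ultradense 2-mm grid, arbitrary
  simulated grids, and per-sample spatial interpolation.
* **Theoretical identifiability** — pairwise aligned normalized
  mean-square difference (NMSD) between multichannel MUAPs with a 5%
  criterion: a unit is identifiable when it differs from *every* other
  unit, an algorithm-independent upper bound on decomposition yield;
  swept over (grid size × IED) configurations.
* **Synthetic EMG** — recruitment thresholds
  `Fth(j) = 0.50(58.12 j + 120 j^1.83)` %MVC, trapezoidal force ramps at
  5 %/s, rate coding capped below 50 discharges/s, band-limited noise at
  a chosen SNR, with exact ground-truth spike trains.
* **Decomposition** — convolutive blind source separation: extension to
  1000 channels, regularized whitening, log-cosh fixed-point extraction
  with deflation and peel-off, CoV-ISI refinement, 28-dB pulse-to-noise
  (PNR) gating, duplicate removal (30% shared discharges within
  0.5 ms), whole-grid or per-quadrant.
* **Metrics** — early/late recruitment classification, spike-triggered
  averaging, adjacent-electrode correlation, normalized unit counts and
  weighted natural-log trend fits, rate of agreement against ground
  truth.

## Worked example

Simulate a pool, score a dense and a sparse montage, then decompose a
synthetic recording against its own ground truth:

```r
library(emgrid)

pool <- build_pool(count = 200, seed = 1)
sw <- sweep_configs(pool,
                    data.frame(length_cm = 10, ied_mm = c(2, 16)),
                    fiber_subsample = 100, seed = 1)
sw[, c("ied_mm", "area_cm2", "n_electrodes", "pct_identifiable",
       "mean_depth_mm")]
#>   ied_mm area_cm2 n_electrodes pct_identifiable mean_depth_mm
#> 1      2    36.00          969               82      13.90043
#> 2     16    30.72           21               85      13.77635
```

82% of the 200 simulated units have a multichannel action potential
that differs by at least 5% NMSD from every other unit on the 36-cm²,
2-mm-IED grid — the theoretical ceiling for any decomposition on that
montage; `mean_depth_mm` is the average depth of those identifiable
units below the skin.

```r
small <- build_pool(count = 15, seed = 11)
grid  <- grid_spec(13, 5, ied = 4, missing = rbind(c(0, 0)))  # 64 ch
muaps <- compute_muaps(small, grid, fiber_subsample = 100, seed = 11)
trains <- simulate_discharges(trapezoid_profile(50, 15), 15, seed = 11)
emg <- render_emg(muaps, trains, snr_db = 20, seed = 11)

res <- decompose(emg, config = decomp_config(seed = 5))
res
match_ground_truth(res, trains, max_lag_s = 0.03)
```

Every accepted train carries its PNR (dB) and CoV of interspike
intervals; `match_ground_truth()` reports the rate of agreement (RoA,
matched discharges over matched plus unmatched) against the generator's
spike trains.

A command-line wrapper covering the same stages
(`simulate-pool`, `simulate-emg`, `sweep`, `decompose`, `analyze`,
`report`) is installed at
`system.file("cli", "emgrid.R", package = "emgrid")`; every run writes a
`manifest.json` with its seed, configuration echo and input hashes.

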