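---
title: "Simulating and decomposing high-density surface EMG for electrode grid design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decomposing high-density surface EMG for electrode grid design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgrid)
```

## The question the package addresses

Grids of surface electromyography (EMG) electrodes, combined with blind
source separation, let physiologists identify the discharge times of
individual spinal motor neurons non-invasively. How many motor units such
a recording can resolve depends on the montage: its area, its number of
electrodes and its interelectrode distance (IED). `emgrid` provides the
computational side of that design question end to end: an anatomical
motor-unit pool in a layered cylindrical muscle, a volume-conductor
forward model producing each unit's multichannel action potential
(MUAP), an algorithm-independent *theoretical identifiability* statistic
swept over grid designs, a synthetic-EMG generator with ground-truth
spike trains, a convolutive blind-source-separation (CBSS) decomposition,
and the post-hoc metrics used to characterize identified units.

## Anatomical model

The muscle is a cylinder of radius 25.4 mm with parallel fibers,
separated from the recording surface by 5 mm of subcutaneous fat and
1 mm of skin. A pool of 200 motor units is placed in the cross-section
by farthest-point sampling over a seeded uniform candidate set (50
candidates per unit; the first center drawn uniformly), which yields a
random but even filling of the disc. Innervation numbers follow the
rank-based exponential law `n_i = 15 * 100^((i-1)/(count-1))`, spanning
15 to 1500 fibers exactly. Territory radii derive from the fixed fiber
density of 20 fibers/mm^2 (`r = sqrt(n / 20 pi)`), clipped to the
0.2-9.8 mm band; territories near the boundary may overhang it, in which
case fibers are resampled into the intersection with the muscle disc, so
the local density in the territory rises slightly rather than the center
shifting.

Two axial choices deserve explanation. Fibers default to 60 mm — the
fascicle-length scale of a dorsiflexor such as the tibialis anterior —
and each unit's fascicle bundle is centered at a unit-specific axial
position drawn uniformly within ±20 mm, emulating innervation zones and
fascicle spans staggered along the muscle. With full-length (100 mm)
fibers spanning the whole montage instead, every unit's surface energy
becomes nearly uniform along the muscle axis (we measured 2.6-4.7% of a
unit's energy per 4-mm electrode row, essentially flat), the axial
dimension carries no information about which unit is which, and grid
length ceases to matter — contrary to both the physiology and the
design question being asked. End-plates sit at the fascicle midpoint
with ±5 mm of per-fiber scatter.

## Volume conductor

The published conductor models this package emulates are cited rather
than printed in the experimental literature, so `emgrid` uses an
analytic line-source model with all parameters exposed in
`tissue_electrical()`:

* The intracellular action potential is the Rosenfalck form
  `psi(z) = 96 z^3 e^(-z) - 90` mV; its second spatial derivative is the
  transmembrane current source density.
* Two depolarization zones leave the end-plate toward both fiber ends at
  the unit's conduction velocity (3.5-4.5 m/s, increasing
  logarithmically with innervation number). Truncating the line sum at
  the end-plate and the fiber ends produces the non-propagating
  generation and end-of-fiber components without special-casing.
* The contribution of a source element to an electrode is weighted by an
  inverse power of the anisotropy-scaled distance,
  `(dx^2 / K + r_eff^2)^(-p/2)`, with longitudinal/transverse
  conductivity ratio `K = 5`. The default power `p = 4` reflects that a
  fiber's transmembrane current is a balanced (quadrupole-like) source
  whose return currents are confined near the source by the
  low-conductivity fat and skin, so the surface potential falls off far
  faster than a monopole field; a monopole weighting (`p = 1`) makes the
  collective far field of the whole pool dominate every channel and is
  qualitatively wrong for surface EMG. The fat and skin layers
  additionally contribute `0.5 x thickness` of effective radial distance
  each, standing in for their blurring of the surface potential.
* Electrodes (1-mm discs in the emulated hardware) are treated as
  points, since the diameter is small against every IED used; a 5-point
  disc stencil is available behind the `stencil` flag for sensitivity
  checks.

Amplitude units are arbitrary (the identifiability statistic is
scale-free and the EMG generator sets noise relative to signal power).
The axial discretization step is 1 mm; halving it changes identifiable
fractions by well under one unit of percent.

## Theoretical identifiability

Two units are *discriminable* when their multichannel MUAPs, after
alignment by a single global lag (chosen by the magnitude of the summed
cross-correlation across channels; per-channel alignment would erase the
inter-electrode delay information that distinguishes units), differ by a
normalized mean-square difference (NMSD) of at least 5%. The
normalization is the mean of the two waveform energies — symmetric, and
scale-balanced in the sense that a pure amplitude ratio `rho` gives
`2(1-rho)^2/(1+rho^2)` regardless of which unit is larger; a
max-energy mode is available in `discriminability_config()`. A unit is
*theoretically identifiable* when it is discriminable from every other
unit of the pool: an upper bound on what any decomposition algorithm can
separate, independent of the algorithm. A single-unit pool is
identifiable by convention (the universal quantifier is vacuous).

`sweep_configs()` evaluates a pool over a ladder of grid designs
(default 7 lengths x 12 IEDs = 84 configurations of a 3.6-cm-wide
grid). MUAPs are computed once on the union of all electrode positions
and sliced per configuration, and an exact per-channel Cauchy-Schwarz
bound prunes pairs that cannot fall below the 5% threshold, which keeps
the 200-unit pairwise computation to seconds per configuration. Fiber
subsampling (at most 100 fibers per unit, rescaled) changes
identifiability decisions for well under 5% of units while cutting the
forward-model cost several-fold; the shipped analyses use it.

What this statistic does and does not reproduce deserves honesty. With
the default conductor, the identifiable fraction at the largest, densest
grid (36 cm^2, 2-mm IED) sits in the mid-80s percent range, and grid
*size* shows the expected monotone benefit. The strong *density* effect
reported for physical recordings — a large drop in identifiable units at
very coarse IEDs — does not emerge from this (or any smooth analytic)
kernel: the channel-summed NMSD is dominated by near-peak electrodes
whose pairwise contrast is low, so fine structure that only dense
sampling resolves is exactly what a smooth line-source model lacks.
Conclusions about IED from this package should therefore lean on the
decomposition pipeline (where density demonstrably matters through
conditioning of the unmixing problem), not on the theoretical statistic
alone.

## Synthetic EMG with ground truth

Recruitment follows the threshold law
`Fth(j) = 0.50 (58.12 j + 120 j^1.83)` % MVC for normalized pool rank
`j in [0, 1]` — zero at the first unit and 89.06% MVC at the last — a
typical frequency distribution of recruitment thresholds for the
tibialis anterior. (The printed form of the second term is typographic;
`120 * j^1.83` is implemented, giving the plausible 89.06% ceiling.)
Force profiles are trapezoids at 5%/s with plateaus at 30% or 50% MVC
(32 s and 35 s total). A unit fires while force is at or above its
threshold, at `min(8 + 0.3 (F - Fth), 35)` discharges/s with Gaussian
interspike-interval jitter of CoV 0.15 — values chosen as typical
tibialis anterior behavior under the hard physiological ceiling of 50
discharges/s; all are arguments of `simulate_discharges()`. EMG channels
are the spike trains convolved with the MUAPs plus 20-500 Hz band-limited
Gaussian noise at a configurable total SNR (default 20 dB). The
generator stores the exact discharge times, the recruitment thresholds
and the early/late ground-truth labels, so every downstream claim is
checkable. What it does not emulate: force production and twitch
dynamics, fatigue, common synaptic drive (discharge trains are
independent across units), electrode-skin artifacts, and movement — so
green tests here demonstrate algorithmic correctness, not robustness to
every nuisance of physical recordings.

## Decomposition

The CBSS pipeline follows the standard convolutive sparse-component
scheme: zero-phase 20-500 Hz second-order Butterworth filtering;
automated channel rejection (RMS beyond 3 robust z-scores from the
montage median — an automated stand-in for an operator's visual
inspection); extension by delayed copies to reach 1000 extended channels
(`R = ceiling(1000/m)`); whitening by eigen-decomposition with
small-eigenvalue regularization (directions below the mean of the
smallest half of the spectrum are noise-dominated and discarded — with
them retained, the fixed point chases noise and extraction fails);
then repeated fixed-point extraction with the log-cosh contrast
(`g' = tanh`), each run initialized at the highest unused activity
sample, deflation-orthogonalized against previous separation vectors,
and stopped when the sparsity measure (mean log-cosh of the source)
changes by less than 1e-4. The pulse train is the signed-squared
projection `s|s|` — squaring skews small values toward zero and sharpens
discharge peaks — on which peaks (minimum distance 10 ms) are classified
by 2-class K-means on amplitude, the high class being the discharges.
The pulse-to-noise ratio (PNR) and the 28-dB acceptance gate are defined
on this squared series, matching the convention of the reference
implementations of this algorithm family.

Each candidate is refined by iteratively recomputing the unit filter as
the mean whitened observation at the current discharge instants and
re-detecting discharges, keeping the iterate with the lowest CoV of the
interspike intervals (at most 20 iterations, stopping when the CoV fails
to decrease). A final polish repeats the filter update while the PNR
keeps improving — recalculating the unit filter from corrected
discharge times reliably sharpens the pulse train, which is also why
operator editing helps in physical-recording workflows. Accepted units must also be physiologically plausible:
at least 10 discharges over at least 2 s, mean rate below 50/s, and
CoV-ISI at most 0.5 — the automated replacement for the manual editing
step that physical-recording workflows rely on. A found unit's mean
delayed embedding is then subtracted from the whitened data
("peel-off"), without which later runs re-extract lagged copies of the
strongest unit instead of descending the pool. Duplicates — trains
sharing at least 30% of discharges within 0.5 ms after alignment (lag
search ±30 ms, since extension plus propagation offsets two estimates of
one unit by tens of milliseconds) — are resolved in favor of the lowest
CoV-ISI. In quadrant mode the montage's four sub-grids are decomposed
independently and duplicates are removed across them.

## Post-decomposition metrics

* `classify_early_late()`: the active pool at target `T` is the rank
  interval `[0, invert_fth(T)]`; units with measured threshold at or
  below `fth(invert_fth(T)/2)` (≈11.5% MVC for a 30% target) are "early
  recruited". The measured threshold estimator is the force at a unit's
  first discharge on the up-ramp.
* `percent_early()` averages per-subject percentages and suppresses a
  condition when five or fewer units occurred for three or more
  subjects.
* `sta_muap()`: spike-triggered averaging over 50-ms windows, dropping
  partial edge segments.
* `adjacent_correlation()`: Pearson correlation between the
  highest-amplitude electrode's MUAP and its lattice neighbors at a
  chosen distance — the redundancy measure that decreases with IED.
* `fit_log_trend()`: weighted least squares of `y = a + b ln(x)`.
  Natural logarithms are the convention: coefficients of the style
  `a = 195, b = -68` evaluate to ≈100 at the 4-mm anchor where counts
  are normalized, which base-10 coefficients would not.
* `rate_of_agreement()`: greedy one-to-one matching within 0.5 ms after
  a bounded alignment-lag search,
  `RoA = common / (common + only_found + only_truth)`.

## Problem sizes, seeds and degenerate inputs

The shipped analyses use 200-unit pools with 100-fiber subsampling for
identifiability sweeps, and 15-unit pools, 64 channels and ~30-s
contractions for decomposition validation; these sizes keep a full
5-seed sweep plus a decomposition run within tens of minutes on a single
core while leaving every qualitative behavior intact. All stochastic
stages take explicit integer seeds and are bit-reproducible given (seed,
configuration). Degenerate inputs resolve explicitly: zero-length MUAP
windows give empty waveforms; a zero baseline saturates the PNR to
`Inf`; trains with fewer than four discharges skip refinement with a
flag; ties in farthest-point sampling resolve to the lowest candidate
index; and K-means on spike amplitudes falls back to "all peaks" when
the amplitudes are constant.

## Known limitations

The conductor is an effective model: its distance-decay exponent and
layer attenuations are calibrated descriptors, not tissue measurements,
and the theoretical-identifiability statistic inherits that (see above
on the IED effect). Farthest-point center placement fills the
cross-section uniformly per unit area, which concentrates units at
mid-depths; depth statistics of identifiable units are accordingly a
millimeter or two shallower than montage studies that assume more
depth-uniform pools. Discharge trains are independent across units — no
common drive — which slightly flatters source-separation performance.
Decomposition of real recordings additionally faces artifacts,
impedance drift and montage motion that the generator deliberately does
not model.
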