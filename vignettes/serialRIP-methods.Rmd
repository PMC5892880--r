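---
title: "Methods: simulated serial radiation-damage-induced phasing"
author: "serialRIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated serial radiation-damage-induced phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

serialRIP simulates serial synchrotron dose-series diffraction
experiments on toy macromolecular crystals and re-implements, end to end,
the inference chain of radiation-damage-induced phasing (RIP): selection
and merging of partial sub-datasets, K-scanned isomorphous difference
amplitudes, dual-space determination of the damage-site substructure,
SIR-style phasing with solvent-mask density modification and signed-site
bootstrapping, and the evaluation battery (model-phased difference-map
peak heights, substructure correctness, weighted mean phase error) as
functions of dose, scale factor K and multiplicity. Everything operates
on synthetic data whose ground truth is retained for evaluation only; no
pipeline stage reads it.

# The forward model

## Toy crystals

A `ToyStructure` is a set of C/N/O/S point atoms with occupancies and
isotropic B factors, placed uniformly inside a compact spherical blob
whose volume matches the non-solvent fraction of the cell per asymmetric
unit, with a hard 1.2 Å minimum inter-atomic distance (including
symmetry mates). The blob matters: solvent-mask density modification is
meaningful only if the scattering matter is spatially compact. Two
space-group presets are provided: P2~1~2~1~2~1~ (default; hard-coded
operators, 8 discrete allowed origin shifts at the half-cell
translations, no polar axes) and P1 (identity only, fully polar origin)
for oracle tests. P2~1~2~1~2~1~ was chosen precisely because its allowed
origin shifts are discrete, which keeps substructure-correctness and
phase-alignment searches exhaustive rather than continuous.

Structure factors are computed by direct summation with tabulated
4-Gaussian scattering-factor coefficients for C, N, O and S only (the
damage chemistry of interest is on sulfur; metals are out of scope),
occupancies, and Debye–Waller factors `exp(-B s²/4)`, `s = 1/d`. There
is no anomalous component, so Friedel's law holds exactly and merging is
anomalous-free throughout.

## Damage

Specific damage: each damage-susceptible S site decays as
`occ(D) = occ₀ · 2^(−D/D_half)` with dose D in MGy. A fraction `r` of
the lost occupancy reappears at a partner site displaced by a fixed
distance (1.5 Å by default) along a per-site random direction chosen
once at generation time — these partner sites are the future negative
peaks of the difference maps. Global damage: an isotropic B inflation
(Å²/MGy) applied to every atom plus an overall linear intensity-scale
decay per MGy. The half-dose is exposed as a free parameter because the
exact damage kinetics is system-dependent; the presets pin it to the
regime the dose ladder probes (see below).

## Serial data

Each of `nCrystals` crystals is re-exposed `nExposures` times with a
cumulative dose ladder `k · dosePerExposure` (default 0.58 MGy per
exposure over six exposures, i.e. 0.58–3.48 MGy — the arithmetic ladder
of a serial dose-series experiment in the few-MGy regime where the RIP
signal is expected to be optimal). Wedge partiality is abstracted as a
random subset of the unique reflections (default 55% per sub-dataset);
the analyses downstream depend on completeness/multiplicity structure,
not on spot geometry, so no rotation geometry is modelled. An optional
orientation-bias term depletes reflections near the c* axis to emulate
preferred crystal orientations; it is off by default.

Per-crystal non-isomorphism: cell-length jitter (0.2% relative),
a log-normal overall scale (σ = 0.1), a B-factor offset (σ = 2 Å²), and
a fixed per-crystal, per-reflection log-normal intensity modulation
(σ = 3%) that persists across that crystal's exposures. Counting noise:
`I = scale · exp(−B s²/2) · |F|² + N(0, σI)` with
`σI = sqrt(quantum · I_true + σ₀²)`. The quantum is calibrated once per
experiment from the undamaged median intensity so that single-observation
`⟨I/σ⟩` lands near a target (15 for the UV-like preset, 12 for the
X-ray-like one); negative observed intensities are retained, as in real
integration output. All randomness flows from one master seed through
purpose-tagged derived streams.

## Presets

* `uv-rip` — 150 atoms, 6 S sites, `D_half = 2.63` MGy (60% occupancy
  loss at the 3.48 MGy final dose), no relocation, no global damage,
  `⟨I/σ⟩ ≈ 15`. The high-signal, isomorphism-preserving UV-illumination
  regime.
* `xray-rip` — 170 atoms, 9 S sites, `D_half = 4` MGy (≈45% loss at
  3.48 MGy), 50% relocation to 1.5 Å partner sites, 1 Å²/MGy global B
  inflation and 3%/MGy scale decay, `⟨I/σ⟩ ≈ 12`. The X-ray burn regime
  where global damage competes with the specific signal.

These generator defaults are the study conditions; the test suite and
the acceptance analyses run against them unchanged.

A third set of conditions backs the dose- and multiplicity-series
analyses. Peak heights are reported in map sigma units, and once the
difference signal dominates the map variance those normalized heights
saturate near a ceiling set by the number of sites and the grid — the
dose dependence disappears exactly when the data are very good. The
paper-style peak-vs-dose and peak-vs-multiplicity curves live in the
noise-limited regime, the one a shell difference-significance of about
2 indicates; the series pools are therefore calibrated to it (4 S
sites, half-dose 8 MGy, single-observation signal-to-noise ~6, doses
0.5-3.0 MGy), and the strong presets are kept for the K-scan and
phasing analyses where absolute signal is what matters.

# The inference chain

## Merging and GA selection

Sub-datasets are scaled to the "strongest" member (largest ΣI/σ; ties to
the lowest id) by a least-squares fit of `log(I_ref/I_sub) = log k +
B s²/2` on common positive observations, then merged by inverse-variance
weighted means. Statistics follow the standard definitions: R_merge with
unweighted group means, R_meas with the `sqrt(n/(n−1))` group factor,
CC~1/2~ from one fixed-seed random half-split (recorded; a single split
keeps the statistic deterministic), completeness against the full
theoretical ASU to the pool's resolution limit, shells equal-volume in
1/d³ (10 by default).

The genetic algorithm selects which sub-datasets to merge: genomes are
inclusion bitmasks; fitness is
`2·norm(⟨I/σ⟩) − norm(R_meas) + norm(CC1/2) + completeness`, i.e.
signal-to-noise is weighted twice as heavily as the other terms and
completeness is not weighted more than any of them. The min-max
normalization bounds are frozen from the initial population rather than
recomputed per generation: a fixed target function makes the elitism
guarantee (best target non-decreasing) exact and allows direct
comparison against an exhaustive subset enumeration in the tests.
Evolution is tournament selection (k = 2), single-point crossover
(p = 0.8), per-bit mutation (p = 0.05), two elites, 40×60
population×generations by default.

## Differences and the K scan

Amplitudes come from the truncation rule `F = sqrt(max(I, 0))` with
`σF = σI/2F` above the sigma floor (a French–Wilson treatment is
deliberately not implemented; the synthetic data control their own
signal-to-noise and the truncation bias is checked by a Monte-Carlo
test). The after set is conventionally scaled onto the before set
(log-linear k, B fit), and the deliberate down-weighting
`ΔF = F_before − K·F_after` is applied on top, on the canonical grid
K = 0.97 to 1.01 in steps of 0.00211. Propagated errors give the
shell significance statistic `⟨|ΔF|/σ(ΔF)⟩` (the d′/σ(d′) of the
difference data); the suggested high-resolution cutoff is where it drops
below 1.5 (configurable up to ≈2.5, which on hard cases is the better
choice). Normalized magnitudes E are |ΔF| scaled to unit rms per shell —
a stand-in for a full normalization pipeline, flagged as such.

## Dual-space substructure search

Per trial, seed sites are either random or placed as a random position
plus a top non-origin difference-Patterson vector (alternating trials).
Each recycling cycle computes point-atom phases (unit scatterers, one
overall B of 5 Å²) from the current sites, synthesizes an E-map from the
**strongest 30%** of the normalized differences, extracts candidate
peaks (rejecting special positions and <1.2 Å contacts), and then
**greedily re-selects** the `nFind` sites that maximize the correlation
between |E_obs| and |E_calc|, with one swap-improvement pass. Blind
top-of-list peak picking fails here: when the phasing model is a partial
substructure, the candidate list contains both hands of the solution and
mixing them destroys the correlation; CC-greedy selection keeps the
growing set internally consistent in hand and origin. Trials are scored
by CC(all) and CC(weak) (weakest 30% of |E_obs|) over the full
reflection set, and the best trial by CC(all)+CC(weak) wins. The search
is deterministic per seed; an optional stop score ends the trial loop
early once a clear solution appears (the accepted solution is still the
best seen). Defaults: 200 trials, 6 cycles, resolution window 500–2.2 Å;
the K-scan driver uses fewer trials with the early stop because it
repeats the search across the whole grid.

## SIR phasing, density modification, bootstrapping

Damaged sites play the heavy-atom role with `F_after ≈ F_before − F_H`;
F_H uses the sulfur form factor × signed occupancy with one overall B
and a single least-squares scale onto |ΔF| (occupancy refinement beyond
one scale is out of scope). The lack of closure
`ε(φ) = |F_a| − |F_b e^{iφ} − F_H|` is evaluated on a 5° grid with
`σ² = σ_b² + K²σ_a² + σ_niso²`, the non-isomorphism term fitted per
shell from the minimal lack of closure in a second pass. Acentric
output is the probability centroid with `m = |⟨e^{iφ}⟩_P|`; centric
reflections use their two allowed phases only.

Density modification departs from a textbook flatten-and-replace in two
ways, both forced by measured failure modes:

* the solvent mask comes from the **local density variance** (smoothed
  ρ² minus squared smoothed ρ, Gaussian B = 60 Å²), not from smoothed
  density. The lowest-resolution phases are the least constrained by RIP
  differences (the difference signal is a tiny fraction of the enormous
  low-angle blob scattering), and a smoothed-density envelope built on
  them proved near-random while the variance envelope recovers ≈85%
  mask agreement with ground truth;
* the solvent is **flipped** about its mean rather than flattened, and
  the resulting map phase is combined with the *input* SIR phase
  distribution, which anchors every cycle. Plain phase replacement
  drifts away from good starts (the flattened map is biased toward the
  substructure model), while anchored flipping is stable from true
  phases (<3° drift over five cycles) and improves SIR starts.

Figures of merit update with a map-consistency weight
`w = X/(1+X)`, `X = |G|/⟨|G|⟩_shell`, combined as
`m ← 1 − (1−m)(1−w)`.

Handedness: both the substructure and its inverted copy are phased and
the higher map contrast (variance of the smoothed map over the protein
envelope) wins, ties to the original. In P1 and P2~1~2~1~2~1~ every
operator translation satisfies `t ≡ −t (mod 1)`, so the inverted
substructure yields exactly conjugate structure factors and the two
hands produce mirror-image maps with *identical* contrast: without
anomalous scattering or chirality-aware model building (both out of
scope) the absolute hand is physically undeterminable, the tie-break
always fires, and all evaluation metrics therefore align over hand
explicitly.

Bootstrapping completes the signed substructure: difference Fourier maps
with current phases are searched for peaks above +6σ (new positive
sites) and below −6σ (new negative sites — the relocation partners),
deduplicated under symmetry, and the SIR step is repeated until the site
list stops changing.

## Evaluation

* Model-phased difference maps: `ΔF·e^{iφ_ref}` syntheses in σ units
  (rms about the mean; the alternative outlier-excluded rms convention
  is not used). Peaks are 26-neighbour local extrema with per-axis
  quadratic interpolation, deduplicated to one symmetry representative.
* Substructure correctness: percent of reference sites matched
  one-to-one within 1.5 Å, maximized over allowed origin shifts × hand,
  with per-site distances minimized over symmetry operators; greedy
  matching by ascending distance (assignment optimality is irrelevant at
  ≤20 sites). The reference is the 6σ peak set of the model-phased map — an
  experimentally accessible pseudo-atom reference — so the metric
  measures what a real experiment could measure; comparisons against generator truth are
  reported separately where used.
* wMPE: `Σ w·|Δφ| / Σ w` with `w = fom·|F|` by default, after alignment
  over allowed origin shifts and hand. In P1 the origin is continuous and
  alignment is restricted to hand; the P1 tests therefore use explicit
  `align = FALSE` comparisons.
* Drivers: `runDoseSeries` pairs exposure 1 with each later exposure and
  averages max/min peak heights over the K grid (error bar = sd over K,
  failures averaged in and flagged); `runMultiplicitySeries` removes
  crystals in nested ≈1.5-fold steps under a fixed resolution window
  (nested rather than independent omission for lower series variance);
  `runKScan` runs the full substructure→phasing→evaluation chain per K
  and reports the per-K correctness/wMPE curves, their across-K average,
  and the best-K phase error (the reported wMPE convention).

# Numerical choices and problem sizes

Maps use FFT grids at ≤ d_min/3 spacing rounded up to 2-3-5-smooth
sizes. Phase probabilities use a 5° grid. The E-map recycling uses the
strong-E subset both for synthesis and for greedy scoring; final CC
scores always use the full set. The K-scan driver runs up to 150 search
trials per K with an early stop at CC(all)+CC(weak) ≥ 68 for the
high-signal preset and 30 trials for the degraded X-ray preset; these
are desk-scale analysis settings chosen to keep a full 20-point K scan
in the minutes range on one core, and they are configuration, not study
conditions. The default experiment sizes (10 crystals × 6 exposures,
~2700 unique reflections to 2 Å in a ~33×35×31 Å cell) were chosen so
that a complete dose-series analysis is interactive.

# What the generator does and does not emulate

It emulates: partial serial sub-datasets with dose ladders; specific
damage with signed (loss + relocation) sites; global B/scale decay;
inter-crystal non-isomorphism; counting noise with a floor; orientation
bias. It does not emulate: diffraction physics at the image level,
absorption, bulk-solvent scattering, anomalous signal, radiation
chemistry beyond first-order occupancy decay, indexing ambiguities, or
non-random wedge geometry. Passing tests therefore demonstrate the
correctness and internal consistency of the analysis chain under the
stated statistical model of the data — not performance on real
diffraction images.

# Known limitations

* Absolute hand is undeterminable by construction (see above); hand
  choice is a documented tie-break.
* The E normalization is shell-rms scaling, not a maximum-likelihood
  normalization.
* SIR phase errors are correlated with the substructure model, so
  density modification gains are modest compared to textbook cases with
  independent phase noise; the anchored scheme trades peak improvement
  for stability.
* The greedy CC site selection can stall on a partial solution when the
  per-trial seed is poor; the trial budget, not per-trial power, carries
  the search success rate.
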