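---
title: "Models and methods: hallucinogen-challenge functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: hallucinogen-challenge functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clawfc)
```

# What the package computes

`clawfc` implements two functional-connectivity (fc) analysis chains built
around the same statistical core, plus an optical-density quantifier for
in situ hybridization autoradiographs:

1. **Regional chain (pharmacological functional ultrasound).** Per-ROI
   power-Doppler timecourses from a 40-min session (vehicle injection at
   5 min, drug challenge at 20 min) are despiked, band-passed to
   0.01–0.2 Hz, and correlated pairwise in 300-s windows slid by 60 s.
   Each window's Pearson matrix is Fisher z-transformed
   (`z = atanh(r)`). The prefrontal–sensorimotor (PFC–SM) connectivity of
   a window is the mean z over the 16 edges between
   {ACA, MOs} × {L, R} and {MOp, SSp} × {L, R}. Changes are referenced to
   the final 5-min window before the challenge; per-window paired t-tests
   across subjects are corrected with Benjamini–Hochberg FDR, and the
   post-challenge Δz curve is summarised by its trapezoidal AUC per
   subject (compared across cohorts with an unpaired t). CBV changes are
   quantified on the despiked, *unfiltered* traces as
   `ΔCBV/CBV(t) = 100·(x(t) − B)/B` with `B` the mean over the final
   5 min before the challenge.

2. **Unit chain (dual-probe extracellular recordings).** Spike times of
   sorted units in MOs and SSp over three 20-min blocks (baseline,
   vehicle, drug) are binned at 50 ms, smoothed with a discrete Gaussian
   (σ = 2 bins, i.e. 100 ms), and z-scored over the analysed 15-min span
   after each injection. Every MOs×SSp unit pair is correlated in 60-s
   windows slid by 30 s and Fisher z-transformed. Static fc per block is
   the per-pair mean across windows; the difference matrix is drug-block
   static minus vehicle-block static; the per-unit Δz of an MOs unit is
   the mean of its difference row over all SSp units. Group statistics
   mirror the unit-level layout: a two-sided one-sample Wilcoxon
   signed-rank test of each cohort's pooled Δz against 0, and
   Kruskal–Wallis with Dunn's post-hoc across cohorts.

3. **Optical-density quantifier.** The mean-intensity trace across a
   rectangle placed over the structure of interest; baseline = median of
   the two flanks outside the central 40% span; AUC = trapezoidal
   integral of the baseline-subtracted, floored-at-zero central segment;
   fold change = AUC ratio to the control-group mean.

Everything is testable offline because the package ships seeded
generators that emulate all three recording modalities together with the
ground truth of every injected effect.

# Statistical core

- `fisher_z(r, clip_eps)` clips `r` into `[−1 + ε, 1 − ε]` (default
  `ε = 1e−7`) before `atanh`, so duplicated traces (r = 1) stay finite
  and order is preserved.
- `bh_fdr` is the standard step-up procedure (via `p.adjust`), returning
  monotone adjusted p-values in input order; a test is rejected when its
  adjusted p ≤ q (default 0.05).
- `t_test` defaults to the classical pooled-variance unpaired form
  (Welch by flag); zero-variance inputs raise `"degenerate sample"`.
- `wilcoxon_one_sample` drops exact zeros (their count is reported),
  uses the exact null distribution for n ≤ 25 with untied absolute
  values, and a continuity-corrected normal approximation otherwise.
- `kruskal_dunn` computes the tie-corrected H and Dunn's pairwise z from
  mean ranks with tie-corrected variance; pairwise p-values are
  BH-adjusted by default (Bonferroni by flag).

# The synthetic generators

## Regional sessions (`gen_pfus`)

Each ROI trace is
`level · (1 + loading·latent(t) + drop·s(t) + noise)`, with unit-variance
Ornstein–Uhlenbeck (OU) latent factors. A ROI loads on a global factor
(weight `√baseline_coupling`), a group factor (PFC or SM, weight
`√drug_coupling_delta`), and a private factor. After the challenge the
two group factors are progressively mixed with a common source following
a peak-normalised gamma onset kernel `s(t)` (shape 3, scale 150 s), so
the PFC×SM latent correlation rises from `baseline_coupling` (0.25) to
`baseline_coupling + drug_coupling_delta` (default +0.3) at the kernel
peak while within-group coupling is unchanged. The same kernel scales the
CBV drop (−15% at peak) in the PFC ROIs. Motion artifacts are
session-wide multiplicative bursts of 1–3 samples (gain 2, 0.5 bursts per
minute) at recorded indices.

Choices worth stating:

- **Sampling rate 1 Hz, not the acquisition frame rate.** The analysis
  band only requires `fs > 0.4 Hz`; 1 Hz keeps simulated sessions small.
  `fs` is configurable.
- **OU timescale 4 s.** The factor spectrum must live inside the
  0.01–0.2 Hz analysis band *and* give enough effective samples per 300-s
  window for window-level inference: at a timescale of τ the effective
  sample count is roughly `window/(2τ)`, so 4 s gives ~37 effective
  samples per window while a slow 20-s factor would give ~7 and make
  per-window tests at n = 10 subjects essentially powerless. 4 s
  (knee ≈ 0.04 Hz) balances both constraints.
- **Artifacts are global events**, as probe or animal motion hits all
  ROIs simultaneously; the despiking recovery tests score per-trace masks
  against the recorded indices.

## Dual-probe sessions (`gen_spikes`)

Units are doubly stochastic Poisson processes:
`λ_u(t) = exp(μ_u + a·f_region(t) + b_k·f_shared(t))` with unit-variance
OU factors, `μ_u` offset by `−(a² + b_k²)/2` so the mean rate equals the
drawn per-unit rate (lognormal, median 1.5 Hz). The cross-region loading
`b_k` is scaled per block: the drug-responsive regime reduces it in the
drug block (0.6, 0.6, 0.2); the non-responsive regime holds it equal and
low across the injection blocks (0.6, 0.05, 0.05). Spikes are drawn by
Poisson splitting — a per-block total count and envelope-weighted bin
placement — which is exactly equivalent in law to independent per-bin
Poisson counts and much cheaper.

The default cohort (6 animals × 34 MOs / 12 SSp units, pooled to ~204
MOs units) and the low rates, couplings and 0.15-s factor timescale were
fixed once, with a purpose: the pooled-unit Wilcoxon treats units as
independent although all units of one animal share the same latent
realisation. The shared (session-level) estimation noise of the per-unit
Δz scales with the *measured* pair correlation and with the factor
timescale, while the unit-level spread scales with the Poisson noise.
Under strong coupling or slow factors the shared noise dominates the
pooled test's standard error and the no-change cohort would be declared
significant in a large fraction of simulated experiments — an
anticonservatism inherent to pooling cluster-correlated units, not a
property of this implementation. The defaults keep the no-change arm at
its nominal level while the responsive arm's median Δz (≈ −0.1) remains
far above threshold. For the same reason the type-I check of the
cross-cohort Kruskal–Wallis is run under the fully independent null
(all couplings zero); with block-constant nonzero coupling and few
animals the pooled KW inflates to roughly twice its nominal level.

## Banded images (`gen_od_image`)

Background plus a Gaussian-profile band along one axis plus pixel noise;
truth records centre, width and amplitude. The AUC estimator is linear
in band amplitude, which the tests exploit (ratio and fold-change
checks).

## What the generators do not emulate

Real power-Doppler physiology (vascular physiology, anesthesia depth
drift, hemodynamic response shapes), real spike-train structure
(refractoriness, bursting, oscillatory coupling, non-Poisson count
dispersion), probe drift, and sorting errors. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
statistical model — not fidelity of the model to any particular animal
dataset.

# Numerical choices and degenerate inputs

- **Despiking**: deviation from an 11-sample rolling median compared to
  `k` (default 5) times a rolling MAD. The MAD is computed over a wider
  101-sample window: an 11-sample MAD is itself so noisy that a 5-MAD
  rule flags ~1% of clean Gaussian samples; the wide scale window brings
  the false-flag rate to the Gaussian tail level (~0.1%) while still
  tracking slow changes in scatter. Flagged samples are linearly
  interpolated between the nearest unflagged neighbours (edges take the
  nearest unflagged value). More than 20% flagged logs a warning; all
  flagged is an error.
- **Band-pass**: zero-phase (forward–backward) 2nd-order Butterworth.
  The trace is extended by odd reflection about its endpoints before
  filtering and trimmed after: without this the filter's start-up
  transient injects a large *shared* component into the first and last
  correlation windows, which showed up as ~100% false rejections in the
  edge windows under null simulations.
- **Zero-variance pairs/units** propagate as missing values, never as
  zero; all averages are over observed entries only. Units that are
  constant in either analysed block are excluded from both.
- **Averaging scale**: windowed values are averaged on the Fisher-z
  scale (the difference-matrix axis of the figures is a Δz); averaging
  on the r scale is available by flag.
- **Baseline window**: the window whose span is exactly the final
  `fc_window_s` before the drug time; Δz at that window is 0 by
  construction.
- **AUC**: trapezoid over window start times from the drug time to the
  end of the recording (the integration span and rule are the package's
  concretisation).
- **CBV tests** are binned to 60 s before testing so the FDR family is
  one test per ROI-minute.
- **OD profile**: central span = central 40% of the trace,
  flank-median baseline, floor at zero — all three exposed in
  `profile_spec`, since the quantifier's peak-span rule is a
  concretisation. An option for inverted film scans negates intensities
  on input.
- **Half-open conventions**: all intervals are `[start, end)`; spike
  bins drop a trailing partial bin; times are seconds from acquisition
  start.

# Problem sizes used by the test suite

The packaged checks run at the scale of the simulated study: regional
power simulations use 100 cohorts of 10 subjects (plus 500 null cohorts
of 6), unit-level power simulations 100 pairs of 6-animal cohorts
(~204 pooled units each), artifact recovery 20 sessions, and the
optical-density linearity 20 seed pairs. These sizes give binomial
standard errors of a few percent on the reported proportions while
keeping a full test run in the tens of minutes on one CPU.

# Known limitations

- The pooled-unit tests inherit the independence assumption of the
  original unit-level analysis; the vignette sections above describe
  when that assumption is consequential.
- The regional chain assumes a common window grid across subjects
  (identical session schedules).
- Dunn's post-hoc uses BH adjustment across pairs by default; the exact
  historical adjustment behind published figures is typically
  unspecified, so Bonferroni is offered as an alternative.
- The despiking detector targets short multiplicative bursts; slow
  baseline drifts are left to the band-pass stage.
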