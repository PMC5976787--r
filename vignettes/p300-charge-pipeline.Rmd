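---
title: "Quantitative P300 source analysis and the regional charge observable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative P300 source analysis and the regional charge observable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a visual oddball experiment a subject watches a stream of frequent
"standard" stimuli (STD) with rare "targets" (TGT) interspersed, pressing a
button at each target. Averaging the EEG epochs time-locked to the stimuli
reveals the P300, a positive deflection some 300–600 ms after stimulus
onset that is larger for targets. Source localization turns the averaged
scalp potentials into an estimate of cortical current density, which can be
summarized per anatomical region (Brodmann areas, BAs).

`p300iota` implements this protocol end to end and adds a scalar summary
per region and condition: the **charge observable ι**. If
\(I(\mathrm{BA}, \tau, t)\) is the current amplitude attributed to a region
at time \(t\) after a stimulus at \(\tau\), then

\[
\iota = q(\mathrm{BA}, \tau) = \int_{\tau + t_1}^{\tau + t_2}
  I(\mathrm{BA}, \tau, t)\, dt ,
\qquad t_1 = 280~\mathrm{ms},\; t_2 = 600~\mathrm{ms},
\]

the electric charge that flowed through the area during the window in
which the P300 is expected. Ranking regions by ι rather than by peak
current rewards activity that is *sustained*, not merely briefly large: a
region at 2 units for 100 ms (charge 0.2) outranks one at 5 units for
10 ms (charge 0.05).

## Pipeline stages and their models

### Forward model

A homogeneous single-sphere head: sensors sit on a 9 cm sphere
(quasi-uniform golden-angle spiral over the upper hemisphere, any montage
size ≥ 8; default 256 to match dense-array nets), sources on a cubic grid
clipped to an 8 cm sphere. The gain of a dipole component \(e\) at
\(r_0\) seen by an electrode at \(r\) is the quasi-static potential
\((1/4\pi\sigma)\, e\cdot(r-r_0)/|r-r_0|^3\) with \(\sigma = 0.33\)
S/m, average-referenced across channels and expressed in µV per nA·m.
This replaces the proprietary head models of acquisition software: it is
deterministic and sufficient for every property tested here, but it is
*not* anatomically realistic (no skull, no CSF, no cortical surface).

The packaged atlas is synthetic: each hemisphere (left/right by the sign
of x; the midline x = 0 counts as right) is divided into angular sectors
mapped to Brodmann-area numbers, with voxels near the center labeled
Hipp/Amyg. It reuses the reporting vocabulary of real atlases — including
merging BA1/BA2/BA3 into "S1" for reports — so outputs are comparable in
form, but region names carry no anatomical meaning on simulated data. A
real voxel-to-region table can be supplied as CSV (`read_atlas_csv()`).

### Simulator

`make_schedule()` generates the stimulus protocol: 4 series of 100
stimuli, 20% targets per series placed in seeded-random order with no two
targets adjacent (the usual oddball constraint; infeasible fractions fall
back to a plain shuffle with a warning), 0.5 s display and 1.5 s
inter-stimulus interval. The first series is a practice series and is
excluded from analysis, leaving 300 stimuli: 60 TGT, 240 STD.

`simulate_recording()` drives a radial dipole at the centroid voxel of a
chosen region with a Gaussian bump (peak 0.4 s, SD 0.06 s — over 95% of
its mass inside the 280–600 ms window) at every stimulus onset: 50 nA·m
peak moment for targets and 20% of that for standards, since standards
evoke a weak but nonzero response. Noise is white sensor noise (2 µV SD)
plus 1/f background (1 µV SD) and an optional common 10 Hz rhythm.
`inject_blinks()` adds 400 µV, 300 ms half-sine transients with a
frontal-dominant spatial profile at seeded times, recorded in the metadata
so rejection logic can be tested against ground truth.

What the generator does *not* emulate: correlated anatomical noise,
saccades, drifts, electrode pops, trial-to-trial latency jitter, or any
subject-level variability. A green end-to-end test therefore establishes
that the chain of estimators is self-consistent — that a known source is
recovered under the stated noise — not that the method is validated on
real recordings.

Defaults not fixed by the protocol were chosen once as field-typical
values and are not tuned: sampling rate 500 Hz (dense-array systems record
250–1000 Hz; the verification runs use 250 Hz to stay fast), ISI 1.5 s
(leaves a full epoch plus baseline without overlap), 50 nA·m dipole moment
(a typical evoked-response moment, giving ~5 µV peak scalp deflection and
an averaged-evoked SNR well above 5 under the default noise).

### Preprocessing

Epochs span (−200, 800) ms around each onset with a (−200, 0) ms baseline
(the protocol does not fix these; the window must contain the ι
integration range). Conventions throughout: 0-based sample indices,
half-open sample intervals, time 0 = stimulus onset. An optional zero-phase
band-pass (0.5–40 Hz, an FFT mask with raised-cosine transitions) runs
before epoching. Artifact rejection is threshold-based — an epoch is
dropped if any channel exceeds 150 µV peak-to-peak, or flagged flat if all
channels stay under 0.1 µV — substituting for the eye-tracker-assisted
ocular correction used with laboratory hardware; it is deterministic and
exactly testable against the injected blink times.

### Inverse solution

The sLORETA estimator: with average-referenced lead field \(K\) and
centering matrix \(H\), the minimum-norm kernel is
\(T = K^\top (K K^\top + \alpha H)^+\), and the estimate
\(\hat J = T \varphi\) is standardized per voxel by the 3×3 diagonal
blocks of the resolution matrix \(S = T K\):
\(p_l(t) = \hat J_l(t)^\top [S]_{ll}^{+} \hat J_l(t)\). Pseudo-inverses
truncate eigenvalues below \(10^{-12}\) of the maximum. `alpha = "auto"`
sets \(\alpha = \mathrm{tr}(K K^\top) / (n\,\mathrm{snr}^2)\) with
snr = 3; noise covariance is assumed identity (scaled into α).

The standardization is the point: for noise-free data from a point source,
the voxel maximizing \(p\) is exactly the true voxel — zero localization
error — at \(\alpha = 0\), for every voxel and orientation, which the test
suite verifies by exhaustive sweep on a 32-channel, ~200-voxel model.
Plain minimum-norm power on the same model mislocalizes deep sources by
several centimeters. Estimates are computed on condition-averaged evoked
responses, not single trials. Amplitudes are reported in model units: the
standardized magnitude is dimensionless under unit noise, and no attempt
is made to restore an absolute nanoampere scale.

### Region aggregation and ι

Voxel magnitudes are reduced per region (mean by default; max and sum are
options — the choice is a genuine free parameter, as nothing in the
protocol fixes how a software package reduces voxels to an area value) and
averaged within 5 ms bins. ι is the trapezoidal integral of the binned
trace over [t₁, t₂] on bin centers, with linear interpolation where a
window edge falls between centers; the integration rule is deliberately
the simplest one consistent with "any numerical integration method".
`most_active_regions()` reports the top region by ι plus any region within
5% of it, at most two — reproducing the at-most-two-areas convention of
printed reports; ties break lexicographically.

## Numerical and degenerate-input choices

* Eigenvalue truncation at \(10^{-12}\) relative, everywhere a
  pseudo-inverse appears.
* Standardized power is clamped at zero to absorb rounding in the
  positive-semidefinite quadratic form.
* A grid step larger than the source radius leaves the degenerate
  single-voxel grid at the origin rather than erroring.
* Channels with zero signal get a unit physical range in the EDF writer to
  avoid a zero scale factor.
* Epochs whose window leaves the recording are silently dropped; if none
  fits, an empty epoch set is returned with a warning.
* Rejection only ever clears `kept` flags, so rejections compose
  monotonically.

## Limitations

The spherical model and synthetic atlas make absolute localization claims
meaningless: only the *relative* machinery (standardization, binning,
integration, ranking, reporting) transfers to real data, where a measured
montage, a realistic head model and a genuine atlas must be supplied. The
ι values are in (model current unit)·seconds and cannot be compared to
charges printed in microcoulombs elsewhere; on evoked responses in
nanoampere-scale units a 0.32 s window yields nano-scale charges, and we
keep model units explicit rather than reproduce an inconsistent unit
label. Nothing here performs group statistics or supports diagnostic
claims.

## A worked run

```{r, eval = FALSE}
library(p300iota)

sens  <- make_standard_montage(32)
src   <- make_grid_source_space(0.022, 0.08)
lf    <- make_spherical_leadfield(sens, src)
atlas <- assign_regions(src)

sch <- make_schedule(seed = 1)
rec <- simulate_recording(sch, lf, atlas, "R18", srate = 250, seed = 1)
res <- run_pipeline(rec, lf, atlas)
res
build_subject_report(res)
```

The same chain, from EDF files on disk, is available through the
command-line driver installed at
`system.file("cli/p300iota.R", package = "p300iota")`.
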