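---
title: "Quantifying MAP7–kinesin dynamics: models, estimators and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MAP7–kinesin dynamics: models, estimators and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axokin)
```

This package quantifies three kinds of measurement that together describe how
the microtubule-associated protein MAP7 cooperates with the kinesin-1 motor in
cells: FRAP binding kinetics on microtubules, run-and-pause statistics of
kinesin-driven organelle transport, and axon arbor morphometry. Because the
underlying microscopy data are not part of the package, every estimator is
paired with a seeded synthetic-data generator that emits a ground-truth event
log; all validation is parameter recovery against those logs. This vignette
explains each model, the tunable parameters and their defaults, the numerical
choices, and what the passing tests do and do not establish about real data.

## FRAP binding kinetics

A fluorescently tagged protein bound to microtubules is bleached in a small
region; recovery of fluorescence reports exchange of bleached for unbleached
molecules. Under a diffusion-uncoupled binding reaction (binding slow relative
to diffusion), the normalized recovery is single-exponential,

$$R(t) = A\,(1 - e^{-k_\mathrm{off} t}),$$

with $k_\mathrm{off}$ the dissociation rate constant (s⁻¹), $A$ the mobile
fraction in percent (reported as *total recovery*), and the half-life tied by
the exact identity $t_{1/2} = \ln 2 / k_\mathrm{off}$.

**Normalization** (`normalize_trace()`). Raw per-frame intensities of three
regions — bleached, unbleached reference, background — are combined as
$C(t) = (F_\mathrm{ble} - F_\mathrm{bg}) / (F_\mathrm{unb} - F_\mathrm{bg})$;
the reference division cancels acquisition photobleaching. Percent recovery is
$100\,(C(t) - F_0)/(F_\mathrm{pre} - F_0)$ with $F_\mathrm{pre}$ the mean
corrected ratio over all pre-bleach frames and $F_0$ the ratio at the first
included post-bleach frame. Two readings were genuinely open:

* $F_0$ is the observed first post-bleach value, not a fitted offset: it is
  defined as the fluorescence immediately after photobleaching, so we treat it
  as data. Consequence: `recovery(0) = 0` holds by construction.
* $F_\mathrm{pre}$ averages all pre-bleach frames (a single-frame definition
  would only add noise; with one pre-bleach frame the two coincide).
* "Maximum recovery set at 100" is read as an upper *bound* on the plateau
  ($0 < A \le 100$), with $A$ itself free and reported as the total recovery.
  Reading it as fixing $A = 100$ would make the reported sub-100% total
  recoveries impossible, so the bound reading is the only consistent one.

Frames flagged out-of-focus are dropped before any computation. Degenerate
inputs fail loudly: a trace with $F_\mathrm{pre} = F_0$ (no bleach) or a
non-positive corrected reference is an error, not a number.

**Fitting** (`fit_recovery()`). Bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with $0 < A \le 100$, $k_\mathrm{off} > 0$. Starting
values are $A_0$ = last observed recovery and $k_0 = \ln 2 /$ (time to half of
$A_0$), falling back to the reciprocal observation span; convergence is
reported honestly in the `converged` flag and non-convergence yields `NA`
estimates rather than silent values. Standard errors come from the curvature
of the least-squares surface; a seeded residual bootstrap (500 replicates)
replaces them when the curvature is ill-conditioned.

**Generator** (`simulate_frap_trace()`). The latent recovery is the model
above; the raw three-region signals are constructed so the normalization
chain recovers it *exactly* at zero noise (the round trip to
$(k_\mathrm{off}, A)$ is then accurate to $10^{-6}$ relative error, which the
tests assert). Per-frame Gaussian noise is added independently to all three
regions; optional whole-field acquisition bleaching decays the reference and
must cancel. Defaults: pre-bleach intensity 1000 a.u. over a background of
50, bleach depth 0.8, so "noise at 3% of the dynamic range" is
`noise_sd = 24`. Simulated studies in this package use 200 traces per regime,
with frame intervals of 1 s (fast regime, ~60 s span) and 5 s (slow regime,
~400 s span), matching each regime's half-life scale. At that noise the mean
fitted plateau of the slow regime carries a small positive bias (≈ +1.5
percentage points at $A = 38$, from the plateau–rate correlation when the
curve is observed for ~2.5 half-lives); it stays well within the 10% recovery
tolerance the tests use.

What this does *not* show: real FRAP curves can be diffusion-coupled,
multi-component, or contaminated by focus drift. The package deliberately
fits only the single-site model and exposes residuals (`rss`) for judging it.

## Organelle transport

Transported organelles alternate **runs** at roughly constant speed with
**pauses**; a pause is operationally movement slower than 0.1 µm/s. A *pause
or speed switch* is any change of speed along a track, i.e. every boundary
between consecutive constant-speed segments. A **sharp turn** is a post-pause
resumption at more than 90° to the previous run, the signature of switching
onto a crossing microtubule.

**Generator** (`simulate_transport_tracks()`). Continuous-time state machine:
exponential waiting times to pause entry and to in-run speed redraws (rates
per minute of run time), truncated-normal run speeds (> 0), pause durations
exponential by default — the distributional form is an assumption, flagged
and configurable via `pause_duration_min`, which shifts the distribution away
from zero for resolution-controlled experiments. In 2D, post-pause headings
turn by more than 90° (uniform up to 180°, random side) with probability
`sharp_turn_prob`, otherwise stay within ±30°; the two classes are disjoint
by construction so recovery of the turn fraction is well-defined. Positions
are sampled at the frame interval with i.i.d. Gaussian localization noise per
coordinate. Defaults emulate control COS-cell mitochondria driven by active
kinesin-1: 0.70 ± 0.15 µm/s runs, 3 pauses/min of ~12 s, 1 speed switch/min,
turn probability 0.45, 2-minute tracks at 1 s sampling, 50 nm localization
noise. Every simulation returns the exact event log.

**Path reduction.** Kymograph analysis reads a 2D trajectory along a drawn
line. `project_onto_path()` is the literal analog (nearest-point arc-length
projection onto a polyline, continuity-tie-breaking, 2 µm corridor);
`track_arc_length()` is the self-path version used for free 2D trajectories:
positions are boxcar-smoothed (3 frames) and cumulative travelled distance
becomes the 1D coordinate. The smoothing matters: unsigned arc length
accumulates localization noise as spurious forward drift during pauses
(≈ 0.09 µm/s at the default noise, right at the pause threshold); smoothing
brings it to ≈ 0.03 µm/s.

**Segmentation** (`segment_track()`). A segment is a maximal constant-speed
portion of a track. The published analysis drew segments by hand on
kymographs; this package operationalizes it as bottom-up change-point
merging:

1. instantaneous frame-to-frame speeds, boxcar-smoothed (3 frames);
2. one segment per frame interval initially; repeatedly merge the adjacent
   pair with the smallest speed difference while that difference is below
   `max(abs_speed_change, rel_speed_change × larger speed)` — defaults
   0.1 µm/s and 30% — or while either member is shorter than
   `min_segment_duration` (2 s);
3. **boundary refinement**: smoothing smears change points by up to the
   boxcar half-width, so each boundary may shift locally to the breakpoint
   minimizing the duration-weighted residual of the *raw* interval speeds,
   never squeezing a segment below the minimum duration;
4. **classification on the eroded core**: each segment is called run or pause
   by the mean raw speed of its interior (boundary intervals excluded when
   the segment can spare them), against the 0.1 µm/s threshold — boundary
   smear otherwise pushes short pauses over the threshold;
5. adjacent pauses coalesce;
6. **sub-frame vertex placement**: each boundary finally moves to the
   intersection of the two flanking constant-speed lines (anchored at the
   eroded-core centroid with the core slope), clamped to within one frame.
   This mirrors how a rater places vertices at kymograph line intersections
   and removes the ~½-frame-per-boundary dilution that grid-aligned
   boundaries impose on $s = l/t$.

Reported segment speeds are signed net displacement over duration between the
placed boundaries, so segment durations tile the observation window exactly
and concatenated displacements telescope to the track displacement — both
asserted as invariants. On noiseless tracks with ≤ 3 phases the segmentation
equals exhaustive minimum-cost change-point search (tested against a
brute-force oracle), and 1D speeds are signed so a direction reversal is a
speed change.

**Statistics** (`run_speed_stats()`, `pause_stats()`, `switch_stats()`,
`sharp_turn_stats()`, `aggregate_by_condition()`). Run speed is $s = l/t$ per
segment, runs weighted equally; frequencies are events per minute of the full
track duration including pauses (the denominator was not specified in the
source analysis; total observed time is the choice that makes frequencies
comparable across conditions with different pausing). Turn angles compare
whole-run mean displacement directions, not single-frame headings, for noise
robustness; a pause at a track boundary is not evaluable and is skipped.
Tracks observed under 30 s are flagged low-confidence; immobile organelles
(net displacement < 1 µm) are excluded from run analysis. Aggregation is
tracks → unweighted cell means → condition mean ± SEM over cells, with a
4-track minimum per cell.

**Detection resolution and what "recovery" means.** Any finite-resolution
segmentation has a floor: a pause shorter than `min_segment_duration`
vanishes into its flanking runs, two pauses separated by a sub-floor run are
one pause to any observer of the data, and a speed redraw below the change
criterion is invisible. `resolvable_events()` filters the ground-truth log
accordingly, and recovery tests compare estimates to the *resolvable* event
counts (within 15% at realistic noise; exactly, for ≥ 95% of tracks, at zero
noise with pause durations bounded away from the floor). Raw generative rates
are still asserted to be recovered *monotonically* (Kendall τ = 1 across
3-point rate grids). With exponential pauses of mean 12 s, ~15% of true
pauses fall under a 2 s floor, so no tracker — human or algorithmic — can
recover the raw generative pause rate to better than that; treating the
resolvable log as the reference is the honest statement of what the method
measures. Equal-weight mean run speed carries a related caveat: short
detected runs are noisier and slightly slow-biased, so the mean is accurate
to ~5% only in the clean regime (the tests assert exactly that), and
duration-weighted speeds are less biased when absolute speeds matter.

## Arbor morphometry

Arbors are rooted trees in SWC form (id, type, x, y, z, radius, parent;
µm; soma = type-1 root). The **main axon** is the soma-to-tip path of maximal
cumulative length (ties broken toward the smallest tip id). A **branch** is
the maximal subtree hanging off a main-axon node; its length is the longest
path from the attachment point to any of its tips, only branches longer than
10 µm count, and the branch count is the number of qualifying tips — so a
bifurcated branch contributes each of its tips, consistent with counting tips
per neuron, while the main axon's own growth cone is not counted (an
unbranched neuron has 0 branches). Branches emerging from the distal 10% of
the main axon are **terminal**, the rest **interstitial**; the 90% boundary
itself classifies as interstitial. All statistics are invariant under rigid
motion of the trace (tested), and the main axon equals exhaustive path
enumeration on trees up to 50 nodes (tested).

The generator (`simulate_arbor()`) places interstitial origins uniformly on
the proximal 90% and terminal origins on the distal 10%, inserting exact
attachment nodes; branch lengths are truncated-normal with a floor of 12 µm
(above the 10 µm counting threshold, so requested branches are countable) and
a cap keeping every soma-to-branch-tip path strictly shorter than the main
axon — terminal origins are likewise kept proximal enough that a
minimum-length branch still fits. Without the cap the longest-path definition
would reassign the main axon through a long branch and the ground-truth
labels would be incoherent.

**Line scans** (`simulate_line_scan()`, `line_scan_peak_ratio()`): a profile
across a microtubule is baseline plus one Gaussian peak; the statistic is
peak over background, with the peak read from a lightly smoothed profile and
the background as the median of samples outside the peak's half-prominence
support (half-maximum measured above the profile median, so a peak comparable
in height to the baseline still has bounded support). A flat profile returns
ratio 1 by definition.

## Statistical layer

Group summaries are mean ± SEM (n−1 standard deviation over √n). Two groups
are compared by unpaired two-tailed Student's t-test (equal variances — the
convention of the source analyses; Welch by flag), three or more by one-way
ANOVA with Tukey HSD post hoc comparisons, both delegated to the standard R
implementations behind a thin reporting surface (stars exactly at *p* < 0.05,
0.01, 0.001). Normality is checked by a one-sample Kolmogorov–Smirnov test
against a normal with the sample's own mean and sd; estimating the reference
from the sample makes the nominal p-value conservative (no Lilliefors
correction is applied) and the result carries that caveat, with n < 5 flagged
underpowered. The suite calibrates the t-test's type-I error (5% ± 1.5% over
2000 seeded null replicates) and checks $F = t^2$ for two groups to machine
precision. Effect sizes are reported as percent change
$100\,( \bar{x}_\mathrm{ctrl} - \bar{x}_\mathrm{trt})/\bar{x}_\mathrm{ctrl}$
(a decrease is positive) and fold change
$\bar{x}_\mathrm{trt}/\bar{x}_\mathrm{ctrl}$.

## Problem sizes, determinism and limitations

Simulated studies use 200 traces per FRAP regime, 200 tracks (or 3 × 100–160
for rate grids) per motility experiment and 20 neurons per arbor condition —
sizes at which the stochastic tolerances above are comfortably powered while
a full run of the suite stays in the minutes range. Every stochastic function
takes an explicit integer seed and is bit-reproducible from it; nothing draws
silent entropy.

Known limitations, by design: no diffusion-coupled or multi-exponential FRAP
models; no particle detection or linking from raw movies (trajectories are
inputs); no point-spread-function or camera-noise modelling beyond additive
Gaussian; no retrograde/anterograde decomposition; no Sholl analysis or
automated neurite tracing. The generators emulate the statistical structure
the estimators assume — which is precisely what makes recovery testable — so
passing tests certify the estimators, not the biology: systematic deviations
of real data from these models (non-exponential pauses, speed drift within
runs, curved bleach geometries) are outside what this validation can see.
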