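---
title: "Methods: EEG reactivity to tactile stimulation and its morphometric correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG reactivity to tactile stimulation and its morphometric correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

After severe traumatic brain injury (TBI), predicting whether a comatose
patient will recover is notoriously hard. One candidate bedside biomarker
is EEG *reactivity*: whether, and how, the spectral content of the EEG
changes when the patient is stimulated. The design this package replicates
compares 19-channel resting-state EEG with EEG recorded during gentle
tactile stimulation of the forearm (four stimulus types: slow/fast
stroking with a soft or hard brush, 10 presentations of 10 s each), in
comatose TBI patients and healthy controls. The quantity of interest is
the per-electrode change in band power between stimulation and rest —
in particular suppression of theta (4–6 Hz) power, which in patients
tracks recovery (GOSe outcome) and the amount of preserved brain tissue
measured by FreeSurfer morphometry.

`tactileEEG` implements the complete analysis chain as a reusable,
tested package: spectral estimation, group statistics, per-subject
significance maps, and the core inferential procedure — a cluster-based
permutation test on Spearman correlation topographies — together with a
synthetic-cohort generator that reproduces the statistical structure of
the study so the whole chain can be exercised end to end without access
to patient data.

## Spectral estimation

Each 10-s epoch is transformed to a one-sided power spectral density per
electrode. The default estimator is Welch's method with 2-s Hann windows
and 50% overlap; segments are demeaned before tapering. A single-window
rectangular mode (`window_spec("rectangular")`) is retained because it
equals the plain DFT periodogram exactly and serves as the oracle in the
test suite (Parseval identity, frequency localization).

Spectra are then normalized to *relative power*: each electrode's PSD is
divided by its integral over [2, 20) Hz, and integrated over the 18
half-open unit bins [2,3), …, [19,20) by trapezoidal quadrature, so the
bins of one electrode sum to exactly 1. Bins are half-open because the
conventional "2–3 Hz, 3–4 Hz" notation leaves boundary ownership
ambiguous; a half-open partition covers [2, 20) without double counting.
Normalization is selectable (`normalize = "none"` for absolute power):
relative power is the common EEG convention and makes subjects with very
different overall amplitudes comparable, but it couples the bands — a
true increase in alpha necessarily depresses every other relative band.
The consequences are discussed under *Limitations* below.

Two band schemes ship because the two analyses call for different
band sets: the
`"contrast"` scheme (slow 2–6, theta 4–6, alpha 11–13, beta 17–20 Hz)
for stimulation-vs-rest contrasts, and the `"resting"` scheme (slow 2–6,
alpha 8–12, beta 16–20 Hz) for resting-state group comparisons. Neither
is silently preferred; every function takes the scheme explicitly.

Condition-level tables average the per-epoch bin spectra over all epochs
of a condition. This is the expectation-equivalent of concatenating the
10-s epochs into one 200-s segment (stationary epochs), but robust to
inter-trial discontinuities; it is a deliberate, documented deviation
from literal concatenation. Merge rules: `per_stimulus` (5 conditions),
`valence_pairs` (soft-brush vs hard-brush pairs, 200 s each), and
`all_stimulation` (all 40 trials pooled, used for the contrast maps).

## Group and individual statistics

Morphometry group differences use the Mann–Whitney U test (midrank ties;
exact enumeration for combined n ≤ 12 without ties, otherwise the normal
approximation with tie and continuity corrections), with the
standardized Z reported alongside as morphometry tables conventionally
do. Two-sided tests are assumed throughout, since sidedness was an open
choice.

PSD group/condition effects use a classical mixed repeated-measures
ANOVA (between factor GROUP, within factor CONDITION: rest + 4 stimulus
types) on electrode-averaged relative power, per 1-Hz bin and repeated
for merged bands. The group effect is tested against subjects-within-
groups; condition and interaction against the condition × subject error.
No sphericity correction is applied by default — this matches the plain
df convention F(1, n−2) for the group effect — but Greenhouse–Geisser
correction is available (`gg_correction = TRUE`). Degenerate strata
(mean squares that are numerically zero relative to the response scale)
are reported as F = 0, p = 1 rather than NaN.

Per-subject reactivity uses a two-sample Wilcoxon rank test per
electrode on the 40 single-trial band powers against the 40 rest-fragment
band powers. The unpaired rank-sum form is the default because
stimulation trials and rest fragments are not naturally paired; a paired
signed-rank mode exists for paired designs. Significance is controlled
across electrodes by Bonferroni: 0.05/19 ≈ 0.0026 — the electrode count
is the divisor that yields that threshold, and it is
configurable.

## The cluster-based permutation test

The core procedure relates a contrast topography (subjects × electrodes,
stimulation minus rest) to a scalar covariate:

1. Per electrode, Spearman's rho (Pearson correlation of midranks)
   between contrast and covariate, transformed to
   t = rho·sqrt((n−2)/(1−rho²)).
2. The covariate is randomly permuted across subjects 500 times and the
   full map recomputed each time. The cluster-forming threshold is taken
   at the 2.5th/97.5th quantiles of the *pooled* permutation t values
   (all electrodes, all permutations). Which distribution the quantiles
   refer to is a genuine design choice; the pooled permutation
   distribution is self-contained and distribution-free, and a
   parametric t(n−2) mode is provided as an alternative.
3. Supra-threshold electrodes are grouped into connected clusters under
   a fixed, shipped adjacency table for the 19-channel 10–20 montage
   (nearest neighbours along the layout's axes, e.g. C3 ~ {F3, Cz, P3,
   T3}); minimum cluster size 1, so singletons survive. Cluster mass =
   sum of member t values.
4. Each permutation contributes its maximum absolute cluster mass (the
   max-statistic construction, which guarantees weak FWER control
   two-sided). Cluster p = (b + 1)/(N + 1), where b counts null maxima
   at or above the observed |mass|; at N = 500 the floor 1/501 displays
   as 0.002.
5. Across the covariate battery (gray-matter volume, right putamen,
   right insula, surface holes, GOSe, paracentral/precentral thickness),
   Bonferroni correction is applied to the cluster p-values. Correcting
   across covariates within a band (rather than across bands too) was an
   open choice; both are available.

Sign convention: the contrast is *stimulation minus rest*, so theta
suppression is negative. Covariates that grow with preserved tissue
(volumes, GOSe) therefore show *negative* clusters, and the
damaged-tissue proxy (surface holes) *positive* ones. The "threshold of
0.025" is read here as the 2.5% tail criterion,
not as an absolute t value of 0.025.

## The synthetic cohort

The generator emulates the study's statistical structure, not its
physiology:

* **EEG**: each epoch is a Gaussian process whose one-sided PSD is a 1/f
  background (exponent 1, amplitude 37 µV²/Hz at 1 Hz — set so control
  resting alpha sits at a signal-to-background ratio near 2) plus
  flat-topped band components: delta 2–4, theta 4–6, alpha 9–13, beta
  16–20 Hz. Components are realized as frequency-domain-shaped white
  noise (equivalently, zero-phase band-pass filtered Gaussian noise),
  not pure tones, so PSD tests are non-degenerate. Patients at rest have
  elevated delta/theta and reduced alpha/beta power relative to controls
  (45/40/8/3 vs 15/12/30/10 µV²); effect sizes give clearly significant
  group contrasts at n = 10 vs 15. Per-subject lognormal band factors
  (log-SD 0.25) model between-subject dispersion.
* **Stimulation**: multiplies alpha power by 1.3 and beta by 1.4 in both
  groups, and theta by (1 − d), where d is the subject's latent
  suppression, a monotone transform of a standard normal into [0, 0.6]
  for patients and 0 for controls.
* **Coupling**: covariates are built through a Gaussian copula — a
  latent normal correlated with the suppression latent at
  r = 2·sin(π·rho_s/6), then mapped through the covariate's marginal —
  which hits the target Spearman correlation (default 0.85 for volumes
  and GOSe, −0.85 for surface holes) in expectation. Targets with
  |rho| > 0.99 are rejected as unreachable. GOSe is an integer cut of
  the coupled latent into {3,…,7} with the outcome frequencies of the
  study's patient table; GCS is uniform on [5, 7]. Thickness values are
  drawn from the per-region, per-group normal distributions of the
  study's thickness table, truncated to (0, 6) mm, with
  paracentral/precentral thickness coupled to a latent beta enhancement.
* **Determinism**: the entire cohort regenerates bit-identically from
  the seed in `cohort.yaml`; the analysis scripts archive only that file
  plus the small tables, and regenerate the EEG on demand.

What the generator does *not* emulate: volume conduction and spatial
correlation between electrodes (channels are independent), artifacts
(eye blinks, ECG — an optional amplitude threshold exists but defaults
off, since no artifact criteria were specified), electrode-specific
topographies of the suppression effect (d acts globally, whereas real
reactivity is regionally weighted), and non-stationarity within epochs.
Passing tests therefore show that the *inference machinery* behaves
correctly under the assumed statistical structure, not that it would be
well calibrated against every property of real clinical EEG — in
particular, spatially correlated noise would make electrode clusters
easier to form under the null than independent channels do, which is
exactly what the permutation null accounts for in either case.

One analysis-level consequence of relative-power normalization is worth
knowing: because stimulation raises alpha/beta power in *both* groups,
relative theta decreases slightly even for control subjects with d = 0.
The generator's own null contract (stimulation leaves theta unchanged
when d = 0) holds in absolute power, and the test suite checks it there.

## Numerical and design choices

* Epochs are half-open sample windows [onset, onset + L) at 0-based
  indices, onsets rounded to the nearest sample; partial trailing
  segments are dropped (a 9.9-s annotation yields no 10-s epoch).
* Rest fragments default to contiguous-from-start selection from the
  rest block; random subsampling is available (`rest_selection`),
  since no fragment-selection rule is canonical.
* EDF I/O is 16-bit with a symmetric physical range; the range is
  remembered on read so write–read–write round-trips are byte-identical.
  Annotations travel in a sidecar events file. The recorder's native
  format is not supported; EDF plus a documented plain-text archive
  dialect stand in.
* The montage adjacency ships as an editable plain-text edge list; the
  graph is validated to be symmetric, loop-free and connected.
* Connected components use a hand-written flood fill over the 19-node
  adjacency matrix because the search sits inside the permutation loop
  (~10^6 calls in the resampling studies); an igraph cross-check guards
  it in the tests.
* Permutations are seeded and the permutation index matrix can be
  stored (`keep_permutations = TRUE`) for exact replay.
* The degrees of freedom of every ANOVA are derived from the data, never
  hard-coded.

## Problem sizes used by the validation suite

The resampling studies in the test suite run at sizes chosen to keep a
complete check of the statistical properties practical on one CPU:
family-wise error is estimated over 300 null cohorts of 10 patients with
a reduced trial structure (2 trials per stimulus type, 8 rest
fragments — under the null the epoch count affects only measurement
noise, not the validity of the permutation test), and coupling recovery
over 50 cohorts at the full study-scale design (10 patients, 4 × 10
trials, 40 rest fragments), where the measured recovery rate at target
rho 0.85 is 78% of seeds with the GOSe association negative in all of
them. These sizes are frozen in the tests as regression guards.

## Limitations

* Spearman rank coupling at n = 10 is intrinsically coarse; even with a
  true rank correlation of 0.85 the sample correlation has an SD of
  roughly 0.12, so single-cohort significance is expected to fail in a
  sizeable minority of replicates. This is a property of the design, not
  of the implementation, and the recovery study quantifies it.
* Because all electrodes share the subject-level suppression latent,
  correlation maps are nearly uniform across the scalp and clusters tend
  to be all-or-nothing; real data would show regional structure.
* The ANOVA is classical (sums of squares); no mixed-effects model is
  fitted; the replication stays with the classical procedure rather
  than improving on it.
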