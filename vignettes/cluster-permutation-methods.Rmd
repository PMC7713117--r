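---
title: "Cluster-based permutation inference for longitudinal ERP studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based permutation inference for longitudinal ERP studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpcluster)
```

## The inference problem

A two-arm longitudinal ERP study yields, for each subject, a channels ×
time voltage matrix per session and stimulus class. The scientific
questions — does the intervention arm change over time, do the arms differ,
does the change differ between arms — are naturally asked at every
(channel, sample) point, which at 32 channels × 150 samples is several
thousand simultaneous tests. The cluster-based permutation test trades
pointwise resolution for family-wise control: evidence is aggregated over
spatiotemporally connected suprathreshold regions, and the aggregate is
referred to a permutation null distribution of the *maximum* such
aggregate, so the probability of any false-positive cluster anywhere in
the map is at most α.

### The statistic

At every point the design's statistic is computed on subject-level ERPs:

* **t-independent** — pooled-variance two-sample *t* over subjects,
  df = n₁ + n₂ − 2;
* **t-paired** — *t* on within-subject condition differences, df = n − 1;
* **F-repeated** — one-way repeated-measures *F* over k matched
  conditions, df = (k − 1, (n − 1)(k − 1)).

Points whose |statistic| exceeds the pointwise critical value at the
cluster-forming α (two-tailed for *t*, upper tail for *F*) are clustered:
two suprathreshold points of like sign are connected when they share a
channel and sit at adjacent samples, or share a sample and sit at
sensor-adjacent channels. The cluster **mass** is the sum of the statistic
over members. Opposite-sign regions never merge.

The minimum-simultaneous-channels rule (default 2) is read as a
*cross-section* constraint: at every time sample, a cluster must span at
least 2 channels; thinner time slices are pruned from the cluster before
its mass is computed. An alternative reading — requiring each member to
have a suprathreshold neighbour — would be stricter per point but permit
single-channel slices; the cross-section reading was chosen because it
directly operationalises "simultaneously significant channels", and the
parameter is configurable (`min_simultaneous_channels = 1` disables it).
Pruning can in principle disconnect a cluster; the pruned member set is
retained as one cluster, since the mass is what is tested.

### The permutation null

The permutation unit respects exchangeability under the null: group labels
are shuffled across subjects (independent design); condition labels are
permuted within subject (paired design: sign flips of the difference;
F design: within-subject permutations of the k labels). For each partition
the maximum |mass| over all clusters is recorded. Two-tailed handling pools
the signs: positive and negative clusters are formed separately, but both
are referred to the same max-|mass| null at α = 0.05. The per-tail
convention (cluster-forming threshold at α/2) is available via
`cluster_alpha = 0.025`; the pooled convention is the default because it
matches a single two-tailed α without halving the forming threshold.

P-values are conservative by construction: the identity partition counts in
both numerator and denominator, so p ≥ 1/(B + 1) with B monte-carlo draws
(p ≥ 1/N for exhaustive enumeration over N partitions), and ties between a
permutation mass and the observed mass count against the observed cluster.
Exhaustive mode activates automatically when the full enumeration is at
most `exhaustive_cap` (default 20 000); monte-carlo is refused outright
below 10 distinct partitions, where a permutation p-value is meaningless.

Group × time interactions with a three-level time factor are tested as
difference-of-differences contrasts: per-subject change waveforms
(T_j − T_i) are computed first, then the independent-groups test compares
the change between arms.

### Effect sizes and brain–behaviour coupling

Cohen's *d* for a cluster averages each subject's voltage over the
cluster's (channel, sample) members and standardises the resulting scalars
(paired: mean/SD of differences; independent: mean difference / pooled
SD). Zero variance yields signed infinity rather than an error, flagged by
the value itself.

Cluster AUC integrates the channel-averaged ERP over the cluster's time
extent with the trapezoid rule (µV·ms, signed). The default reduction is
the cluster's *rectangular hull* — all member channels over the full
member time extent — the simplest reading of "significant channels and
timepoints"; member-exact masking per sample is available
(`member_exact = TRUE`). AUC values are pooled across timepoints within a
group and correlated with reaction time (Pearson, Fisher-z 95% CI);
reported degrees of freedom are n − 2 where n is the post-exclusion pair
count, and the 5th–95th percentile screen logs its exclusions so the df
are always traceable. A correlation needs at least 3 pairs (the CI needs
4 and is NA below that).

## The synthetic study

The generator emulates the study design the analysis assumes, so every
inferential property can be checked against planted ground truth.

* **Montage** — 32 channels by default on a schematic head disc of 10 cm
  radius (sunflower-spiral layout); channel count configurable. The
  statistics are layout-agnostic, so a reduced montage loses nothing
  inferentially while keeping desk-scale runtimes. Sensor adjacency uses a
  distance threshold chosen automatically so the mean degree is ≈ 6, a
  typical sensor-net neighbourhood; the criterion and threshold are logged
  with every result.
* **Task** — AX-CPT blocks of 800 trials with exactly 60 AX targets, 60
  A\* and 60 \*X catch pairs (7.5% each), letters from the angular set
  A, E, F, H, L, N, T, V, X, Y, Z, font size uniform over 100–180 pt, ISI
  uniform over 500–1000 ms. Counts are exact by construction: pairs are
  laid down as two-trial units and fillers never use A or X, so no
  accidental A→X adjacency can occur.
* **ERP components** — P1 (33–107 ms, left parieto-occipital, positive),
  N1 (155–190 ms, parietal-temporal, negative), P2 (178–235 ms, occipital)
  on the cue; P3 (230–400 ms, centroparietal) on the target. Each is a
  plateau over its latency window with raised-cosine shoulders, times a
  topography that is exactly 1 within a core radius of its centroid with
  Gaussian falloff outside. The plateau/core construction makes the
  planted amplitude recoverable *exactly* as the mean over the core
  channels and window — a sharper contract than a Gaussian bump, whose
  mask average undershoots its peak; a Gaussian profile remains available
  per component.
* **Amplitude model** — signed amplitude = polarity·base + planted
  (group, timepoint) delta + subject offset + session offset + trial
  jitter. The between-subject SD (default 2 µV) is split evenly between a
  stable subject component and a session component, so a planted delta Δ
  yields a paired T1-vs-T3 effect size of about Δ/2 at the defaults — the
  planted deltas (P1 +1.3, N1 −1.1, P2 −1.5, P3 +0.72 µV) correspond to
  paired d ≈ 0.65, 0.55, 0.75 and 0.36.
* **Noise** — spatially correlated Gaussian noise with 1/f spectral
  shaping (squared-exponential spatial covariance over sensor distance,
  correlation length half the montage radius; per-channel SD 3 µV). Real
  EEG additionally carries ocular and cardiac artifacts, line noise,
  electrode drift and non-stationarity, none of which are simulated —
  passing tests therefore demonstrate the statistics' operating
  characteristics under a well-behaved noise model, not robustness to
  artifact structure.
* **Behaviour** — trial RTs are log-normal with the cell's mean and
  coefficient of variation (baseline 433 ms, CV 0.14); errors are
  Bernoulli per trial (baseline ≈ 0.45% of 800 trials); breath-counting
  accuracy is Gaussian between subjects (baseline 44.8 ± 32.7% vs
  53.4 ± 34.8%) with the same stable/session variance split. Time courses
  improve over sessions in both arms for errors and RTCV, and only in the
  MT arm for breath counting. Trial-level Gaussian-copula couplings link
  component amplitudes to RT (N1 +0.24, P3 −0.19 by default).

All generators are bit-reproducible under a fixed seed; stage seeds are
derived from the master seed with a fixed modular map, so stages can be
re-run independently.

## Preprocessing

The chain follows standard ERP practice: 1–40 Hz band-pass (4th-order
Butterworth applied forward–backward for zero net phase, with one
low-frequency-period reflection padding against edge transients), average
reference, artifact rejection, −200–0 ms baseline, crop to −200–600 ms and
trial averaging; the order is recorded in the processing log and echoed in
the report. Artifact rejection replaces the visual-plus-ICA screening used
on real recordings with a deterministic ±100 µV max-absolute threshold —
adequate for artifact-free synthetic data and, unlike visual inspection,
testable. Target ERPs average correct-response trials only (a `correct`
metadata flag), cue ERPs all artifact-free cue trials; this reading of
"correct trials" is configurable. All windows are closed intervals in ms
mapped to nearest samples (a window of length L s at sfreq Hz spans
round(L·sfreq) + 1 samples), fixed once to avoid off-by-one drift between
modules.

## Numerical choices

* **Zero-variance points.** A pointwise statistic with zero variance and a
  nonzero mean difference is set to a large finite sentinel (10⁹) with its
  sign preserved and the point counted in `n_degenerate`; with a zero mean
  difference it is 0. Constant synthetic inputs thus behave as maximal
  evidence where a difference truly exists and as no evidence where
  nothing does, without NaN/Inf arithmetic. The same convention applies to
  the behavioural t tests (identical inputs give t = 0, p = 1; zero spread
  with a real difference is an error).
* **Degeneracy tolerances.** Repeated-measures F and the split-plot ANOVA
  compare sums of squares against a relative tolerance (10⁻¹² and 10⁻¹⁰ of
  the total squared magnitude) before declaring a stratum degenerate, so
  floating-point dust in all-constant tables cannot masquerade as F ≈ 1.
* **Ties.** A permutation mass equal to the observed mass counts toward
  the p-value (conservative).
* **ANOVA effect size.** Partial η² is primary;
  d = 2·sqrt(η²/(1 − η²)) is emitted as a labelled convenience conversion
  only, since the mapping from a mixed-design F to a d is not unique.
  Sphericity correction is not applied by default (the classical
  split-plot F is reported); the fitted `aov` object is kept on the result
  for users who need corrections.
* **Outlier screen.** Percentiles use the type-7 linear-interpolation
  convention (R's default); values strictly outside the 5th–95th band are
  flagged, and with fewer than 10 values the screen warns and flags
  nothing.

## Problem sizes

The test suite and acceptance script run the simulations at sizes chosen
to finish in minutes on one CPU while keeping each check informative: the
family-wise error simulation uses 200 null datasets of 2 × 15 subjects,
16 channels and 150 samples at 500 randomizations; planted-effect recovery
uses 50 replicates of the full 50-subject MT arm at 32 channels, 20 trials
per cell and 1000 randomizations; null-uniformity checks use exhaustive
enumeration over 2⁸ sign flips. The engine itself has no scale
assumptions; `n_permutations = 5000` is the analysis default.

## Limitations

* No volume conduction or source model: topographies are circular weight
  maps, so spatial realism is limited to smooth, localised fields.
* No artifact simulation (ocular, cardiac, line noise, bad channels) and
  no ICA; the preprocessing chain is linear apart from trial rejection.
* The split-plot ANOVA is the classical fixed-effects decomposition, not
  a random-slope mixed model; unbalanced groups are handled, but missing
  sessions drop the whole subject from that ANOVA (with a logged count).
* Monte-carlo p-values inherit sampling error of order
  sqrt(p(1 − p)/B); exhaustive mode removes it but is capped at
  enumerations of 20 000 partitions.
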