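---
title: "Models and methods behind digdive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind digdive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digdive)
```

## The assay and its coordinate frame

A third-instar larva is confined to a vertical chamber: a 12 mm agarose
column, 3 mm wide, with a 2 mm air chamber above it. Its centroid is tracked
at 1 Hz for 15 min (900 samples). All modules share one spatial convention:
`z = 0` at the gel surface, positive up into the air chamber, negative down
into the gel. Durations are computed from timestamps, not frame counts, so
any uniform sampling rate works; tracking gaps carry an explicit missing
mask rather than sentinel values.

Behavior decomposes into elementary modes by depth alone: **surfacing**
(`0 < z <= air_top`), **digging** (`Z_diving < z <= 0`, the larva
"snorkeling" with spiracles at the interface), **diving** (`z <= Z_diving`,
apneic), and **escaping** (`z > air_top`, out of the arena).

## Threshold estimation from the depth distribution

The digging boundary is fixed at the gel surface; only the diving boundary
is estimated. Depths pooled across a cohort are smoothed with a
Gaussian-kernel density estimate and the grid is scanned downward from the
sample mean; the first local minimum is the boundary between the digging
bulk and the diving tail. Estimation is per cohort/species, not per trial:
single trials rarely contain enough diving frames to shape the tail.

Numerical choices that matter here:

- **Exact kernel sums.** The density is evaluated as the exact Gaussian
  kernel sum on the grid rather than by binned FFT approximation. The binned
  approximation carries ~1% pointwise error and sub-percent non-monotonic
  jitter — enough to create spurious "local minima" on perfectly unimodal
  data and to violate closed-form checks.
- **Bandwidth and grid.** Silverman's rule by default (an explicit bandwidth
  can be supplied), grid step 0.05 mm, grid span six bandwidths beyond the
  data range so the trapezoidal integral equals one to better than 1e-8.
- **Minimum qualification.** Even exact kernel estimates of unimodal data
  develop tiny dips between sparse extreme samples in the tail. A genuine
  mode boundary separates the bulk from a *populated* diving tail, so a
  candidate minimum qualifies only if at least `min_deep_mass` (default 1%)
  of the probability mass lies below it. Spurious tail dips sit below ~0.1%
  of the mass (roughly the mass beyond 3 sd); diving occupies percent-level
  time whenever the assay shows diving at all. When no minimum qualifies the
  function raises an explicit no-minimum condition — never a silent default —
  which is also the honest answer for conditions with essentially no diving
  (very soft gels, blocked spiracles).
- **Plateaus and ties.** A flat valley resolves to its shallow (larger `z`)
  edge; the scan is deterministic for a fixed grid.
- **Well-posedness.** The rule "first minimum below the mean" presumes the
  mean lies inside the dominant shallow mode. That holds for real depth
  distributions (digging dominates). For an exactly symmetric 50/50 mixture
  the mean coincides with the valley and the scan may start below it; the
  validation mixtures therefore use a dominant shallow mode.
- **Air-chamber pooling.** Whether surfacing samples (`z > 0`) belong in the
  mean used as the scan origin is a free choice; pooling everything is the
  default, `submerged_only = TRUE` restricts to the chamber interior. With
  pooling-all the mean sits slightly higher, which only moves the scan
  origin, not the valley.

## Classification, escapes, inactivity

Classification is a pure per-frame comparison against the two thresholds.
Missing frames inherit the previous label (a missing lead-in counts as
surfacing, where larvae are introduced). Two trial-level flags follow:

- **Escape.** A trial is escaped once a *contiguous* out-of-arena run
  exceeds 30 s. The run-length reading is the stricter of the two possible
  interpretations (contiguous vs cumulative); frames from the onset of the
  qualifying run are excluded from time-fraction denominators while the
  trial still counts as escaped.
- **Inactivity.** Drowned larvae freeze in place below the surface. The
  original procedure excluded such animals by visual inspection; here it is
  automated: if, while submerged, the centroid displacement within every
  rolling 120 s window stays below 0.2 mm through to the trial end, the
  trial is flagged and frames from the onset excluded. Both parameters are
  exposed; against simulated drowning ground truth the detector agrees on
  well over 95% of trials.

## Dive events and cohort metrics

Dive events are maximal runs of diving frames. An event's duration runs from
its first diving sample to the first non-diving sample (trial-final dives
close one sampling interval after their last frame), so event durations sum
exactly to total diving time. Maximum depth is the most negative `z` in the
run. "Dive speed" is not defined unambiguously in the field; the default is
the mean centroid *path* speed (`sqrt(dx^2+dz^2)/dt` averaged over the run)
with a vertical-only alternative behind a flag. Dives count from one full
sample below threshold; no minimum-duration filter is applied.

Sliding-window mode probabilities average a per-trial mode indicator over
active (non-excluded) trials, then smooth with a centred 1-min moving
average truncated at the edges (no padding); with the window equal to the
sampling interval the series is exactly the unsmoothed mean. Post-dive
surface intervals pair each dive with the surfacing + digging time before
the next dive; trial-final intervals are censored and dropped, which biases
the dive-vs-recovery correlation less than keeping truncated values.

## The statistical toolkit

- **Normality gating.** Lilliefors' test (KS distance to a normal with
  estimated parameters) with a Monte-Carlo p-value: parameters are
  re-estimated per null replicate, seed-controlled. Published tables are
  approximations; the Monte-Carlo null is exact up to simulation error. When
  both samples pass, comparisons use Student's t (equal variances);
  otherwise the Mann–Whitney rank-sum test.
- **Rank-sum branches.** Exact enumeration for `n_x + n_y <= 12` without
  ties; otherwise the midrank/tie-corrected normal approximation with
  continuity correction (which keeps the two branches within ~0.02 of each
  other at 6 vs 6 and returns p = 1 for identical samples).
- **Multiple groups.** Kruskal–Wallis, then all pairwise rank-sum tests with
  p-values multiplied by the number of pairs (capped at 1). The compact
  letter display assigns one letter per maximal clique of the
  "not-significantly-different" graph (Bron–Kerbosch enumeration), so two
  groups share a letter exactly when they are not distinguished.
- **Effect size and power.** Cohen's d uses the pooled sd by default (the
  control-group sd is available behind a flag). Power of the two-sided
  one-sample t-test comes from the noncentral t distribution
  (`ncp = (delta/sigma) * sqrt(n)`, `df = n - 1`); the minimal sample size
  is the smallest integer n whose power reaches the target. This
  reproduces the published planning values n0 = 34 for
  (mu 0.15, sigma 0.1, delta 0.05) and n0 = 6 for (0.5, 0.2, 0.3). Two other
  published planning anchors (n0 = 6 at d = 1 and n0 = 12 at d = 1) are
  mutually inconsistent under any single t convention and are not targeted.
  Sidedness is not stated in the source procedures; two-sided matches the
  retained anchors.

## The simulator: what it emulates and what it does not

The generator is a semi-Markov state model, not a per-frame Markov chain:
observed dive durations are long-tailed and species-dependent, so dwell
times carry explicit distributions (lognormal, for positivity and skew).

- Surfacing and digging alternate with lognormal dwells; within a dwell the
  larva station-keeps at a level drawn per dwell (truncated normal within
  the mode's depth band) with per-frame jitter re-drawn from the truncated
  normal, so no probability mass piles up at band edges.
- The per-trial dive count is drawn from a negative binomial matched to the
  condition's published mean ± sd (Poisson when no overdispersion is
  implied); start times are uniform over the trial. A dive descends at
  constant speed to a target depth drawn from a truncated normal on
  `(gel_bottom, Z_diving]` and ascends at the same speed — a triangular
  profile chosen because it makes the mean-speed metric exactly recoverable.
  The target is quantised onto the constant-speed stepping grid and the
  horizontal coordinate is frozen during dives, so with zero jitter the
  extracted mean dive speed equals the configured speed to 1e-6.
- Apnea beyond the aerobic limit exposes the larva to a per-second drowning
  hazard; a drowned larva freezes for the remainder of the trial
  (the inactivity detector's ground truth). An optional escape excursion
  lifts the centroid above the air chamber for a lognormal duration.
- Per-trial seeds derive from the root seed as
  `(seed * 48271 + i * 1009) mod (2^31 - 1) + 1`, so cohorts are
  order-independent and individually reproducible.

Preset conditions pin the dive-count means (and sds) to published cohort
anchors — 4.1 ± 3.2 dives/trial for wild-type *D. melanogaster* in 0.4%
agarose, 5.3 ± 2.5 with an attractive odor, 0.3 ± 0.6 with blocked
spiracles, 1.9 ± 1.5 and 1.0 ± 0.9 for *D. suzukii* intact/blocked — and
reproduce qualitative structure: roughly tenfold longer dives in
*D. suzukii* (deeper targets at ~5x slower speed), surfacing dominance with
drowning risk in very soft gels, and mostly-surfacing behavior on hard
gels. Dive speeds are otherwise unconstrained by published numbers; dwell
scales are chosen to give plausible mode balances (about 77% digging, 19%
surfacing, 4% diving in the baseline preset, pooled mean depth near
-2.2 mm). These are phenomenological targets, not fitted parameters, with
±20% documented tolerance.

What the simulator does **not** emulate: posture and peristalsis, odor
gradients (conditions differ only through preset parameters), multi-larva
interactions, and tracker-level nuisances such as reflections or
illumination drift. Passing closed-loop tests therefore validates the
pipeline's logic and calibration, not its robustness to real-video
artifacts.

## Renderer and tracker

Frames are 8-bit grayscale: chamber walls at a distinct intensity, the larva
a filled ellipse mapped through the pixel calibration, additive Gaussian
noise clipped to [0, 255]. The tracker subtracts a background, thresholds
the absolute difference (Otsu by default, fixed value as override), cleans
with morphological opening, labels connected components, and takes the
intensity-weighted centroid of the largest component of sufficient area
(ties: larger summed intensity, then nearer the frame top). Gaps up to 3 s
are linearly interpolated and flagged; longer gaps are masked missing —
keeping dive durations conservative.

The background model is the pixel-wise temporal median. Its premise is that
every pixel is larva-free most of the time. A station-keeping larva violates
this — it can occupy its dig-level pixels for most of a trial — in which
case the median retains the larva and tracking degrades. The closed-loop
validation therefore estimates the background from rendered empty-chamber
frames, mirroring the standard practice of acquiring an empty reference
before loading the animal; with that reference, centroid RMSE against
ground truth is well below one pixel at noise sd 3 and the error grows
monotonically with noise.

## Problem sizes used in validation

The test-suite and acceptance computations run at deliberately desk-scale
sizes: cohorts of 20–200 simulated trials, 200-frame rendered stacks,
10,000-sample mixtures over 20 seeds, 1000–2000 null simulations for test
calibration, and 1e5 Monte-Carlo replicates for the power cross-check.
These sizes keep every property estimate's simulation error well inside the
asserted tolerances.

## Known limitations

- Threshold estimation needs a populated diving tail; conditions with
  almost no diving correctly raise the no-minimum condition and must borrow
  a threshold from a baseline cohort (as done across conditions in
  practice).
- The inactivity detector assumes drowned larvae are *completely* still;
  residual passive drift beyond 0.2 mm per 2 min window would defeat it.
- The tracker is single-animal and centroid-only by design; posture-level
  behaviors (head casts, mouth-hook contractions) are out of scope, and
  contraction counts enter only as externally supplied numbers via the rate
  formula.
- Escape handling treats the 30 s rule as contiguous; a cumulative reading
  would flag slightly more trials.
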