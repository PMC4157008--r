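---
title: "Methods: time-domain peak detection with swarm-optimized rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-domain peak detection with swarm-optimized rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakswarm)
```

## The model

A sampled single-channel trace `x(I)`, `I = 0, …, L−1`, contains a small
number of expert-annotated transient peaks among thousands of incidental
local maxima. The detector factors into four stages.

**Candidates.** A candidate is a strict three-point local maximum with a
strict local minimum (valley) on each side; maxima lacking an interior
valley on either side are discarded. Strictness is taken literally:
plateaus never produce candidates. An optional jitter pre-pass
(`detect_candidates(jitter = TRUE)`, off by default) adds an infinitesimal
index-ordered ramp so that a plateau maximum resolves to its last sample;
it exists for quantized integer signals and is never used by the pipeline
itself.

**Landmarks and features.** For each candidate, eight landmarks are found:
the peak `pp`, valleys `vp1`/`vp2`, turning points `tp1`/`tp2` (walking
from the peak toward a valley, the endpoint of the first one-sample
segment whose slope magnitude drops by *more than* 50% relative to the
preceding segment; the valley itself if no segment qualifies), half points
`hp1`/`hp2` (first sample at or below the midpoint level between peak and
valley values; no sub-sample interpolation, so widths stay integers), and
the moving-average-curve value `MAC(pp)` (centered window mean, truncated
at the signal edges). Fourteen features follow: amplitudes
`f1 = |x(pp) − x(vp1)|`, `f2 = |x(pp) − x(vp2)|`, `f3`, `f4` (peak minus
turning points), `f5 = |x(pp) − MAC(pp)|`; widths `f6 = |vp1 − vp2|`,
`f7 = |pp − vp1|`, `f8 = |pp − vp2|`, `f9 = |tp1 − tp2|`,
`f10 = |hp1 − hp2|`; slopes `f11`–`f14`, the amplitude differences divided
by the corresponding index differences. All are absolute values, hence
non-negative, and the turning-point fallback keeps them defined for every
candidate; a slope whose denominator would be zero is defined as 0.

**Classifier.** A rule model is a feature mask plus per-feature decision
thresholds: a candidate is a peak iff `f_i ≥ th_i` for every selected `i`.
An empty mask accepts everything (vacuously true conjunction) — during
training such a model scores a true-non-peak rate of 0 and is eliminated.
Four published fixed masks are available: `dumpala` {f1, f6, f11, f12},
`acir` {f1, f2, f7, f8, f13, f14}, `liu` {f1…f4, f6, f9…f14} and `dingle`
{f5, f6, f11, f12}.

**Fitness.** With `TPR = tp/(tp+fn)` and `TNR = tn/(tn+fp)` (each 0 when
its denominator is 0), the training fitness is `Gmean = √(TPR·TNR)`. On a
candidate set where positives are outnumbered 50:1 this is the right
currency: accuracy would reward the trivial all-negative rule with 98%,
Gmean gives it 0.

## The optimizer

Each particle concatenates 14 binary mask dimensions with 14 continuous
threshold dimensions. Velocities follow
`v′ = ω v + c1 r1 (pbest − x) + c2 r2 (gbest − x)` with `c1 = c2 = 2`,
scalar `r1, r2 ~ U[0,1]` per particle per iteration (a per-dimension mode
exists), and ω decreased linearly from 0.9 to 0.4 over the run. Continuous
positions move additively and are clipped into their search ranges; binary
positions flip with probability `T(v′) = |tanh v′|` (the v-shaped
transfer; note `|tanh|` saturates to 1.0 in double precision near
`|v| ≈ 19`, which is why velocity clamping matters). Velocity clamps: 6
for binary dimensions; for continuous dimensions the classical setup
specifies none, so the package defaults to 20% of each range width —
without a clamp, a width threshold with range 781.25 overshoots
essentially forever.

Threshold search ranges are assigned by feature category — amplitudes
[0, 30], widths [0, 781.25], slopes [0, 24.16]. The historically printed
assignment indexes particle dimensions instead and splits the categories
mid-way (a slope threshold bounded at 781.25, a width at 24.16); it is
physically incoherent but reproducible via
`threshold_ranges(literal_table = TRUE)`.

Two update schedules are implemented. *Synchronous*: evaluate all
particles, refresh all pbest/gbest, then move all particles.
*Random-asynchronous* (RA-PSO): per iteration, draw `N` particle indices
uniformly **with replacement** (some particles move several times, some
not at all — this is the adopted reading of the deliberately loose
published description) and let each drawn particle evaluate, refresh the
shared gbest, and move immediately. Both spend identical budgets:
`(k_max + 1) · N` evaluations including one initial synchronous pass that
seeds pbest/gbest.

Numerical conventions: initial bits are equiprobable, thresholds uniform
in range, velocities zero; pbest/gbest scores start at 0, read as a
"nothing evaluated yet" sentinel that any genuine improvement replaces;
replacement is strictly-better-only, so ties keep the incumbent and seeded
runs are bit-reproducible. `gbest_history` is therefore non-decreasing by
construction, which the tests assert.

**Stagnation.** A conjunctive rule scores 0 unless at least one true peak
passes *every* selected threshold. A random width threshold (range
781.25, realistic widths below ~100 samples) or slope threshold rarely
lets any positive through, so a 30-particle initial population sometimes
contains no particle with positive fitness; the swarm then has no gradient
and can collapse onto an arbitrary incumbent. This is not an
implementation artifact — it is the same mechanism by which the
eleven-feature `liu` mask is reported to score zero percent — and it
shows up here as roughly one to two stagnant runs in ten at the
30 × 200 test budget. The acceptance criterion (≥ 8 of 10 seeds
succeeding for each algorithm) deliberately tolerates it.

## The synthetic world

The recording the method was originally demonstrated on (40 s at 256 Hz,
C4 electrode, 40 expert-annotated peaks, i.e. 10240 samples of which
10200 are non-peaks) was never deposited, so `generate_recording()`
emulates its specification rather than reproducing its physiology:

- background: a sum of eight random-phase sinusoids below 8 Hz with total
  amplitude ≤ 3 µV, plus white noise (σ = 0.3 µV);
- 40 planted transients (Gaussian or triangular), apex amplitudes
  20–32 µV, per-side half-widths log-uniform in 4–20 samples (left and
  right drawn independently, so morphologies range narrow-symmetric to
  broad-asymmetric), apices ≥ 120 samples apart and ≥ 320 samples from
  the edges;
- white noise is attenuated inside a transient's footprint (to 10% at the
  apex): without this, noise occasionally carves a spurious local maximum
  into a shoulder whose prominence rivals the apex;
- apex strictness is guaranteed: if residual noise still leaves the
  annotated sample a non-maximum (broad transients are nearly flat on
  top), the apex alone is lifted just above its neighbours by a small
  positive jitter. Neighbours are never lowered, so the repair cannot
  create high-prominence artifacts. Consequently every annotation is
  recovered by `detect_candidates()` and tolerance-0 labelling is exact;
- optionally, biphasic "decoy" artifacts: a small crest (1–2.5 µV)
  between two deep valleys (20–30 µV) at ±12–18 samples, all piecewise
  linear so every segment is steep enough that noise cannot carve
  intervening micro-valleys.

The decoys are the interesting design choice. A crest between deep
valleys has near-peak values of every valley-referenced feature — f1–f4,
the widths, the slopes — while staying close to the moving-average curve
(small f5). They exist so that `make_separable_fixture()` can plant a
ground-truth rule that is *uniquely* recoverable: the builder verifies
(a) the f5 distributions of positives and negatives separate with a
margin, and plants `θ` at the midpoint; (b) in each partition some
negative dominates the positives' componentwise minima on all thirteen
other features, so *no* f5-free conjunction can be perfect and any
perfect rule the swarm finds must include f5; (c) the planted
single-feature rule scores Gmean = 1 on the training half. If any gate
fails the recording is regenerated from a derived seed (bounded
attempts), and with `snr_knob` below ~1 the builder always refuses —
that knob rescales transient amplitudes to a multiple of the 99th
percentile of background-only candidate prominence, and the fixture
default is 8.

What a green parameter-recovery test does establish: both optimizer
variants can find a planted, identifiable rule from a realistic candidate
population at desk scale (30 particles × 200 iterations). What it does
not establish: performance on real eye-movement EEG (no physiology, no
artifacts, no filtering is modelled), or the published headline accuracy
numbers — whose confusion counts are internally inconsistent anyway (a
training half of 5120 samples cannot yield TN + FP = 5140), which is why
no attempt is made to reproduce them.

## Open design decisions, resolved

- **Gmean radical.** The source formula is printed as a bare product
  `TPR × TNR` while being *named* geometric mean, and neither variant
  reproduces the printed percentages from the printed counts. The package
  computes `√(TPR·TNR)`; `gmean(..., literal = TRUE)` gives the product.
  Both are monotone-equivalent as fitness.
- **f12's denominator.** Printed as `pp − vp1` — a duplicate of f11's and
  contradicting the feature's own description ("slope at the second half
  wave"). Corrected to `pp − vp2` by default; `literal_f12 = TRUE`
  reproduces the printed formula.
- **MAC window.** Unspecified at source; default 257 samples (≈ 1 s at
  256 Hz), odd, centered, boundary-truncated, configurable. One second is
  the natural EEG baseline scale.
- **Matching tolerance.** Annotations are matched to candidates exactly
  (tolerance 0) by default — the generator guarantees apex-exact
  annotations. Real annotations jitter, so a tolerance in samples is
  exposed; each annotation is consumed by at most one candidate (nearest
  peak index wins, earlier index breaks ties).
- **Indexing.** All stored indices are 0-based half-open (files
  included); only human-readable CLI output converts to 1-based. One
  conversion point, no off-by-one arithmetic in the math.
- **Split convention.** `split_recording` keeps `[0, boundary)` for
  training, re-bases test annotations to the test origin, and refuses
  empty partitions. Aggregates use the sample (n−1) standard deviation,
  treating the runs as a sample of the optimizer's behaviour.
- **Run seeding.** Experiment run *r* reseeds only the optimizer with
  `seed + r − 1`; feature extraction is deterministic, so reseeding it
  would be a no-op.

## Limitations

No multi-channel support, no preprocessing beyond what the generator
produces (the unspecified band-pass filter of the original recording is
out of scope), no probabilistic scores — the rule is a hard conjunction.
The optimizer inherits conjunctive-rule stagnation (above); at the
published full budget (30 × 1000) stagnation is rarer but not impossible.
Threshold upper bounds are taken as given; on signals whose feature scales
differ wildly from the 256 Hz microvolt world they encode, the search
ranges should be reconfigured via `swarm_config(ranges = ...)`.
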