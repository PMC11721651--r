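---
title: "Methods: gesture expressivity and electrodermal resonance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gesture expressivity and electrodermal resonance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them: what is computed, under which assumptions, which parameters
matter, what the synthetic generator does and does not emulate, and where
the design was genuinely open.

## The measurement model

### Gesture expressivity

A gesture's expressivity is scored on seven binary parameters and averaged
into the Gesture Expressivity Index (GEI), an equal-weight mean with exact
range {0/7, …, 7/7}. Four parameters are rater-coded from video (SZ, FO,
CV, SL) and one read off annotation descriptions (MA); the package consumes
these codings — it does not attempt kinematic coding from video. Two are
derived from the gesture-phase tier:

- **HO** — yes iff any phase segment is labeled `hold`.
- **ND** — yes iff the gesture's total *nucleus* duration strictly exceeds
  the arithmetic mean of total nucleus durations over the same story's
  gestures. "Nucleus duration" here sums only segments labeled `nucleus`;
  holds are excluded even though some traditions fold post-stroke holds
  into the nucleus. Folding them in would make ND partially a function of
  HO, undermining the working assumption that the seven features are
  roughly independent and equally weighted. A single-gesture story can
  never code ND yes (nothing strictly exceeds its own mean) — accepted as
  the cost of the strict inequality, which guarantees ND is not vacuously
  yes when all nuclei are equal.

Equal weighting is an assumption, not a finding: there is no established
weighting of expressivity features, and the index deliberately mixes
kinematic salience (SZ, FO, HO, ND), multimodal coarticulation (SL, MA) and
narrative embodiment (CV).

### Positional and contextual covariates

- **Relative position**: the i-th of n gestures (sorted by onset) gets
  (i−1)/(n−1), so every story spans [0, 1] regardless of gesture count.
  For n = 1 the formula is undefined; the package assigns the unbiased
  midpoint 0.5. Positions are invariant under uniform time shifts.
- **Co-quote flag**: a gesture is a quote gesture iff some quote's start
  lies within ±1.5 s of the gesture onset. The tolerance is symmetric
  because a "distance" between start times is naturally an absolute
  difference; the flag is onset-based, not overlap-based, because
  quote-accompanying gestures frequently anticipate or trail the speech
  they enact.
- **Sentiment**: each inter-pausal unit (IPU) carries word-level composite
  sentiment scores in [−1, 1] (any lexicon can populate them; the package
  treats the scores as given). An IPU's sentiment is the mean of its word
  scores; a gesture receives the score of the IPU with maximal temporal
  overlap, ties to the earlier IPU, and 0 (neutral) when no IPU overlaps —
  the natural value for gestures during silence.

### Specific EDA responses and resonance

Skin conductance is sampled at 4 Hz in μS (hardware range 0.01–100). For
each gesture and participant the response window is the half-open interval
[onset, offset + 1.5 s). Half-openness avoids double-counting boundary
samples between adjacent windows at 4 Hz; the 1.5 s pad is the analysis
constant absorbing typical 1–3 s response latency. Windows running past a
trace's end are truncated and flagged; fully uncovered windows are a
coverage error and the gesture lands in the exclusion log.

The window amplitude is the **maximal trough-to-peak rise**:
max over sample pairs i < j of `v[j] − v[i]`, floored at 0 (computed via a
running minimum, and checked in the tests against a brute-force pairwise
maximum). This is the conventional SCR amplitude reading and tolerates a
declining tonic baseline; the alternative last-minus-first reading was
rejected because it misses transient waves that rise and fall within the
window. A response is *specific* when the amplitude strictly exceeds
0.05 μS ("larger than" is a strict inequality: a rise of exactly 0.05 is
not specific). No smoothing or detrending is applied by default — none is
part of the analysis definition — and the amplitude is measured against the
within-window trough, not an external baseline.

A gesture *resonates* when at least 2 participants show specific responses
within that gesture's window. Concurrency is operationalized at window
level, not sample level, because resonance is defined per gesture. The
narrator counts toward the tally; whether the narrator must be among the
responders is not settled by the definition, so the inclusive rule is the
default and `require_narrator = TRUE` exposes the stricter one. With
`resonance_min = 1` the flag degenerates, by design, to "any specific
response" — useful as a sanity probe.

One caveat on monotonicity: adding an SCR to a window is guaranteed not to
lower the trough-to-peak amplitude only while the added component is
non-decreasing over the window (its rise phase). An SCR *decaying* through
the window can lower the measured rise of the pair that previously attained
the maximum. The property tests therefore assert monotonicity for
rise-phase additions, which is the physiologically relevant case for a
stimulus-aligned window.

## Inter-rater reliability

Percent agreement and the Holley–Guilford G index,
G = (agreements − disagreements)/N = 2·p_agree − 1, for two raters and
binary codes. G is used instead of Cohen's kappa because the codings are
heavily skewed toward "no", where kappa collapses. The algebraic identity
G = 2·p − 1 is enforced by a property test, and reported values are rounded
half-up to 2 d.p., matching reporting conventions (base R's round-half-even
would turn 0.885 into 0.88). Only the two-rater case is supported.

## The inference stages

### RQ1 — crescendo model

`G_expressivity ~ G_position_rel + (1 + G_position_rel | ID)` fitted by
REML for reporting, where `ID` is the narrator-by-recording grouping. When
the random-slope fit is singular (common at small group counts) the model
falls back to random intercepts and says so in the result. Significance is
a likelihood-ratio test between ML refits with and without the fixed
position term — identical random structure on both sides, so the df is the
parameter-count difference (1). The per-group random slopes give the
fraction of narrators with a positive position–expressivity association; it
is reported only when the slope model actually converged. A constant
response short-circuits to a degenerate result (slope 0, LRT p = 1,
pseudo-R² flagged undefined) rather than an optimizer failure.

The response is a bounded mean of binaries, so the Gaussian LMM is an
approximation; the type-I simulations in the test suite are the check that
this approximation does not distort the LRT at the sizes used.

### RQ2 — arousal model

Mixed logistic regression of the per-gesture, per-participant specific
indicator on GEI, with crossed random intercepts for participant and
recording (crossed rather than nested: participants can appear in several
recordings). Random slopes are not attempted — with the small numbers of
recordings typical here they produce singular fits. The LRT drops the fixed
GEI term. A single-class outcome is a fit error, not a silent degenerate
fit.

Conditional pseudo-R² for both models follows the Nakagawa decomposition:
fixed-effect variance from the linear predictor, random-effect variance as
the mean diagonal of ZΣZ′, residual variance σ² (Gaussian) or π²/3
(logit). It is implemented directly from that formula (a few lines of
linear algebra) and is exercised against its [0, 1] range and degenerate
cases in the tests.

### RQ3 — resonance forest

A randomForest classification forest, `ntree = 1500`, `mtry = 3`, over 13
predictors; unordered factors are split natively by subset membership, so
no one-hot encoding is needed. All stochastic fits take explicit seeds.

**Importance** is out-of-bag permutation importance: baseline OOB accuracy
minus the mean OOB accuracy over R permutations (default 10) of one
predictor's column, where OOB predictions are majority votes over the trees
in which an observation was out of bag (ties break to the majority class
"no" — deterministic, and conservative for a rare positive class). This is
"mean decrease in accuracy on removal" in its standard OOB form;
*conditional* importance in the strict party sense is out of scope, but
permutations can be stratified within levels of a declared covariate
(`within =`) to blunt confounding, and the output records which variant was
used. Permuting a constant column is exactly a no-op, which the tests use
as a null anchor.

**Fit metrics** are computed on OOB vote fractions: traditional
R² = 1 − SSE/SST against the 0/1 outcome (flagged undefined when SST = 0);
McFadden's R² = 1 − ℓ_model/ℓ_null with probabilities clipped to
[1e−6, 1 − 1e−6] to keep the Bernoulli log-likelihood finite; and an exact
one-tailed binomial test of the OOB correct count against the
majority-class rate. McFadden's R² on OOB probabilities can be *negative*
when the forest has no real signal — OOB probabilities are honest and can
be worse than the base rate — which is intended behavior, not a bug.

**ICE curves**: for one predictor, each record's predicted resonance
probability is traced over a grid (factor levels, or 20 equi-spaced points
over the observed numeric range) with all other fields held at observed
values. Evaluating a curve at the record's own value reproduces the direct
model prediction, and the column-wise mean of the curves is the
partial-dependence curve — both identities are asserted numerically in the
tests. Group-stratified means of the same curves give the stratified
partial dependence used to probe interactions (e.g. kinematic effects by
group size).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes — it
is the package's test bed, not a physiological simulator:

- **Corpus shape** (defaults): 9 recordings alternating dyads and triads and
  cycling mixed/all-female/all-male composition, ~6 stories per recording,
  4–40 gestures per story (a uniform draw with mean ≈ 22, matching the wide
  spread of real storytellings), one narrator per story rotating through
  the participants.
- **Gestures**: phase-structured (preparation, nucleus, optional hold,
  retraction) with durations drawn so that a typical gesture lasts ≈ 2.5–3 s.
  Component probabilities follow a logistic curve in relative position with
  slope `crescendo_slope` (default 0.2, which yields a GEI-per-position
  slope of roughly 0.03 — a subtle, realistically sized crescendo; recovery
  tests plant 2 for unambiguous signal). Base rates are loosely matched to
  observed marginal frequencies (HO ≈ 0.33, CV ≈ 0.06, MA ≈ 0.04,
  SL ≈ 0.02); SZ = 0.45 and FO = 0.35 are not published anywhere and were
  chosen once so that the median simulated GEI sits near 2/7, the published
  median. ND is *emergent*: nucleus log-durations get the same positional
  shift, and ND is then derived exactly as the analysis derives it.
- **EDA**: trace = tonic level (2 μS) + iid Gaussian noise + Bateman
  (difference-of-exponentials) kernels, peak-normalized so the drawn
  amplitude *is* the peak, with rise/decay constants 0.7 s / 3 s. The
  narrator responds to a gesture with probability
  logistic(−0.95 + 1.43·GEI) by default — intercept and slope taken from
  the fitted arousal model of the study this design follows, so the default
  response rate (~30%) is empirically anchored. Each recipient responds
  with probability `coupling` (default 0.3) *given* the narrator fired;
  `coupling_triad` lets triads couple differently for interaction probes.
  SCR latency is uniform in 1–3 s from gesture onset.
- **Noise calibration**: the default noise SD is 0.005 μS. At 4 Hz, iid
  noise of SD σ has a within-window trough-to-peak range of roughly 3.5–4σ,
  so σ must sit well below 0.05/4 ≈ 0.0125 μS for the specific-response
  criterion to mean anything; 0.005 models a smooth wrist-device trace
  whose quantization jitter is far below the response threshold.
- **Ground truth** records, per gesture × participant, whether an SCR was
  planted, its onset and amplitude, plus the realized GEI — the oracle for
  detection-recovery tests.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: tonic drift and slow baseline waves,
spontaneous (non-gesture-locked) SCRs, movement artifacts, autocorrelated
sensor noise, speech-gesture semantic coupling (sentiments are uniform
noise), inter-story dependence, and any genuine association between group
composition and physiology. A detector that is near-perfect here will be
substantially noisier on real traces; the recovery results validate the
*implementation*, not field sensitivity.

Latency interacts with the window: a 1.5 s pad cannot cover a 3 s latency
after a very short gesture, so a small fraction of planted late responses
is undetectable in principle. With the default gesture durations this loss
stays within the detection-recovery margin; it mirrors a real limitation of
the fixed-pad design rather than a simulator artifact.

## Numerical choices and conventions

- Times are seconds (float) internally, converted from the millisecond
  times of the file formats; round trips preserve boundaries at ms
  resolution. Windows and phase-overlap checks use a 1e−6 s tolerance.
- Reporting rounds half-up (`round_half_up()`); internal computation never
  rounds.
- The amplitude scan, G index, GEI and relative positions are exact
  arithmetic; the only iterative numerics are the lme4 optimizers, whose
  nested-model log-likelihood ordering is asserted to 1e−6 and whose LRT is
  checked for invariance under affine predictor rescaling to 1e−4.
- Seeds: every stochastic stage takes an explicit seed; the pipeline
  derives per-stage seeds deterministically from its master seed, and
  reruns are byte-identical.
- Problem sizes in the test suite were chosen to make each check sharp but
  cheap: sign-recovery uses 20 replicates of 40-story corpora with planted
  slopes of 2; type-I calibration uses 100 replicates of 12-story corpora
  with null effects, accepting rejection counts in the central 99% binomial
  band [0, 11] around the nominal 5%; detection recovery uses amplitudes
  ≥ 0.2 μS over ~500 gesture × participant windows; forest checks run at
  100–300 trees (the 1,500-tree default is a production setting, not a
  statistical necessity — OOB estimates stabilize far earlier).

## Known limitations

- The Gaussian LMM for a bounded GEI response, and the window-level
  concurrency notion, are faithful to the analysis design but are
  simplifications; alternatives (beta regression, sample-level peak
  alignment) would be different analyses.
- Only two raters are supported in the reliability module; multi-rater
  generalizations (Krippendorff's α) are out of scope, as is Cohen's kappa.
- The EAF reader implements a documented tier convention sufficient for
  round-tripping this package's data model; it is not a general ELAN
  toolkit (no reference annotations, controlled vocabularies, or symbolic
  subdivisions).
- Clock alignment between annotation time and device time is assumed
  perfect (a single shared clock per recording); no cross-modal
  synchronization is attempted.
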