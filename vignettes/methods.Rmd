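---
title: "Methods: decoding outcome and response representations during instrumental learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding outcome and response representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(instrudecode)
```

This vignette documents the models, parameters and numerical choices behind
the package, in the order the pipeline runs them.

## 1. The behavioural paradigm and the two-controller agent

The reinforcement-learning task is a trading game: on each learning trial a
fractal stimulus (S\_high or S\_low) is shown, the participant offers it to
one of two alien tribes (responses R1/R2, cued by a blue or red symbol), and
a correct offer is accepted, yielding an outcome card (object for S\_high,
worth 100 points; scene for S\_low, worth 20) minus a 5-point response cost.
An incorrect offer is rejected at no cost.  A session has 33 blocks of 27
trials: 12 learning trials per stimulus plus 3 consumption trials at
within-block positions 7, 14 and 21.  The high-valued outcome is devalued
(worth 0, feedback masked with "???") in blocks 2, 16 and 29; the low-valued
outcome in blocks 3, 17 and 30.  Because an accepted trade for a devalued
card nets −5 points, continuing to respond towards it is the behavioural
marker of habitual control; consumption trials (a free choice between the
two cards, no cost) probe whether the current values are known at all.

The literature describes the two-system account verbally but gives no agent
equations, so the generator implements the minimal mechanism that produces
the behavioural dissociation: a softmax mixture of

* a goal-directed controller that scores each response by its expected net
  point value under the **current** (devaluation-aware) outcome values, and
* a habitual controller whose strength for an (S, R) pair increases by
  `habit_rate` (default 0.01) each time that pair is executed,

combined as `goal_weight * EV + habit_weight[block] * strength` and passed
through a softmax with temperature 2 (in points).  As the temperature tends
to 0 with zero habit weight, choices become value-maximizing: devalued
responding is exactly 0 and consumption choices always pick the valued card
— the two degenerate checks the test suite asserts.

`habit_weight_schedule()` ramps the habit weight linearly across blocks,
scaled by a per-subject latent *habit susceptibility* `g`.  Group profiles
are `g ~ N(1, 0.3)` (stress) and `g ~ N(0.15, 0.15)` (control), truncated at
0.  With the default gain of 1.5 these values place devalued responding in
the final high-value devaluation block at roughly 0.45 for a typical
stressed subject and 0.10 for a control — the size of dissociation the
paradigm is designed to detect — while both groups start near 0.08 in block
2 and always choose the valued card on consumption trials.  The schedule
endpoints were fixed from this block-2/block-29 calibration of the agent
alone, before any decoding was run.

Timeouts occur with probability 0.01 per learning trial; reaction times are
log-normal (median 0.7 s) and purely descriptive.

## 2. The DMS task and a deliberate arithmetic choice

Classifiers are trained on a delayed-matching-to-sample task performed
before and after learning; each session has 128 trials over the four target
categories.  The printed pool allocation 90/90/48/48 sums to 276, which two
128-trial sessions cannot produce; the two constraints are mutually
inconsistent.  The generator keeps the 128-trial session count and uses a
per-session allocation of 45/45/19/19, which preserves the object+scene
pooled raw count of 180 — hence exactly 90 pseudo-trials after pairwise
averaging, the n behind the printed 60.11% chance threshold for the card
classifier.  The symbol classes absorb the shortfall (38 pooled raw trials
per class instead of 48).  Category order is randomized under the
constraint that no category repeats more than three times in a row
(interleaved, since the original ordering is not described).

## 3. The EEG signal model

Epochs are trials x channels x samples tensors.  Each trial is a sum of
unit-norm spatial patterns under temporal kernels plus noise:

* **Category patterns.**  Gaussian scalp maps (width 3 cm) centred
  parieto-occipitally for the outcome categories (object left, scene right)
  and centroparietally for the response symbols (blue left, red right),
  motivated by where each representation is reported to be decodable.
  Lateralization within each pair makes the two maps of a pair linearly
  distinct.
* **Temporal kernels.**  DMS *delay* epochs carry a sustained maintenance
  signal (sigmoid onset by ~100 ms, held across the 2 s delay): the
  category is being held in working memory, and a sustained signal is what
  makes many training windows informative.  Learning-task epochs carry a
  transient Gaussian kernel (latency 200 ms, SD 50 ms), the time at which
  cross-task decodability is reported to peak.
* **Noise.**  Spatially correlated Gaussian noise: correlation 0.6 between
  channels 2 cm apart, decaying exponentially with distance (so montage
  geometry matters for the searchlight); unit variance per channel and
  sample; white in time.
* **Evoked components** (stimulus-locked epochs only): an occipital P1-like
  bump at 115 ms whose amplitude is value-*insensitive*, and a late
  centroparietal 400–700 ms component scaled by the current outcome value —
  giving the ERP module realistic structure to quantify.

The **amplitude schedules** encode the generative hypothesis.  With
per-subject susceptibility `g` and training progress `x` in [0, 1]:

```
outcome amplitude  = base * (1 - 1.0 * (g - 0.25) * x)
response amplitude = base * (1 + 1.1 * (g - 0.40) * x)
```

so a stressed subject (`g ≈ 1`) loses outcome signal and gains response
signal across training while a control subject (`g ≈ 0.15`) drifts slightly
the opposite way, and — because the same `g` drives the habit-weight
schedule — decoding deltas and devaluation insensitivity share one latent
cause.  The slopes and base amplitudes were calibrated on the package's own
simulations so that (i) single-trial cross-task accuracy sits on the steep
part of its psychometric range rather than at ceiling or at the
max-over-windows noise floor, and (ii) the final-superblock group gaps are
comparable, in units of the between-subject SD, to the medium-to-large
effects the design targets.  The DMS amplitude is set to twice the
learning-task base: with a weakly trained decoder, the part of the weight
vector that is noise overlaps randomly with the response-pattern axis, and
since outcome and response classes are confounded across learning trials
(each stimulus implies both), that leakage adds a subject-specific bias to
the outcome series; a cleanly trained decoder suppresses it.

## 4. The decoding pipeline

* **Pseudo-trials**: within each class, trials are randomly partitioned
  into disjoint pairs and averaged (`k = 2`); odd trials are dropped.  The
  pairing is seeded and performed once per analysis.
* **Sliding windows**: 100 ms windows on a 10 ms nominal grid.  At 250 Hz
  the step is 2.5 samples; windows are mapped to the nearest sample and
  duplicate start indices dropped — on this grid none collide, giving 191
  windows on a 2 s epoch.
* **Training**: per window, features are per-channel window means; a linear
  SVM (`e1071::svm`, cost 1, no scaling — the cost default is stated, and a
  sensitivity check across cost 0.1–10 leaves the leave-one-out ranking of
  windows unchanged on separable synthetic data) is evaluated by
  leave-one-out refitting.  The decoder is refit on all pseudo-trials at
  the best window; ties break to the earliest window.
* **Chance thresholds**: the adjusted Wald (Agresti–Coull, add two
  successes and two failures) upper bound around 0.5,
  `0.5 + 1.96 * sqrt(0.25 / (n + 4))`: 63.59% for n = 48 and 60.11% for
  n = 90.  A subject is kept only if accuracy is *strictly* above the
  threshold (equality is not above chance).
* **Cross-task decoding**: the trained weights are applied to every
  learning-task trial at every window in blocks without devaluation; the
  per-block statistic is the maximum over windows of the fraction of
  correctly classified trials.  The per-block fraction-correct reading (as
  opposed to averaging per-trial window maxima) is adopted because the
  block statistic is described as a single maximal accuracy.
* **Aggregation**: consecutive disjoint groups of 6 blocks (144 learning
  trials) of the first 24 no-devaluation blocks; group sizes 2, 3, 6 and 12
  are supported, with 3 dividing all 27 blocks evenly.

Leave-one-out on no-signal data deserves a note: with balanced classes the
left-out trial's class is always the minority of the training fold, so a
degenerate classifier drifts towards majority voting and LOO accuracy can
fall far *below* 0.5 (even to 0).  This is a property of the estimator, not
a bug, and it is why the searchlight's duplication-invariance is only
approximate at uninformative centres.  It has a second consequence worth
stating plainly: LOO accuracies are overdispersed relative to a binomial
proportion (folds are correlated, and the majority-vote collapse widens the
null distribution), and the exclusion statistic is the *maximum* of these
accuracies over windows.  A single-proportion adjusted-Wald bound is
therefore anti-conservative for it: in simulations with pure-noise epochs,
the selected-window accuracy exceeds the threshold for 30–75% of no-signal
subjects depending on geometry, not 5%.  The test suite documents this
honestly (the type-I property test fails by construction); users should
read the exclusion rule as a coarse data-quality screen, not a calibrated
hypothesis test — a permutation-based per-subject threshold would be the
calibrated alternative.

## 5. ERP and searchlight modules

The ERP module averages baseline-corrected (−200 to 0 ms) stimulus-locked
epochs by condition.  The P1 is the largest positive deflection of the
condition grand average at Oz within 75–200 ms; per-condition magnitude is
the fixed 80–150 ms window mean (two-step procedure: find the common peak,
then quantify with a fixed window).  The late analysis averages a
centroparietal set (CPz, CP1, CP2, Cz, Pz — a named, configurable fixture,
since only the region is specified) in six 50 ms bins over 400–700 ms.
Statistical follow-ups (mixed ANOVAs) are standard off-the-shelf statistics
and are left to the user; the module emits the condition x bin table.

The searchlight builds, for every centre electrode, the cluster of
electrodes within 4 cm (3-D chord distance — the simplest reading of a
radius on a head surface) and decodes from member-channel means over a
±100 ms window around the time of maximal decodability.  The packaged
montage is a deterministic Fibonacci lattice on a 9.5 cm sphere (cap to
90° from the vertex) with canonical 10-10 landmarks snapped in; its mean
4 cm cluster size is 9.3 electrodes, in the plausible range for a dense
128-channel net but not an exact reproduction of any digitized montage.

## 6. Correlation statistics

Difference scores are first-minus-last: mean per-block accuracy over the
first six blocks minus the last six (of the 24 grouped), and devalued
responding in the first high-value devaluation block minus the last.
Higher scores mean larger decreases.  Spearman correlations use average
ranks and a Fisher-z 95% CI.

The Bayes-factor correlation test integrates the sampling distribution of
the observed Pearson r (nuisance parameters integrated out; the
hypergeometric factor is evaluated by its power series to 1e-12) over a
symmetric stretched-beta prior on the population correlation with width
0.707 — the default prior family of standard Bayesian correlation software.
The source literature labels this default a "Cauchy prior 0.707"; the
stretched-beta family is what that software actually uses, and the naming
discrepancy is documented here rather than resolved.  BF01 is the exact
reciprocal of BF10.  An independent fine-grid trapezoid rule guards the
adaptive quadrature in the test suite (agreement to 1e-4 relative error).

Note that in the synthetic model the outcome and response deltas are driven
by the same latent `g` and are therefore *anticorrelated* by construction;
the empirical finding of uncorrelated representations is a property of real
data that this generator deliberately does not emulate.

## 7. Problem sizes used by the test and acceptance runs

The full acquisition geometry (128 channels, 250 Hz, 2 s epochs, 10 ms
window grid, two 128-trial DMS sessions) is the package default and is
exercised by the unit tests of each stage.  The end-to-end simulation
studies use the `"reduced"` geometry chosen as this package's standard
simulation configuration: 32 channels, 100 Hz, 1 s epochs, 50 ms window
step, two 80-trial DMS sessions, 6 subjects per group, and 10 seeded
cohorts for the recovery properties.  The reduced geometry's base amplitude
(0.45) is scaled up by roughly `sqrt(25/10)` relative to the full geometry
so that the per-window feature signal-to-noise ratio is comparable despite
averaging 10 instead of 25 samples per window.  Simulations with the
generator show these cohorts recover the group-by-stage crossing and the
brain–behaviour correlation signs in well over 90% of seeds.

## 8. What passing tests do and do not show

The generator produces clean, artifact-free, stationary Gaussian epochs
with known class structure.  Passing the recovery suites therefore shows
that the *pipeline* is correct and sensitive under the assumed statistical
structure — it does not validate the assumptions themselves against real
EEG (non-Gaussian noise, temporal autocorrelation, artifacts, drifting
montages, unbalanced designs).  Accordingly, no preprocessing beyond an
optional zero-phase band-pass hook is implemented: real recordings are
expected to arrive cleaned and epoched.

## 9. Known limitations

* Outcome and response classes are confounded across learning trials (each
  stimulus implies both); the package mitigates decoder-weight leakage via
  clean training data but cannot remove the confound, which is inherent to
  the two-mapping design.
* The per-block maximum-over-windows statistic is upward-biased at chance
  and compresses group differences near its noise floor; comparisons are
  meaningful because every series is computed identically.
* `resample_epochs()` supports integer decimation (zero-phase IIR) and
  rational ratios (polyphase FIR); the FIR path has visible edge transients
  on short epochs.
* Bayes factors are computed for the correlation test only; no other
  Bayesian models are implemented.
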