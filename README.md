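# instrudecode

EEG-based decoding of outcome and response representations during
instrumental learning, with a full synthetic-study generator.

## The scientific problem

Instrumental behaviour is controlled by two systems: a *goal-directed*
system that learns stimulus–response–outcome (S-R-O) associations and is
sensitive to the current value of the outcome, and a *habitual* system that
learns bare S-R links and keeps responding even after the outcome has been
devalued.  Classical outcome-devaluation assays show *that* behaviour has
become habitual, but not *why*: is the outcome representation lost, or has
the response representation grown stronger?

Multivariate EEG decoding can separate the two.  Category classifiers
(linear SVMs) are trained on an independent delayed-matching-to-sample
(DMS) task to discriminate the image categories that serve as outcomes
(object vs scene cards) and response cues (blue vs red symbols) in a
reinforcement-learning task.  Applied cross-task to the learning-task
epochs, the classifiers read out, block by block:

* the **outcome representation** at stimulus onset and at response choice —
  a signature of goal-directed S-R-O processing, and
* the **response representation** at stimulus onset — a signature of S-R
  processing.

This package implements the complete pipeline for that design — and,
because no human data ship with it, a generative model that produces
behavioural sessions and EEG epochs with the statistical structure the
analysis assumes, so every stage is testable end to end.

## What is implemented

* **Task simulation** (`task_config()`, `agent_params()`,
  `generate_task_session()`): 33 blocks x 27 trials (12 learning trials per
  stimulus + 3 free-choice consumption trials at positions 7/14/21), with
  the high-valued outcome (100 points) devalued in blocks 2/16/29 and the
  low-valued outcome (20 points) in blocks 3/17/30; 5-point response cost
  on accepted trades; feedback masked in devaluation blocks.  The agent is
  a softmax mixture of a value-based controller and an incremental
  S-R habit controller.
* **EEG simulation** (`signal_model()`, `generate_epochs()`,
  `spherical_montage()`): category-specific spatial patterns
  (parieto-occipital for outcome categories, centroparietal for response
  symbols) under temporal kernels, spatially correlated noise, and optional
  evoked components (occipital P1, late value-scaled centroparietal wave).
* **Epoch container** (`epoch_set()`, `save_epochs()`/`load_epochs()`,
  `baseline_correct()`, `resample_epochs()`, `crop_epochs()`): trials x
  channels x samples with HDF5 serialization.
* **Decoding** (`make_pseudo_trials()`, `train_decoder()`,
  `chance_threshold()`, `exclude_below_chance()`, `decode_cross_task()`,
  `aggregate_blocks()`): pseudo-trial averaging (pairs), sliding-window
  (100 ms window, 10 ms step) leave-one-out linear-SVM training with
  best-window selection, adjusted-Wald (Agresti–Coull) chance thresholds

      threshold = 0.5 + 1.96 * sqrt(0.25 / (n + 4))

  (63.59% at n = 48, 60.11% at n = 90), cross-task per-block maximal
  accuracy, and six-block superblock aggregation (144 learning trials per
  superblock).
* **ERP summaries** (`compute_erp()`, `find_p1_peak()`, `window_mean()`,
  `late_bins()`): occipital P1 (peak 75–200 ms at Oz, fixed 80–150 ms
  quantification window) and six 50 ms centroparietal bins over 400–700 ms.
* **Searchlight** (`build_clusters()`, `searchlight_decode()`): 4 cm
  electrode neighbourhoods, leave-one-out accuracy per centre.
* **Statistics** (`devaluation_rates()`, `delta_scores()`,
  `spearman_corr()`, `bayes_corr()`, `effect_sizes()`): devaluation
  summaries, first-minus-last difference scores, Spearman correlations with
  Fisher-z CIs, and a Bayes-factor correlation test (stretched-beta prior,
  width 0.707, numerical quadrature).
* **Orchestration** (`study_settings()`, `simulate_subject()`,
  `decode_subject()`, `run_cohort()`, `run_pipeline()`): seeded end-to-end
  cohorts and a report bundle (CSV/JSON).

## Worked example

```r
library(instrudecode)

# one stressed subject, reduced simulation geometry (32 channels, 100 Hz)
subj <- simulate_subject("s01", "stress", seed = 11,
                         settings = study_settings("reduced"))
res <- decode_subject(subj, study_settings("reduced")$spec, seed = 42)
res$decoders$outcome
#> trained_decoder object vs scene: LOO accuracy 1.000 at 0.1 s (n = 48 pseudo-trials)
chance_threshold(48)
#> chance threshold: 63.59% (n = 48, z = 1.96)
```

A small two-group study, end to end:

```r
res <- run_cohort(n_per_group = 6, seed = 1, settings = study_settings("reduced"))
print(res)
#> cohort_result: 12 subjects (reduced geometry, seed 1)
#>   outcome_stimulus, final superblock: stress 0.694 vs control 0.760
#>   outcome_choice, final superblock: stress 0.688 vs control 0.766
#>   response_stimulus, final superblock: stress 0.839 vs control 0.757
#>   Spearman d_outcome vs d_devalued: -0.549; d_response vs d_devalued: 0.487
#>   BF01 (d_outcome vs d_response): 0.785
```

Read: at the end of training the stressed group's outcome decoding has
fallen below the control group's while its response decoding has risen
above — the neural signature of a shift from goal-directed to habitual
control — and the per-subject decline in outcome decoding correlates
negatively (response decoding positively) with the loss of behavioural
devaluation sensitivity.

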