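---
title: "Connectivity-pattern decoding of working-memory content: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-pattern decoding of working-memory content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmconn)
```

## The model

`wmconn` tests whether the identity of a stimulus held in working memory can
be read out from the *correlation structure* between cortical sub-regions,
rather than from their activation levels. The analysis unit is a **network**
of 2–4 regions of interest (ROIs), each tiled into subROIs (icosahedral
patches of the fsaverage3 mesh, `10 * 4^3 + 2 = 642` vertices per
hemisphere). For a network {A, B} and each (run, maintained-class) cell, the
feature vector is the N~A~ × N~B~ matrix of Pearson correlations between
every subROI pair, computed on residualized BOLD series inside
hemodynamically lagged maintenance windows and flattened row-major; for
larger networks the pair blocks are concatenated in canonical (sorted-name)
order, giving T = Σ~pairs~ N~A~N~B~ features. With 4 runs and 6 stimulus
classes this yields 24 exemplars per network and subject.

Decoding is a six-class linear support-vector machine (C-SVC, cost C = 1,
one-vs-one majority vote — the libsvm conventions) under leave-one-run-out
cross-validation: 18 training and 6 test exemplars per fold. Group-level
inference uses a **maximum-statistic permutation test**: class labels are
shuffled uniformly *within runs* (runs are the exchangeability blocks of a
run-wise cross-validated statistic), the same shuffled labels are applied to
every unit of the family within a subject — required for a valid family-wise
maximum — and each permutation contributes the maximum over units of the
group-mean accuracy. A unit's p-value is `max(1, #{max >= observed}) /
n_perm`, so ties count against the observation and the smallest attainable p
at 500 permutations is 0.002. The identity permutation is not excluded
(standard Monte-Carlo practice, negligible at these counts). Because label
permutations never alter the features, the null permutes labels of
precomputed exemplars; this is computationally equivalent to re-running the
feature extraction per permutation.

## Timing parameters

| parameter | default | meaning |
|---|---|---|
| `tr` | 1.47 s | repetition time; all windows snap to this grid |
| `lag` | 4.41 s | hemodynamic lag applied before sampling maintenance activity; must be an integer multiple of TR (here 3) |
| `highpass_hz` | 0.006 Hz | drift cutoff; per-run Legendre polynomial order = max(1, round(2·cutoff·run_length)) |
| `maintenance_dur` | 15 s | retro-cue to probe delay |
| `run_length` | 620 s | 24 trials × 25 s envelope + lead-in/out; the source study does not print its run duration, so this is a package default |
| HRF | double-gamma, peak 6 s, undershoot 16 s, ratio 1/6 | the canonical shape; the study does not state its HRF |

Maintenance windows are half-open `[anchor + lag, probe_onset + lag)` with
floored start and ceiled stop indices on the TR grid. Whether the published
analysis anchored at the retro-cue onset or at the nominal maintenance-period
onset is ambiguous; `window_anchor` exposes both, defaulting to the
retro-cue onset, which matches the synthetic generator's injection
convention so parameter recovery is well-posed.

The connectivity GLM regresses out the evoked responses of *all* task events
(alert cue, both items, retro-cue, probe, response cue), drifts and global
confound channels, but never the per-class content boxcars — those would
remove the signal of interest. The content boxcars (from 4 s after the
retro-cue to the probe) exist only in the activation path, where per-run
contrast effect sizes per class form the beta-feature exemplars.

## The stimulus side

Memory items are moving ripples `s(g,t) = D0 + D·cos[2π(ωt + Ωg) + ψ]`
synthesized as 20 log-spaced random-phase sinusoids per octave from 0.2 to
1.6 kHz. Each simulated listener has a just-noticeable difference (JND) in
log2 ripple velocity, estimated by a transformed up-down staircase. The
printed task rule, 1-down/2-up, converges at the 29.3 %-correct point
((1−p)² = ½), which is atypical for threshold tracking; the rule is a
configuration enum with the printed rule as default (with a warning) and
2-down/1-up (70.7 %) available for conventional use. The stimulus pool is 17
velocities spaced 0.5·JND in log2 units upward from 4 cycles/s (bounded to
3–48 cycles/s), with the six item classes every 1.5·JND, i.e. at pool grid
indices 0, 3, …, 15 — the grid start is a package choice; the source does
not state where in the pool the classes sit. Schedules satisfy: 24
trials/run, each class retro-cued 4× per run, retro-cue position balanced
within class (a package choice; not stated in the source), and probe types
50 % match / 25 % match-neither / 25 % irrelevant-match, with the irrelevant
item drawn from another class and offset half a JND.

## What the synthetic generator emulates — and what it does not

`simulate_session()` writes content into connectivity and nothing else. Each
subROI is "tuned" to class `(index - 1) mod 6 + 1` — a discretized
best-velocity topography. During each trial's lag-shifted maintenance
window, the subROIs tuned to the maintained class across the signal
network's ROIs share a latent Gaussian factor with loading √a against
residual √(1−a), so the implied correlation of a class-matched pair is
exactly the coupling a ∈ [0, 1] (a one-factor construction, hence always
positive semi-definite). On top sit HRF-convolved evoked responses with
random subROI loadings (amplitude 2), Legendre drifts (amplitude 3), two
smooth global confound channels (amplitude 1), and unit-variance white noise
(AR(1) optional). Amplitudes are class-exchangeable by construction, so
activation-based decoding of these data carries no content — a deliberate
dissociation that the test suite exploits.

What passing tests on these data show: the pipeline recovers planted
coupling, is calibrated at chance without it, and controls the family-wise
error of the maximum-statistic test. What they cannot show: robustness to
physiological noise, motion, inter-subject anatomical variability, or any
real hemodynamic nonlinearity — the generator has none of these.

## Numerical and design choices

- **Correlations** are computed over the class-concatenated segment as one
  series (trial joins included), literally following the concatenation
  convention; a per-trial alternative would be a sensitivity analysis, not
  the default. Raw r is used (no Fisher z — the classifier is
  order-preserving in the features and the source is silent). Zero-variance
  series yield r = 0 with a warning rather than NaN so degenerate cases stay
  decodable.
- **Flattening order** of the pair blocks is fixed (canonical member order,
  row-major); any fixed order is equivalent for margin classifiers.
- **SVM engines.** `loro_cv_decode()` fits e1071/libsvm on raw features by
  default. The permutation machinery uses an in-package dual solver on the
  precomputed 24 × 24 linear Gram matrix (the SVM dual depends on features
  only through inner products, and labels never change the Gram), with
  libsvm's rho and voting conventions; the suite verifies
  prediction-for-prediction agreement with libsvm across random instances,
  including permuted-label ones. Tie-breaks follow libsvm: one-vs-one votes,
  earliest class (training-appearance order) on ties.
- **No feature standardization** by default; optional z-scoring is fit on
  training folds only.
- **Seeds.** Every stochastic stage takes a seed; cohort members get
  independent child seeds from one master seed, and identical configuration
  plus seed reproduces every number bit-for-bit.
- **Desk-scale profile.** The default configuration runs 8 subjects, a
  50-network family and 99 permutations (~20 s on one core); the full 2500 ×
  500 analysis is the same code path with `n_networks = NULL, n_perm = 500`.
  Control families exclude networks sharing ≥ 2 ROIs with a planted signal
  network: such networks contain a genuinely coupled subROI pair, so
  excluding them makes "only the planted network should be flagged" a
  correct expectation rather than an approximation.

## Known limitations

The activation-86 label table is reconstructed from its published
construction rule (Desikan base, 9-way superior-temporal split, ventral/
dorsal pre-/post-central splits); individual labels that the construction
implies but the source does not name are marked `inferred` in the packaged
table, as are the precentral subROI counts (30/30) in the connectivity
registry. The generator's run length and trial envelope are package
defaults. Accuracy values quoted anywhere in this documentation are outputs
of the package's own test suite and acceptance script on synthetic data;
none are empirical claims about real recordings.
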