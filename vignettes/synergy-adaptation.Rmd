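---
title: "Methods: muscle-synergy extraction and adaptation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-synergy extraction and adaptation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A muscle activation pattern `M` (muscles × time bins, nonnegative) is
modeled as a linear combination of a small number of time-invariant muscle
synergies:

    M = c1 w1 + c2 w2 + ... + cn wn + e

where each `w_i` is a nonnegative weighting across muscles (a motor module),
`c_i(t)` is its nonnegative time-varying recruitment coefficient, and `e` is
residual noise. Estimation is by non-negative matrix factorization (NMF),
`M ≈ W C`, minimizing the squared Frobenius reconstruction error. The model
assumes spatially fixed modules within a condition — the synergy's muscle
balance does not change across the analyzed cycle — and leaves all temporal
structure to `C`.

The scientific questions the pipeline answers are about *reorganization*:
across adaptation stages of a perturbation-training session (a novel slip,
early adaptation, late adaptation), are the same modules recruited, do
several modules of one stage appear merged into one module of another
(equivalently: one module fractionates into several), and do modules keep
their temporal drive while shifting individual muscle weightings?

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| high-pass cutoff | 35 | Hz | removes motion artifact/baseline drift before rectification |
| low-pass cutoff | 40 | Hz | envelope smoothing; 2nd-order zero-phase Butterworth |
| bin duration | 30 | ms | time resolution without bin-to-bin EMG volatility |
| VAF thresholds | 0.75 / 0.90 | fraction | per-muscle and overall reconstruction criteria |
| major-contributor cutoff | 0.4 | unit-norm weight | conventional reading of "dominant muscle" |
| structural threshold | `critical_r(m−2, 0.01)` | r | 0.834 at 8 muscles; generalizes to other montages |
| activation screen | 0.3 | r | fixed conservative screen (critical value at df = 98 is 0.256) |
| NMF restarts | 20 | – | local-minimum control; best of restarts kept |
| NMF tolerance | 1e-6 | relative SSE change | checked every 10 iterations, cap 1000 |
| merge activity floor | 0.2 × max coef | – | suppresses numerically tiny NNLS activations |
| modification delta cutoff | 0.2 | unit-norm weight | half the major-contributor cutoff |

The structural threshold is computed from the degrees of freedom rather than
hard-coded: for vectors of length `m`, `r* = t*/sqrt(t*^2 + (m−2))` with
`t*` the two-tailed Student-t quantile at `alpha`. With 8 muscles this
reproduces 0.834 at `alpha = 0.01` exactly; the activation screen is kept at
the fixed 0.3 rather than its exact critical value (0.256 at df = 98)
because the fixed screen is the stricter, conventional choice. Both values
are reported by `classify_modes()`.

## What the generator emulates — and what it does not

`make_ground_truth_bank()` + `generate_cohort()` produce raw-like EMG whose
every downstream property is known:

* **Weights.** Each mode is a unit-norm nonnegative 8-vector with a sparse
  gamma background and one *signature muscle* it dominates. The signature
  structure mirrors real motor modules (a dorsiflexor-dominant module, a
  plantarflexor-dominant module, ...) and is what makes the planted mode
  count identifiable: a reconstruction missing one mode starves that mode's
  signature muscle, which the per-muscle VAF criterion detects. Pairwise
  mode correlations are additionally rejected above 0.7. A consequence is
  that at most `n_muscles` modes can be planted.
* **Activations.** Gaussian bursts in normalized gait time (default width
  0.10 of the cycle, centers spread over [0.12, 0.88] with slight jitter) —
  smooth, burst-like curves of the kind stance/swing muscles produce.
* **Raw signal.** The summed envelope (plus additive Gaussian noise,
  clipped at zero; default sd 0.05 of the unit burst amplitude) multiplies a
  unit-variance zero-mean Gaussian carrier, so the high-pass, rectification
  and smoothing stages operate on realistic broadband input. Rectification
  recovers the envelope scaled by `sqrt(2/pi)`, and the 35 Hz high-pass
  removes its share of the carrier's power; both factors are common to all
  muscles and cancel in every correlation-based comparison.
* **Cohort structure.** Per subject: three baseline trials (all modes at
  0.3 amplitude — these exist to give every muscle a positive normalization
  maximum), one novel trial, three early and three late trials. One
  multiplicative log-normal weight jitter (sd 0.1) per subject, shared by
  all of that subject's trials. Stage recipes can emit a mode as-is, merged
  (`recipe_merged`), or with per-muscle weight deltas (`recipe_modified`),
  planting the three reorganization mechanisms the detector looks for.

Not emulated: motor-unit firing statistics, signal-dependent noise,
crosstalk between channels, electrode lift or motion artifact, force or
kinematics. Passing tests on this generator therefore demonstrate that the
*estimation chain* is correct and well-calibrated under its own model
assumptions; they cannot certify performance on real EMG, where the envelope
model and the spatial fixity assumption are approximations.

A practical note on scales: baseline-max normalization (deliberately, as in
real protocols) rescales each muscle by its own baseline amplitude, so
extracted weights live in normalized units. When scoring recovery against
the generative truth, `synergy_weights(fit, "raw")` undoes that known
rescaling first; comparisons between normalized weights and raw-unit truth
would conflate measurement scaling with estimation error.

## Numerical choices

* **Filters.** The high-pass is a 4th-order Butterworth, the low-pass
  2nd-order, both applied forward-and-backward (`signal::filtfilt`) for zero
  phase so gait events stay aligned. Filter family and order for the
  high-pass are a design choice (standard EMG practice); only the cutoffs
  are scientifically constrained. Negative excursions after smoothing are
  clipped to zero (NMF requires nonnegativity).
* **Binning.** Non-overlapping 30 ms windows; a trailing partial window is
  averaged over its available samples rather than dropped (conserves the
  segment tail; `drop_partial = TRUE` switches this off). Binning conserves
  the count-weighted segment mean exactly.
* **Normalization.** Rows are divided by the baseline maximum of the
  *conditioned* envelope (the baseline maxima could also be taken on raw
  rectified signals; conditioned envelopes were chosen so that baseline and
  stage data pass through the identical chain), then by the row's sample
  standard deviation (n−1 denominator). Both divisors are stored and the
  unit-variance scale is removed from `W` after extraction.
* **NMF.** Lee–Seung multiplicative updates; 20 random nonnegative
  initializations per candidate `k`; convergence when the relative SSE
  change over 10 iterations falls below 1e-6, cap 1000 iterations. `W`
  columns are unit-normalized with the scale absorbed into `C`. The
  candidate range is `k = 1 ... number of muscles`.
* **VAF.** Uncentered sums of squares (`1 − Σ(M−WC)²/ΣM²`), the dominant
  convention in the synergy literature; the centered variant is available
  via `centered = TRUE`. Selection takes the smallest `k` satisfying both
  criteria; if none does, `k_max` is returned with `criteria_met = FALSE`
  rather than silently passing. Identical settings are used for the
  single-trial novel stage and the concatenated adaptation stages.
* **Clustering.** Distance `1 − Pearson r` between unit-norm weight
  vectors with average linkage (robust for correlation distances; Ward on
  Euclidean available via `distance = "euclidean"`). The tree is cut at the
  smallest cluster count whose partition has no within-cluster subject
  duplicate; ascending the same tree makes the first satisfying count
  unique. Cluster mean activations average each member's across-trial mean
  curve; since the uniqueness rule admits at most one synergy per subject
  per cluster, per-subject and per-member averaging coincide.
* **Matching.** Greedy one-to-one matching in descending `r` above the
  structural threshold (exhaustive optimal assignment available via
  `method = "optimal"`; the two are compared in the test suite). The
  three-stage mode registry chains pairwise matches by connected components.
* **Merging.** NNLS (Lawson–Hanson, via `pracma::lsqnonneg`) of an
  unmatched cluster mean against the other stage's cluster means; a merge
  verdict needs reconstruction `r` above the structural threshold *and* at
  least two coefficients within a factor 5 of the largest. The acceptance
  threshold for "similar to the combination" reuses the structural critical
  r — the least arbitrary choice, since no separate criterion is
  conventional. Modification candidates are all cross-stage pairs failing
  structural matching (not only unmatched clusters), screened by the
  activation threshold.
* **Cross-validation.** Sampling without replacement, a fresh independent
  draw per repetition, per-repetition seeds derived from one master seed.
  Existing per-subject synergies are re-clustered rather than re-extracted
  (re-extraction changes nothing at the weight level the clusters operate
  on, and would multiply runtime by the repetition count).
* **Determinism.** All randomness flows through explicitly passed seeds
  (R's default Mersenne-Twister); internal seeding never disturbs the
  caller's RNG state. Derived seeds stay below 2^31.

## Validation design

The test suite and `scripts/acceptance.R` validate the chain at these
problem sizes, chosen to exercise every stage while keeping a full run in
minutes: 50 independent single-subject runs with 4 planted modes and
envelope noise sd 0.05 for order-selection and structure recovery (scored on
the raw scale after greedy matching); a 30-subject, 7-mode pool for the
subject-uniqueness cluster rule; a planted `0.6 w1 + 0.4 w2` merge with a
200-draw Monte-Carlo null for the NNLS detector; brute-force oracles
(elementwise VAF, exhaustive active-set NNLS) for numerical agreement; and a
4-subject, 3-mode demo pipeline run twice for byte-level determinism.

One measured property deserves note: with the df = 6 threshold and a 4-mode
basis, random synergy vectors drawn from the generator's own distribution
are rejected as merges at roughly 90 %, not more — occasionally a random
8-muscle vector genuinely is well reconstructed by a nonnegative
combination of two basis modes. Merge verdicts on small montages should
therefore be read as evidence, not proof; corroboration by the activation
curves and by consistency across stage pairs is advisable.

## Known limitations

* Eight muscles bound the detectable synergy count from above, and the
  df = 6 structural threshold is correspondingly permissive about chance
  similarity (see the null-rejection note above).
* The dual-VAF rule is sensitive to near-threshold reconstructions: a bank
  whose weakest mode contributes marginal per-muscle variance can sit on
  either side of the 75 % bar. The generator's signature-muscle constraint
  exists precisely to keep planted truths away from that boundary.
* Uncentered VAF rewards reconstructing a muscle's mean level; muscles with
  little modulation are therefore easy to "explain" and contribute weak
  selection signal.
* Greedy matching can differ from optimal assignment when several
  cross-stage correlations are nearly tied; the `method = "optimal"` flag
  exists to check this on real analyses.
* The pipeline treats stages independently up to matching; it does not
  model within-stage trial-to-trial adaptation.
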