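---
title: "Predicting pain-related learning from resting-state connectomes: models, assumptions, and design choices"
author: "paincpm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pain-related learning from resting-state connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paincpm)
```

## The scientific problem

Individual differences in how strongly people learn to associate cues with
pain are clinically meaningful: maladaptive pain-related learning is a
candidate driver of pain chronification. `paincpm` implements a
registered-model workflow for building and *externally validating* a
predictive biomarker of this trait from resting-state functional
connectivity: a model is discovered on one cohort, frozen down to every
constant, and then applied — without any refitting — to independent
cohorts, yielding unbiased effect-size estimates.

The behavioral target is the **differential valence change** (DVC) from a
differential conditioning paradigm: participants rate the unpleasantness
of a cue paired with pain (CS+) and of a never-reinforced safety cue
(CS-) on a 0-100 visual-analogue scale, once during habituation and
again at the end of acquisition,

$$\mathrm{DVC} = (CS^{+}_{acq} - CS^{+}_{hab}) - (CS^{-}_{acq} - CS^{-}_{hab}).$$

Positive values mean the reinforced cue became more unpleasant than the
safety cue — i.e. learning occurred. The score is invariant to rating
shifts shared by all four cells. One validation cohort rates on a scale
with different verbal anchors; `harmonize_scale()` maps it onto the
reference anchors by `value/2 + 50`, applied **only** when a cohort is
explicitly flagged, never auto-detected: silent rescaling is a
correctness hazard.

## From timeseries to features

Inputs are preprocessed region timeseries (T timepoints x M regions; at
study scale, 122 atlas regions plus the global gray-matter signal,
M = 123). Per subject the pipeline standardizes each region signal,
estimates the M x M **partial-correlation** matrix, and vectorizes its
strict upper triangle in row-major order into an edge vector of length
$M(M-1)/2$ (7503 for M = 123). Partial correlations are computed from
the precision matrix $P$ as $-P_{ij}/\sqrt{P_{ii}P_{jj}}$, i.e. the
association of two regions with all other regions held fixed.

With T comparable to M the sample covariance is ill-conditioned, so by
default the covariance is shrunk toward a scaled identity with an
analytic (Ledoit-Wolf) data-driven intensity before inversion
(`shrinkage = "auto"`). `shrinkage = "none"` inverts the raw covariance
and refuses singular inputs; a fixed numeric intensity is also accepted.
Because the estimator used in the original analyses of this kind is
typically unreported, exact numerical agreement with any particular
deposited matrix is not promised — the choice is explicit and
configurable, and tests pin the estimator to a residual-regression
oracle.

Scrubbed (high-motion) frames are assumed removed upstream; rows are
treated as exchangeable samples, with no temporal modelling. Subjects
with mean framewise displacement above 0.15 mm or more than 25% of
volumes scrubbed are excluded by `qc_exclude()` (both limits
configurable, including "no exclusion").

## Model discovery

Discovery combines k-best univariate edge selection (absolute Pearson
correlation with the target; ties break toward the lower edge index)
with ridge regression (unpenalized intercept) under **nested
leave-one-participant-out (LOPO) cross-validation**: the inner loop
picks $(k, \alpha)$ by held-out mean squared error, the outer loop
estimates internal performance, and the final model refits on the full
discovery sample with hyperparameters chosen by the same inner criterion.
Selection, centering, and fitting are all recomputed inside every
training partition, so held-out subjects cannot leak into their fold's
model (a property the test suite checks directly by corrupting held-out
rows).

Defaults: $k \in \{5, 10, 25, 50, 100\}$ and
$\alpha \in \{0.001, 0.01, 0.1, 1, 10\}$; ties prefer smaller $k$, then
larger $\alpha$ (parsimony, stability). Significance of the internal
estimate comes from a permutation test that shuffles the target and
reruns the *entire* nested procedure per permutation, with
$p = (1 + \#\{r_{null} \ge r_{obs}\})/(B + 1)$.

**Feature scaling.** Edge features are centered with training-partition
means but *not* divided by their standard deviations by default
(`scale_features = FALSE`). Partial correlations already share the
common scale $[-1, 1]$; per-feature scaling inflates near-constant,
uninformative edges to unit variance and measurably halves externally
validated correlations on synthetic cohorts (true edges vary across
subjects; null edges carry only estimation noise). The scaled variant
remains available for data whose features lack a common scale.

The final model is serialized as a JSON **frozen model** — edge indices
(0-based, under a versioned ordering tag), weights, intercept,
hyperparameters, and centering constants — at 17 significant digits, so
a freeze/load round trip reproduces predictions bit-exactly, and a model
can never be silently applied to edges laid out under a different
convention.

## External validation

`predict.frozen_model()` is a pure linear form; no parameter adapts to
the new cohort. `evaluate_predictions()` reports, per cohort and pooled:
Pearson r with a one-tailed p (t-transform, $n - 2$ df; an
observed-positive-association alternative is the registered question),
a percentile-bootstrap 90% CI for r (5000 resamples by default; the
construction is labelled because other CI constructions exist),
explained variance both as $r^2$ (the convention behind "percent
variance explained" for correlation-scale effects) and as the
coefficient of determination $1 - SS_{res}/SS_{tot}$ (which additionally
punishes miscalibration), RMSE in rating units, and the observed range.

## Validity and confounders

Marginal correlations between model predictions and a third variable are
misleading whenever that variable is itself correlated with the target.
The package therefore tests **conditional independence**: is the
prediction associated with a validator/confounder *beyond* what the
shared association with the target explains? The statistic is the
absolute partial correlation of prediction and validator given the
target; the null distribution comes from conditional permutations of the
validator that preserve its dependence on the target.

Two permutation schemes are provided; both are certified by the
calibration suite:

* `"bins"` (default, assumption-light): subjects are ranked by the
  target and cut into $\lfloor\sqrt{n}\rfloor$ nearly equal strata
  (strata under 3 subjects merge with a neighbor); the validator is
  permuted within strata.
* `"residual"` (model-based): a spline regression of the validator on
  the target is fitted, residuals are permuted and fitted values added
  back.

No multiplicity correction is applied across a battery by default —
each validator answers a separate substantive question — but
Benjamini-Hochberg adjustment is one flag away. Rejection means the
model *generalizes* to a convergent validator, or is *biased* by a
confounder; the test detects bias, it does not remove it.

## Exclusion-loss importance

Model coefficients of small-sample sparse models are notoriously
unstable, so importance is measured behaviorally: remove one edge (LOFO)
or all edges incident to one region (LORO) from the candidate space,
rerun the *complete* discovery procedure including hyperparameter
search, and record the drop in externally validated explained variance,
in percentage points. Losses can legitimately be negative (a truncated
model may generalize better), losses are not additive across features,
and an edge the deterministic pipeline never selects has a loss of
exactly 0. The default significance flag uses a fixed 5.8
percentage-point threshold (a published operating point for single
connections); because its derivation is not specified anywhere usable,
it is a configurable constant, and a permutation-style alternative —
compare against losses from excluding random non-model edges — is the
recommended cohort-specific null. A fast mode that keeps $(k, \alpha)$
fixed exists for exploration and is labelled as such.

## The synthetic-cohort generator

Every stage above is testable without imaging data. `generate_cohort()`
draws multi-subject Gaussian timeseries whose **precision-domain**
structure carries the signal: a shared base precision matrix (identity
plus small random symmetric off-diagonals, diagonally loaded to
guarantee positive definiteness) receives per-subject perturbations of K
designated "true" edges; those latent strengths drive the behavioral
target linearly. Injecting signal in the precision domain makes partial
correlation — the pipeline's feature — the natural readout. The
generator exports full ground truth (true edges, latent strengths,
weights, noise), and the target is reconstructible from it to machine
precision.

Key parameters and their fixed study-scale values:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 25 / 26 / 23 | analyzed (post-QC) cohort sizes |
| `n_nodes` | 123 | 122 regions + global gray-matter signal |
| `n_timepoints` | 260 (192 for cohort 3) | resting-state volumes |
| `true_edges` | 5 | edges truly coupled to the target |
| `coupling_sd` | 0.25 | across-subject SD of true-edge precision perturbations |
| `effect_size` | 0.5 | fraction of target variance carried by the edges |
| `noise_sd` | 16 | residual target SD (rating units) |
| `intercept` | 25 | mean DVC (rating units) |

`noise_sd = 16` with `effect_size = 0.5` gives a total DVC standard
deviation near 23 and a group mean near 25 — the scale of group-level
learning effects and their dispersion in conditioning studies of this
kind. Latent edge strengths are independent across edges and subjects;
generative weights are random signs of equal magnitude so each true edge
carries an equal share of signal. Motion summaries emulate an analyzed,
motion-passing population (the cohort sizes are post-exclusion by
definition); a separate confound channel with controllable correlation
to the target provides the confounder stress test.
`make_study_replica()` packages three cohorts from one shared generative
template, with the third cohort's ratings stored on the alternate anchor
scheme so harmonization is exercised end to end.

**What the generator does not emulate:** hemodynamic and scanner noise
spectra, temporal autocorrelation, motion artifacts at the image level,
site effects, non-Gaussian rating distributions, and — importantly —
any concentration of signal into strongly detectable individual edges.
Passing recovery tests on synthetic cohorts therefore demonstrates that
the *procedure* is correct and calibrated, not that any particular real
dataset contains recoverable signal.

## Problem sizes, numerical choices, and known limitations

Tests and calibration simulations run at reduced scale, chosen so each
suite completes in minutes while retaining the statistical structure of
the full problem: recovery and importance scenarios use M = 20 nodes
(190 edges) with n = 30 discovery / 50 validation subjects; permutation
calibration uses 100 null cohorts at M = 10, n = 20 with B = 99 and a
reduced grid (k in {5, 10}, alpha in {0.01, 0.1, 1}) — type-I error of a
permutation test does not depend on the grid; conditional-test
calibration uses 200 datasets at n = 50 with B = 199. The study replica
itself runs at full scale (M = 123, 7503 edges).

Numerical conventions worth knowing:

* Ridge systems solve $(Z^\top Z + \alpha I)w = Z^\top y$ via Cholesky
  with a pseudoinverse fallback for singular unpenalized systems; the
  standalone `fit_ridge()` uses QR on the $\sqrt{\alpha}$-augmented
  design. Both are tested against the normal-equations closed form.
* Univariate-score ties break toward the lower edge index; hyperparameter
  ties prefer smaller k, then larger alpha. All tie-breaks are
  deterministic, which is what makes "exclusion loss of an unselected
  edge is exactly zero" a theorem rather than an approximation.
* Constant features score zero and are never selected ahead of any
  informative feature; constant targets are an error, not a warning.
* Bootstrap CIs are percentile-method; all resampling sits behind a
  single integer seed and the caller's RNG state is always restored.

Limitations. At full study scale (7503 candidate edges, 25 discovery
subjects) a signal spread evenly over 5 edges at `effect_size = 0.5`
leaves each edge's univariate correlation (~0.3) below the selection
noise floor, so the study-scale replica typically shows the classic
small-sample pattern: a plausible internal estimate with weak external
validation. The desk-scale scenarios (M = 20), where the same share of
signal is spread over 3 of 190 edges, recover planted edges and validate
externally at r ~ 0.5. This gap is a faithful property of
whole-connectome discovery at n = 25, not an artifact of the
implementation; real datasets in which such models validate externally
presumably concentrate more predictable signal than the deliberately
conservative generator defaults do. The conditional-independence test is
approximately, not exactly, calibrated at small n (binned permutations
discretize the conditioning); its operating characteristics are
certified by simulation in the test suite rather than assumed.
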