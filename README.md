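# paincpm — connectome-based predictive modelling of pain-related learning

`paincpm` builds, freezes, and *externally validates* sparse linear models
that predict individual differences in pain-related associative learning
from resting-state functional connectomes, following a registered-model
design: every preprocessing constant, selected feature, and weight is
fixed before the model ever sees validation data, so external performance
estimates are unbiased.

It is aimed at researchers in pain neuroscience and biomarker development
who have (a) preprocessed region timeseries and motion summaries, and
(b) conditioning ratings — or who want to study the statistical behavior
of this class of pipelines on fully synthetic cohorts with known ground
truth.

## The model

The behavioral target is the differential valence change

    DVC = (CS+_acq − CS+_hab) − (CS−_acq − CS−_hab),

the degree to which a pain-predicting cue became more unpleasant over
acquisition relative to a safety cue (0–100 rating scale; positive =
learning). Features are partial correlations between M brain regions
(entry `−P_ij / sqrt(P_ii P_jj)` of the — optionally Ledoit–Wolf
shrunk — precision matrix P), vectorized as the strict upper triangle in
row-major order: M = 123 nodes (122 atlas regions + global gray-matter
signal) give 7503 edges. Discovery combines k-best univariate edge
selection with ridge regression,

    min_w ||y − Zw − b||² + α ||w||²,

under nested leave-one-participant-out cross-validation (the inner loop
picks (k, α) by held-out MSE; the outer loop estimates internal
performance; a permutation test reruns the whole nested procedure per
shuffle). The frozen model is applied to external cohorts without any
refitting; validity and confounding are probed with a
conditional-permutation independence test (is the prediction associated
with a third variable *given* its association with the target?), and
predictive importance is measured as *exclusion loss* — the drop in
externally validated explained variance after removing one edge (LOFO)
or one region's edges (LORO) and rerunning the entire discovery
procedure.

## Worked example

A full discovery → freeze → external-validation → confounder-check run
on synthetic cohorts with three planted edges (M = 20 nodes, 190 edges):

```r
library(paincpm)
spec <- cohort_spec(n_subjects = 30, n_nodes = 20, n_timepoints = 260,
                    true_edges = 3, effect_size = 0.5, seed = 105, label = "disc")
tpl  <- cohort_template(spec)        # shared generative ground truth
disc <- generate_cohort(spec, tpl)
val  <- generate_cohort(cohort_spec(n_subjects = 50, n_nodes = 20,
                        n_timepoints = 260, true_edges = 3, effect_size = 0.5,
                        seed = 5105, label = "val"), tpl)

X_disc <- cohort_edge_matrix(disc)               # standardize + pcor + vectorize
y_disc <- score_cohort_behavior(disc)$value      # ratings -> DVC
fit <- nested_cv_discover(X_disc, y_disc)
print(fit$model)
#> Frozen model (dvc): 10 edges, alpha = 0.01, intercept = 25.321
#>   nodes: 20 | ordering: utri-rowmajor-0based/v1

metrics <- evaluate_predictions(predict(fit$model, cohort_edge_matrix(val)),
                                score_cohort_behavior(val)$value, seed = 2)
metrics[, c("n", "r", "p_one_tailed", "ci_lo", "ci_hi", "r_squared", "rmse")]
#>    n     r p_one_tailed ci_lo ci_hi r_squared rmse
#> 1 50 0.479      0.00022 0.277 0.641     0.229 22.3
```

The frozen 10-edge model includes two of the three planted edges and
explains ~23% of variance in the held-out cohort (r = 0.48, one-tailed
p = 2.2e-4, bootstrap 90% CI [0.28, 0.64], RMSE in rating units). A
confounder check against in-scanner motion:

```r
pgt <- partial_generalization_test(score_cohort_behavior(val)$value,
         predict(fit$model, cohort_edge_matrix(val)),
         val$covariates$mean_fd, B = 999, seed = 3, validator_name = "mean_fd")
print(pgt)
#> Conditional independence test for 'mean_fd' (scheme: bins, B = 999)
#>   R2 target~validator:       3.6%
#>   R2 prediction~validator:   0.0%
#>   R2 target~prediction:     22.9%
#>   p (conditional):         0.443
```

p = 0.44: no evidence that predictions are biased by head motion beyond
what the motion–target association alone would produce.

Models freeze to versioned JSON (`freeze_model()` / `load_model()`) and
reload bit-exactly; `lofo()` / `loro()` + `importance_table()` produce
the exclusion-loss importance report.

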