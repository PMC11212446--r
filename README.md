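# noisytab

Noise-robust training for tabular clinical classifiers.

Diagnostic labels in electronic health records are imperfect: when the
reference test misses cases (PCR-style sensitivity of 80–90%, near-perfect
specificity), training labels carry *asymmetric, class-conditional noise* —
many false negatives among true cases, few false positives among controls —
and a classifier trained with plain cross-entropy gradually memorizes the
wrong labels. `noisytab` implements three mitigation methods ported from
computer vision on top of a fully connected sigmoid-output network, plus
everything needed to study them under controlled corruption:

- **Label smoothing** — targets `1 − ε` / `ε/(C−1)` instead of one-hot;
- **Mix-up** — per-batch convex combinations
  `x_mix = λx₁ + (1−λ)x₂`, `y_mix = λy₁ + (1−λ)y₂`, `λ ~ Beta(α, α)`;
- **Neighbour Consistency Regularization (NCR)** — for each sample `i` in a
  batch of `m`, penalize the divergence between its predicted class
  distribution `σ(zᵢ)` and the cosine-similarity-weighted mixture of its
  `k` nearest neighbours' predictions in a hidden-layer representation
  space:

  ```
  L_NCR = (1/m) Σᵢ D( σ(zᵢ) ‖ Σ_{j∈NN_k(vᵢ)} s_ij / Σ_l s_il · σ(z_j) ),
  s_ij = cos(vᵢ, vⱼ),   L_total = L_CE + α·L_NCR
  ```

  with KL, Jensen–Shannon and mean-absolute-error divergence variants, a
  warm-up period during which only cross-entropy is active, and analytic
  gradients through both the logits and the representations (verified
  against finite differences in the tests).

The package also provides: a synthetic EHR-like cohort generator with a
closed-form Bayes AUROC ceiling and exact class-conditional noise
injection; leakage-free median-imputation/standardization; a
gradient-boosted tree baseline (xgboost); threshold tuning to a target
sensitivity (default 0.85); percentile-bootstrap CIs and paired-bootstrap
model comparison; memorization diagnostics (latent-similarity strata and
per-epoch confidence traces for clean vs mislabeled samples); and a
sweep/ablation runner with a thin CLI (`inst/cli/noisytab`).

## Worked example

Train NCR on a cohort whose training labels have lost 40% of the true
cases (and gained 0.5% false positives), then evaluate against the clean
test labels:

```r
library(noisytab)

cohort <- generate_cohort(cohort_spec(seed = 7))   # 6000 x 20, 5% positive
splits <- split_cohort(cohort, c(0.6, 0.2, 0.2), seed = 7)
state  <- fit_preprocess(splits$train)
train  <- apply_preprocess(splits$train, state)
val    <- apply_preprocess(splits$val, state)
test   <- apply_preprocess(splits$test, state)

train_noisy <- inject_label_noise(train,
                                  noise_spec(fn_rate = 0.4, fp_rate = 0.005,
                                             seed = 7))
sum(train_noisy$noise_flag)
#> [1] 87

fit <- train_model(train_noisy, val, train_config(method = "ncr", seed = 7))
fit
#> <mlp_fit> method = ncr, 60 epochs, final val AUROC = 0.758

thr <- tune_threshold(val$label, predict(fit, val))   # sensitivity >= 0.85
report <- evaluate_scores(test$clean_label, predict(fit, test), thr, seed = 7)
glance(report)
#> # A tibble: 1 x 6
#>   auroc auprc sensitivity specificity threshold n_boot
#>   <dbl> <dbl>       <dbl>       <dbl>     <dbl>  <dbl>
#> 1 0.769 0.248       0.810       0.511 0.0000896   1000
```

The AUROC of 0.769 should be read against two anchors: the same network
trained with plain cross-entropy on the same corrupted labels reaches
0.759, and the generator's Bayes ceiling (`bayes_auroc(cohort_spec())`) is
0.889 — single seeds are noisy, and the systematic comparison is the
sweep below. `tidy(report)` gives each metric with its bootstrap 95% CI,
`autoplot(fit$history)` shows the CE/NCR terms and validation AUROC per
epoch, and `similarity_strata()` / `confidence_trace()` expose the
memorization mechanics.

The multi-seed comparison across corruption levels:

```r
res <- run_sweep(sweep_spec(methods = c("baseline", "ncr"), n_seeds = 5))
summarize_sweep(res)   # per-level means + across-noise sd (consistency)
plot_sweep(res)        # AUROC vs noise level by method
```

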