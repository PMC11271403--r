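# afwear

Wearable heart-rate analytics for randomized rate-control trials in
permanent atrial fibrillation.

Consumer wrist devices record heart rate every few seconds and step counts
every minute for months, at rest and on exertion — but with device-off
gaps, connectivity dropouts, and no ready-made analysis path. `afwear`
implements that path end to end, for trial statisticians and methods
researchers working with dense two-channel physiological streams:

* **Synthetic cohorts.** A seeded generator for two-arm randomized cohorts
  of per-minute wearable streams with circadian structure, activity-coupled
  heart rate, exchangeable weekly variance, device-off missingness, and
  end-of-trial NYHA labels linked to activity. Real streams of this kind
  are rarely redistributable; the generator provides ground truth against
  which every estimator in the package is validated.
* **Preprocessing.** One-minute pooling (heart rate averaged, steps
  summed), per-patient normalization (heart-rate z-scores, steps scaled to
  [0,1]), missingness encoded as a third channel rather than imputed,
  staggered 4-hour windows, and weekly summaries with CDC activity bands
  (<15,000 / 15,000–30,000 / ≥30,000 steps per week).
* **Treatment comparison.** Gaussian GEE with exchangeable working
  correlation and robust (sandwich) standard errors for weekly mean heart
  rate on arm:

  $$E[\bar{hr}_{iw}] = \beta_0 + \beta_1[\text{digoxin}_i] + \gamma^\top x_{iw},
    \qquad \mathrm{corr}(\bar{hr}_{iw}, \bar{hr}_{iw'}) = \rho,$$

  plus the unadjusted / covariate-adjusted / activity-adjusted /
  activity-subgroup analysis family, Kruskal–Wallis and t tests, and a
  repeated-measures power calculator with a simulation cross-check.
* **Self-supervised CNN.** A 1-D convolutional network (8/20/32 filters,
  kernel 21 min, max pool 2 after the first layer, global average pooling
  to 32 dimensions, dropout 0.5, single sigmoid unit) trained to
  discriminate original windows from cross-patient *channel-scrambled*
  windows (heart rate of patient A, steps of patient B). Solving the task
  requires learning the temporal interaction between channels. Implemented
  natively in R (BLAS im2col convolutions, hand-derived backprop verified
  by finite differences), with patient-level 5-fold cross-validation and
  strictly out-of-fold first-week embeddings.
* **Outcome prediction & evaluation.** Ridge-penalized, label-smoothed
  logistic regression of end-of-trial NYHA class (I/II vs III/IV) on
  embedding, conventional (ECG heart rate + 6-minute-walk), or combined
  features; F1 with patient-level bootstrap CIs, permutation chance-level
  F1, tie-corrected AUROC, and paired bootstrap model comparison.

## Worked example

```r
library(afwear)

cfg <- cohort_config(n_patients = 10, n_weeks = 2, seed = 42)
cohort <- generate_cohort(cfg)
pp <- preprocess_cohort(cohort$streams, stride_min = 240)

fit <- fit_gee_exchangeable(pp$summaries, cohort$profiles, model_spec())
print(fit)
#> <gee_fit> 10 patients, 20 patient-weeks, rho_hat = 0.793
#>                beta robust_se   lower   upper      p
#> (Intercept) 80.7119    1.7141 77.3523 84.0714 0.0000
#> arm_digoxin -4.7389    2.1391 -8.9315 -0.5463 0.0267

dc <- daytime_correlation(cohort$streams[[1]])
round(c(rho = dc$rho), 3); dc$band
#>   rho
#> 0.243
#> [1] "weak to moderate"
```

The GEE line reads: across 20 patient-weeks from 10 patients, the weekly
mean heart rate of digoxin-randomized patients was 4.7 bpm lower than the
beta-blocker arm's (robust 95% CI −8.9 to −0.5), with the estimated
exchangeable correlation of weekly means at 0.79. This toy cohort was
generated with a *zero* true arm effect: the nominally significant
P = 0.027 is exactly the small-sample anticonservatism of sandwich-based
Wald inference at 10 clusters, which is why the package's calibration
checks (null p-value uniformity, CI coverage) run at realistic cluster
counts of 40–100 patients. The Spearman correlation between daytime 10-s
heart rate and activity for the first patient is 0.24, in the
weak-to-moderate band typical of wrist devices.

The self-supervised branch follows the same pattern (see the methods
vignette in `vignettes/` for parameter guidance):

```r
fit  <- train_discriminator(pp$windows, cnn_spec(), folds = 5, seed = 1)
emb  <- ssl_oof_embeddings(fit, split_first_week(pp$windows)$first_week)
fs   <- make_features(cohort$profiles, emb, "wearable")
pred <- fit_ridge_logistic(fs, setNames(cohort$profiles$nyha_final,
                                        cohort$profiles$patient_id))
f1_score(pred$predictions$true_class, pred$predictions$predicted_class)
```

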