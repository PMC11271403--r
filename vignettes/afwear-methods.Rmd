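---
title: "Methods: wearable heart-rate analytics for rate-control trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable heart-rate analytics for rate-control trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afwear)
```

# The problem

Rate-control trials in permanent atrial fibrillation (AF) traditionally
compare arms with periodic clinic measurements: a 12-lead ECG heart rate and
a 6-minute-walk (6MW) test every few months. A wrist-worn consumer wearable
instead produces heart-rate readings every few seconds and per-minute step
counts for months, at rest and on exertion, but with device-off gaps,
connectivity dropouts and substantial noise. `afwear` implements an
end-to-end analysis pipeline for such data:

1. a **synthetic cohort generator** producing two-arm randomized cohorts of
   per-minute heart-rate/step streams with the statistical structure the
   downstream analyses assume;
2. **preprocessing**: 1-minute pooling, per-patient normalization,
   missingness-as-a-channel encoding, staggered 4-h windows, weekly
   summaries;
3. a **repeated-measures treatment comparison** by Gaussian GEE with an
   exchangeable working correlation and robust standard errors;
4. a **self-supervised convolutional network** trained by cross-patient
   channel scrambling, yielding 32-dimensional patient embeddings;
5. **NYHA-class prediction** from those embeddings with ridge-penalized,
   label-smoothed logistic regression, evaluated by F1, AUROC and bootstrap
   confidence intervals.

Because real trial streams of this kind are not freely redistributable, the
generator is a first-class, tested component: every claim the test suite
makes is a claim about recovery of *known* structure injected by the
generator.

# The cohort model

`cohort_config()` fixes the study conditions. Defaults describe an older,
multimorbid AF cohort: 50 patients followed for 20 weeks, heart rate near
76 bpm, 40% women, mean age ~76 (s.d. 8.4), right-skewed NT-proBNP (median
~1100 pg/ml), ~45% with diagnosed heart failure, and NYHA class
concentrated in II (~70%) and III (~26%).

Minute-level heart rate for patient $i$ at minute $t$ is

$$hr_i(t) = \mu + \delta\,[\text{digoxin}_i] + b_i + u_{i,w(t)}
  + A\cos\!\left(\tfrac{2\pi (h(t)-16)}{24}\right) + g\,s_i(t) + e_i(t),$$

with patient intercept $b_i$, weekly perturbation $u_{iw}$, a circadian
sinusoid peaking at 16:00, an activity gain $g$ (bpm per step/min), and
AR(1) minute noise $e_i(t)$ (autocorrelation $\phi = 0.8$, so short-range
structure exists for a convolutional model to exploit). Steps are
zero-inflated Poisson walking bouts, gated to near zero between 23:00 and
07:00. A patient's latent capacity scales the *frequency* of bouts
($p_{\text{active}} = 0.1\,a_i$ per daytime minute, cadence fixed near 40
steps/min), not their intensity: low-capacity patients walk less often at a
similar cadence. This choice matters downstream — per-patient
normalization scales steps by each patient's own maximum, which would erase
capacity differences expressed through intensity, whereas bout frequency
survives normalization and is exactly what a first-week embedding can
legitimately learn. The device emits heart rate every 10 s and steps once
per minute, so the 1-minute pooling rule is genuinely exercised.

Key parameter choices, made once:

* **Weekly variance structure.** Weekly mean heart rates are exchangeable
  with correlation `week_correlation` (default 0.91) and standard deviation
  ~6 bpm, the regime in which repeated-measures modelling of such trials
  operates. `between_patient_sd_bpm` = $6\sqrt{0.91} \approx 5.72$ and the
  week-level noise follow from those two quantities.
* **Activity gain** defaults to 0.15 bpm per step/min: a walking bout at
  100 steps/min raises heart rate ~15 bpm, and the implied daytime
  Spearman correlation between 10-s heart rate and activity lands in the
  "weak to moderate" band typical of wrist devices.
* **Missingness** is generated as contiguous device-off gaps (geometric
  lengths, mean 60 min, both channels removed) totalling 15% of minutes by
  default. Gaps are placed until the deleted fraction matches the target,
  trimming the final gap.
* **NYHA labels.** End-of-trial class is drawn from an ordinal latent model
  $-\beta\, z(\bar s_i) + \epsilon$, where $\bar s_i$ is mean weekly steps;
  thresholds are rescaled by the latent s.d. so the marginal distribution
  stays near 2/70/26/2% for classes I–IV regardless of the link strength
  $\beta$. Because ~70% of the mass sits in class II, tie-corrected rank
  correlations between activity and class saturate near $-0.78$ even for
  very strong links — a ceiling imposed by the marginal, not a weakness of
  the link.

`simulate_weekly_cohort()` draws the *weekly marginal* of the same model
directly (patient intercept + weekly noise + activity contribution +
$m^{-1/2}$ residual of averaging $m$ minutes), skipping minute
materialization. Repeated-measure simulation studies (bias, coverage, null
calibration) use it; anything touching pooling, windows or the CNN uses the
full minute-level generator.

What the generator does *not* emulate: photoplethysmography artifacts,
atrial-fibrillation beat-to-beat irregularity, behavioral feedback from
wearing the device, informative (outcome-dependent) missingness, and
drug-titration dynamics. Tests passing on synthetic cohorts therefore
demonstrate correctness of the estimators and the learnability machinery
under the stated model, not clinical performance on trial data.

# Preprocessing

`pool_to_minutes()` averages heart-rate samples and sums steps within each
calendar minute from the first to the last record. A minute missing either
channel gets mask 1 (the *union* rule): the mask stays truthful for both
channels, which matters because the scrambling task later recombines them.

`normalize_patient()` uses each patient's own statistics: heart rate to
z-scores over nonmissing minutes; steps to $[0,1]$ by the patient's maximum
per-minute count with a `max(1, .)` guard (an all-zero step channel stays
zero). Missing minutes are filled with 0 — the per-patient mean heart rate
and zero steps, neutral under both normalizations — and the mask channel
lets the model learn what missingness means instead of imputing.

`extract_windows()` cuts staggered 4-h (240-min) windows every 60 min by
default; a window is *available* when at least half its heart-rate minutes
are nonmissing. Both stride and threshold are configurable since any
specific choice of stagger and eligibility is a judgment call.
`weekly_summaries()` indexes 10,080-minute weeks from the first device
minute, drops weeks under 10% nonmissing, and attaches the CDC activity
band of the weekly step total (<15,000 low; 15,000–30,000 minimum
recommended; ≥30,000 recommended).

# Treatment comparison

The estimator is a Gaussian identity-link GEE with exchangeable working
correlation: weekly mean heart rate on arm (plus covariates), correlation
estimated by the moment estimator from Pearson residuals, estimating
equations iterated to convergence, and a robust sandwich covariance. For
balanced Gaussian data the point estimate coincides with random-intercept
GLS, and with $\rho$ fixed at 0 it *is* ordinary least squares — both facts
are exploited as oracles in the tests (explicit dense GLS algebra on a
2-patient × 2-week table must agree to 1e-8).

Covariate coding is fixed and documented: age centered, woman = 1,
heart-failure diagnosis = 1, NT-proBNP log-transformed (right-skewed),
weekly steps in thousands. `run_analysis_suite()` produces the five-fit
family — unadjusted; covariate-adjusted; activity-adjusted; and three
subgroup fits filtering *week-level* records by activity band, so one
patient can contribute weeks to several subgroups, reported as
(patient-weeks, patients). Wald normal inference is used throughout
(CI $= \hat\beta \pm 1.96\,\widehat{se}$); with 30–100 clusters the normal
approximation is the standard choice for sandwich-based GEE.

`power_repeated_measures()` implements the textbook two-sample calculation
on patient-level means of $m$ equi-correlated measurements,
$\mathrm{Var}(\bar y) = \sigma^2(1+(m-1)\rho)/m$. At $\delta = 2$ bpm,
$\sigma = 6$, $\rho = 0.91$, $m = 20$, $\alpha = 0.05$, power 0.9 this
gives 173 patients per arm — the design effect at $\rho = 0.91$ is ~18.3,
so 20 weekly repeats buy very little over a single week. Much smaller
headline sample sizes sometimes quoted for designs in this parameter regime
are not reproducible from this (or any standard) repeated-measures formula;
the function reports the standard result, cross-checked against a
Monte-Carlo power oracle to ±0.03, and we deliberately did not tune it
toward any external figure.

# Self-supervised embedding

The auxiliary task: discriminate original windows from *scrambled* windows
whose heart-rate channel comes from patient A but whose step channel comes
from a different patient B. Original windows have cross-channel temporal
coupling (exertion raises heart rate); scrambled ones do not; a
discriminator that succeeds must therefore have learned that coupling.

Two design details prevent degenerate shortcuts:

* **Mask equalization.** A scrambled sample's mask is the union of its two
  donors' masks. If originals kept their own (sparser) masks, mask density
  alone would identify the class — we measured ~0.57 held-out accuracy on
  *decoupled* channels from this cue alone. Each pair's union mask is
  therefore applied to both members (value channels zero-filled under it),
  making the mask distribution identical across classes by construction.
* **Time-of-day matching.** Step donors are drawn from the same 4-h
  time-of-day bucket when possible, so circadian phase cannot solve the
  task. (Night windows, with near-zero steps in both classes, remain
  intrinsically ambiguous; they bound the attainable accuracy below 1.)

The network is the reference architecture: three 1-D conv layers (8/20/32
filters, kernel 21 minutes), max pooling (size and stride 2) after the
first only, global average pooling to a 32-vector, dropout 0.5 on that
vector, one sigmoid unit; ReLU elsewhere; Adam at 3e-4; BCE loss; L2 1e-8
on non-bias parameters; batch 64; early stopping on held-out loss with
patience 10 within a 200-epoch cap. Convolutions are im2col matrix
products; the backward pass is hand-derived and verified against central
finite differences to ~1e-7 relative error. Training tests use a reduced
network (4/8/8 filters, kernel 9) — the learning dynamics being tested are
architecture-size-independent, and the full architecture is separately
pinned by structural tests (embedding length 32, parameter count 17,397,
minimum input length 102).

Cross-validation is by patient: 5 folds, each model trained on scrambles
built only from its training patients' non-first-week windows, with the
held-out patients' scrambles monitoring overfitting. `ssl_oof_embeddings()`
embeds each patient's *first week* with the model from the fold where that
patient was held out, so no patient is embedded by a model that ever saw
their windows; per-window vectors are averaged (unweighted) into one
32-vector per patient.

# NYHA prediction and evaluation

NYHA is binarized as I/II versus III/IV — the split between slight and
marked limitation — because single AUROC/F1 values are well defined for a
binary outcome; with class IV at ~2% prevalence a 4-class model on ~50
patients would be estimating empty cells. Features (embedding; or ECG heart
rate + 6MW distance/time/speed; or embedding + age/gender/BMI) are
standardized with training-fold statistics; targets are smoothed
($y' = y(1-\varepsilon) + \varepsilon/2$, $\varepsilon = 0.1$); the ridge
penalty is chosen from {0.01, 0.1, 1, 10} by inner 3-fold log-loss. All
reported predictions are out-of-fold at the patient level, stacking on top
of the embedding folds so the no-leakage property holds end to end.

Evaluation: F1 (binary by default, macro/weighted available; zero-division
convention 0), tie-corrected rank AUROC, percentile bootstrap CIs over
patients (degenerate single-class resamples skipped and counted),
`chance_f1()` as the expected F1 of a uniformly random permutation of the
labels (exact enumeration for $n \le 7$), and a paired patient-level
bootstrap of $\Delta F1$ for model comparison with two-sided p-value
$\min(1, 2\min(P(\Delta\le 0), P(\Delta\ge 0)))$. Percentile rather than
BCa intervals are used: at 40–50 patients the difference is far smaller
than the Monte-Carlo noise, and percentile intervals are the transparent
default.

# Numerical choices and degenerate inputs

* GEE: $\hat\rho$ clamped to $(-1/(\max n_i - 1) + 10^{-6},\ 0.999)$;
  singular designs error naming the collinear columns; non-convergence
  returns `converged = FALSE` with a warning rather than failing.
* Normalization: constant heart-rate series and all-missing series are
  errors; an all-zero step channel is valid (guarded denominator).
* Ridge logistic: Newton iterations with the Hessian's IRLS weights
  clamped at $10^{-6}$; the intercept is never penalized.
* CNN: He-normal initialization; ties in max pooling route the gradient to
  the first element; all stochastic steps (initialization, shuffling,
  dropout, scrambling, folds) take explicit seeds and are reproducible on
  one thread.
* Windows shorter than the kernel chain are a constructive error reporting
  the computed minimum input length.

# Problem sizes used in the shipped checks

The package's simulation studies are sized so the full suite runs on one
CPU in minutes while keeping Monte-Carlo error well inside the asserted
tolerances: bias/coverage of the arm effect over 200 weekly cohorts of 100
patients × 20 weeks; null p-value calibration over 500 cohorts of 40
patients × 10 weeks; and a shared pair of self-supervised runs (strongly
coupled channels with activity-linked labels, versus fully decoupled
channels with unlinked labels) on 20 patients × 2 weeks of minute-level
data with non-overlapping 4-h windows, feeding both the discriminator
controls and the end-to-end label-recovery check. These sizes
are the package's own choices and are stated here so that anyone scaling
them up knows what was actually verified.

# Known limitations

* The generator's missingness is ignorable by construction; the
  mask-channel approach is *motivated* by non-ignorable missingness, but
  demonstrating benefit under informative gaps would require extending the
  generator.
* The discriminator's held-out accuracy on realistic (weakly coupled,
  noisy) cohorts is modest; the embeddings remain informative because the
  convolutional features summarize activity and heart-rate structure even
  when the auxiliary task is only partially solved.
* Weekly GEE assumes the exchangeable structure the generator injects;
  under long-memory drift the sandwich errors remain valid but the
  efficiency argument for the working correlation weakens.
* No multiplicity correction across the five-fit analysis family, matching
  standard practice for a prespecified primary comparison with descriptive
  secondaries.
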