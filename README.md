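# cinesurv

Unsupervised cine-CMR fingerprinting and censoring-aware neural risk
prediction for arrhythmic outcomes — with a fully synthetic beating-heart
cohort so the whole pipeline is testable without patient data.

## Who this is for

Researchers developing imaging-based risk models for primary-prevention
ICD candidates (and, more generally, anyone who wants a worked,
end-to-end-tested reference for cross-validated neural survival analysis
on image cohorts). The clinical motivation: LVEF alone is a blunt
selector of who benefits from a defibrillator, while routine non-contrast
cine CMR already contains rich chamber structure and function. The
package implements the two-network answer:

1. **Cine fingerprint extractor** — a probabilistic encoder–decoder
   (variational autoencoder) trained fully unsupervised on cropped
   four-chamber cine sequences (production geometry 128 × 128 px at
   2.2 mm). It minimises
   `L2(reconstruction) + kl_weight · KL(q(z|x) ‖ N(0, I))` and emits a
   per-subject latent *fingerprint* (posterior mean + log-variance).
2. **Risk predictor** — a small feed-forward head on the fingerprint
   trained with the Cox partial-likelihood loss
   `ℓ(η) = Σ_{events i} [η_i − log Σ_{t_j ≥ t_i} exp(η_j)]`
   (Breslow ties), so censored follow-up is used correctly; it reports a
   0–1 *cine risk score* `plogis(η)`, retrained per outcome (ventricular
   arrhythmia, heart-failure death, all-cause death).

Both networks are trained under a shared no-leak sixfold protocol: for
each fold, both networks are trained with that fold held out and only the
held-out fold is scored; pooling the folds gives exactly one out-of-fold
score per subject. Evaluation covers Harrell's C (bootstrap CI), Cox
hazard ratios, Kaplan–Meier/log-rank on the median split, Fine–Gray
competing-risk regression, continuous NRI, exact-Poisson incidence rates
per 100 person-years, and a two-proportion sample-size calculator.

Because the motivating cohort is private, the package ships generators
for (a) four-chamber cine phantoms with controllable ejection fractions,
atrial emptying, and noise; (b) exponential survival with log-linear
hazards on the generative parameters, competing death, and administrative
censoring; and (c) LGE phantoms with exact core-scar / gray-zone pixel
counts for the half-max / normal-peak thresholding rule.

## Worked example

Simulate a small cohort whose hazard rises as LVEF falls, run the
cross-validated two-network pipeline, and evaluate:

```r
library(cinesurv)

cohort <- sample_cohort(60, seed = 5, size_px = 32, n_frames = 8)
surv   <- simulate_survival(
  cohort,
  survival_sim_config(baseline_hazard = 0.03,
                      log_hazard_coeffs = c(lv_ef = -1),
                      admin_censor_years = 10, seed = 6))
surv
#> <cohort_table> outcome VA: 60 subjects, 26 primary events, 0 competing deaths

res <- run_pipeline(
  cohort$sequence, surv, outcomes = "VA", k_folds = 6,
  extractor = extractor_config(latent_dim = 16, hidden_dim = 32, epochs = 120,
                               kl_weight = 1e-4, pool = 2),
  risk = risk_config(hidden_dim = 4, epochs = 200, weight_decay = 0.2),
  seed = 7, n_resamples = 50)
res$evaluations$VA
#> <outcome_evaluation> VA: n = 60, events = 26
#>   C-index 0.581 (95% CI 0.444-0.675)
#>   HR per unit score 6.00 (95% CI 0.57-63.05), p = 0.135
#>   median-split log-rank chi2 = 1.64, p = 0.2
#>   incidence 5.74/100 PY overall, 4.00/100 PY below the 25% cutoff
```

Every subject receives exactly one out-of-fold score
(`res$predictions`), scored only by models whose training excluded it.
This miniature run (60 subjects, 32 px frames, ~25 seconds of training)
shows the mechanics; with 26 events nothing reaches significance. The
study-scale behaviour is exercised by the test suite and the acceptance
script (240 subjects, 64 px frames, sixfold CV repeated three times):
there the pooled out-of-fold C-index lands around 0.64-0.73 depending on
the cohort draw (0.73 at the suite's fixed seed, against an oracle
ceiling of 0.76 for the true generative covariate) and the median-split
log-rank test separates at p < 0.001. The headline numbers and what they
mean:

* `c_index` — probability that, of two comparable subjects, the one with
  the higher cine risk score has the earlier event (0.5 = chance);
* `hazard.ratio` — per-unit-score hazard ratio from a univariate Cox fit;
* `logrank.p` — survival-curve separation of the median-split risk groups;
* `incidence.rate` / `incidence.rate.low` — events per 100 person-years
  overall and in the lowest score quartile.

Single components work standalone, tidyverse-style:

```r
sample_size_two_proportions(0.877, 0.740, alpha = 0.05, power = 0.90)
#> $n_per_group
#> [1] 172
#> $n_total
#> [1] 344

ph <- generate_lge_phantom(scar_core_px = 20, scar_gray_px = 10, seed = 4)
quantify_scar(ph$image, ph$myocardium_mask, ph$hyperenhanced_mask,
              voxel_volume_mm3 = 1.5 * 2.3 * 8)
#> # A tibble: 1 × 8
#>   core_px gray_px unclassified_px core_g gray_g total_g max_si normal_peak_si
#>     <int>   <int>           <int>  <dbl>  <dbl>   <dbl>  <dbl>          <dbl>
#> 1      20      10               0  0.580  0.290   0.869      1            0.3

fit <- fit_cox(cbind(score = runif(100)), rexp(100), rbinom(100, 1, 0.5))
tidy(fit)    # term, estimate, hazard.ratio, conf.low/high, p.value
glance(fit)  # n, n.events, logLik
```

`autoplot()` works on Kaplan–Meier curves and risk-score results;
`plot_risk_groups()` draws the split-survival figure;
`plot_cine_frame()` shows phantom frames.

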