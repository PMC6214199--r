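# survscreen

Screening and variable selection for ultra-high-dimensional survival data.

Genome-wide SNP panels offer hundreds of thousands of candidate predictors
for a few hundred patients with a right-censored outcome. `survscreen`
implements the two-stage strategy for building proportional-hazards
prognostic models in that regime — **screening** the dimension down
(aggressive sure independence screening, iterative SIS, principled SIS)
and then **selecting** a final model (LASSO, adaptive LASSO, or
random-survival-forest minimal-depth thresholding) — together with a
Hardy–Weinberg SNP survival simulator, discrimination / calibration /
overall-performance metrics, bootstrap optimism correction, SNP QC
filters, and a replicated benchmark driver that compares all thirteen
screen × selector combinations.

The statistical core, in the field's standard notation:

* marginal utility of variable *k*:
  maximized univariate Cox log partial likelihood
  *u*ₖ = max over βₖ of Σᵢ δᵢ xᵢₖβₖ − Σᵢ δᵢ log Σ_{j∈R(yᵢ)} exp(xⱼₖβₖ);
  aggressive SIS keeps the top *s* = ⌊n/log n⌋ variables per random
  half-sample and intersects the two top sets; iterative SIS alternates
  conditional screening with a selector until the selected set stabilizes;
  principled SIS thresholds the standardized marginal statistic
  I(β̂)^½·|β̂| at Φ⁻¹(1 − q_m/2).
* penalized selection: β̂ = argmax (2/n)·l(β) − λ‖Wβ‖₁ with W = I
  (LASSO) or W = diag(1/|β̃|) (adaptive LASSO), λ by 10-fold
  cross-validated partial-likelihood deviance.
* RSF minimal depth: a variable is kept when its forest-averaged minimal
  depth is at or below the mean of the noise-variable null distribution
  P(D_v = d) = (1 − 1/p)^{L_d}(1 − (1 − 1/p)^{l_d}) evaluated on each
  tree's observed topology.
* metrics: Harrell's c-index, IPCW Brier-score R²(t* = 2), calibration
  slope by proportional-hazards regression of new outcomes on the
  prognostic index, quartile calibration tables, Harrell-style bootstrap
  optimism.

## Worked example

Simulate a strong-signal scenario (n = 300 training subjects, p = 2000
SNPs at MAF 0.15, six informative variants, Weibull failure times with 20%
calibrated uniform censoring, an independent n = 2000 test set), run the
ISIS–LASSO pipeline, and evaluate the refit model:

```r
library(survscreen)

cfg <- scenarioConfig(n = 300, p = 2000, a = 2, seed = 5, testN = 2000)
d <- genDataset(cfg, includeTest = TRUE)
d$train$outcome
#> SurvivalOutcome: 300 subjects, 236 events (21.3% censored)

scr <- isis(d$train$geno, d$train$outcome, selector = "LASSO", seed = 101)
scr
#> ScreenResult [ISIS]: 10 variables selected after 4 iteration(s)
selected(scr)
#>  [1]    1    2    3    4    5    6  354  366  529 1593

fit <- coxRefit(d$train$geno, d$train$outcome, selected(scr))
ev <- evaluateModel(fit, d$test$geno, d$test$outcome, tStar = 2)
ev
#> EvalReport: c-index=0.8901  R2_BS=0.7731  calibration slope=0.8764
```

The screen recovered all six informative variants (columns 1–6) plus four
intersection-surviving noise columns (at p = 2000 the two-partition
intersection lets through about s²/p ≈ 1.4 noise variables per pass); the
refit model discriminates at c ≈ 0.89 on independent data, explains ≈ 77%
of the 2-year Brier score relative to the null model, and its calibration
slope is close to 1 (the four noise coefficients cost a little shrinkage
on new data).

The same pipeline is available per-replicate through the benchmark layer:

```r
b <- runBenchmark(cfg, methodSpec("ISIS", "LASSO"), reps = 10, seed = 42)
b$summary[, c("method", "sizeSelected_mean", "nInformative_mean",
              "cTest_mean", "calSlope_mean")]
```

A thin command-line front end over the same functions lives at
`inst/cli/survscreen.R` (subcommands `simulate`, `screen`, `select`,
`evaluate`, `benchmark`, each taking a JSON config, `--seed`, `--out`).

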