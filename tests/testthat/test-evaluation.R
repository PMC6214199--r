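# Discrimination, overall performance, calibration, optimism.

test_that("Harrell's c matches the exhaustive pair oracle", {
  y4 <- survivalOutcome(1:4, rep(1L, 4))
  expect_equal(harrellC(c(4, 3, 1, 2), y4), 5 / 6)

  for (seed in c(2, 13, 40)) {
    set.seed(seed)
    n <- sample(20:100, 1)
    tt <- rexp(n)
    dd <- rbinom(n, 1, 0.7)
    lp <- round(rnorm(n), 1) # coarse rounding induces predictor ties
    tt[sample(n, 4)] <- tt[1] # induce tied times
    y <- survivalOutcome(tt, dd)
    expect_equal(harrellC(lp, y), pairOracleC(lp, tt, dd))
  }

  # perfect concordance on uncensored data with the true risk ordering
  set.seed(1)
  tt <- sort(rexp(30), decreasing = TRUE)
  expect_equal(harrellC(seq_len(30), survivalOutcome(tt, rep(1L, 30))), 1)

  # random predictions hover at 1/2
  set.seed(3)
  tt <- rexp(2000)
  y <- survivalOutcome(tt, rbinom(2000, 1, 0.8))
  expect_lt(abs(harrellC(rnorm(2000), y) - 0.5), 0.03)

  expect_error(harrellC(1, survivalOutcome(1, 1L)), "comparable")
})

test_that("Brier R2 has its fixed points and matches a hand computation", {
  set.seed(6)
  n <- 200
  tt <- rexp(n)
  dd <- rbinom(n, 1, 0.75)
  y <- survivalOutcome(tt, dd)
  tStar <- quantile(tt, 0.4)
  km <- survival::survfit(asSurv(y) ~ 1)
  sNull <- min(km$surv[km$time <= tStar], 1)
  # the null model scored against itself is exactly zero
  expect_equal(brierR2(rep(sNull, n), y, tStar), 0)

  # perfect 0/1 predictions with no censoring reach 1
  yAll <- survivalOutcome(tt, rep(1L, n))
  expect_equal(brierR2(as.numeric(tt > tStar), yAll, tStar), 1)

  # spreadsheet-style oracle on a small set with censoring
  t10 <- c(0.2, 0.5, 0.8, 1.1, 1.4, 1.7, 2.1, 2.5, 3.0, 3.5)
  d10 <- c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, 1L)
  y10 <- survivalOutcome(t10, d10)
  p10 <- seq(0.95, 0.05, length.out = 10)
  bsModel <- spreadsheetBrier(p10, t10, d10, 1.5)
  km10 <- survival::survfit(asSurv(y10) ~ 1)
  s0 <- min(km10$surv[km10$time <= 1.5])
  bsNull <- spreadsheetBrier(rep(s0, 10), t10, d10, 1.5)
  expect_equal(brierR2(p10, y10, 1.5), 1 - bsModel / bsNull,
               tolerance = 1e-12)

  # degrading perfect predictions monotonically lowers R2
  truth <- as.numeric(tt > tStar)
  r2s <- vapply(c(0, 0.1, 0.25, 0.45), function(eps) {
    noisy <- pmin(pmax(truth + eps * (0.5 - truth) * 2, 0), 1)
    brierR2(noisy, yAll, tStar)
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))

  expect_error(brierR2(rep(0.5, n), y, max(tt) + 1), "at risk")
})

test_that("calibration slope is scale-equivariant and centred at truth", {
  cfg <- scenarioConfig(n = 4000, p = 6, a = 2, seed = 77)
  d <- genDataset(cfg)
  lpTrue <- 1.5 * as.vector(genoValues(d$train$geno) %*% d$model@beta[1:6])
  sl <- calibrationSlope(lpTrue, d$train$outcome)
  se <- sqrt(diag(vcov(survival::coxph(asSurv(d$train$outcome) ~ lpTrue))))
  expect_lt(abs(sl - 1), 3 * se)

  # doubling the index halves the slope exactly
  expect_equal(calibrationSlope(2 * lpTrue, d$train$outcome), sl / 2,
               tolerance = 1e-8)

  # a pure-noise index has slope ~ 0
  set.seed(5)
  noise <- rnorm(4000)
  slN <- calibrationSlope(noise, d$train$outcome)
  seN <- sqrt(diag(vcov(survival::coxph(asSurv(d$train$outcome) ~ noise))))
  expect_lt(abs(slN), 3 * seN)

  expect_error(calibrationSlope(rep(1, 4000), d$train$outcome), "constant")
})

test_that("quartile calibration bins behave and track the truth", {
  cfg <- scenarioConfig(n = 4000, p = 6, a = 2, seed = 55)
  d <- genDataset(cfg)
  fit <- coxRefit(d$train$geno, d$train$outcome, 1:6)
  ps <- predictSurvival(fit, d$train$geno, 2)
  tab <- calibrationQuartiles(ps, d$train$outcome, 2)
  expect_identical(nrow(tab), 4L)
  expect_true(all(diff(tab$meanPredicted) >= 0)) # bin 1 = highest risk
  # a well-specified model on its own large training set calibrates closely
  expect_lt(max(abs(tab$observed - tab$meanPredicted), na.rm = TRUE), 0.05)

  # homogeneous predictions give four bins with one shared mean
  tabH <- calibrationQuartiles(rep(0.4, 200),
                               survivalOutcome(rexp(200), rep(1L, 200)), 0.5)
  expect_equal(tabH$meanPredicted, rep(0.4, 4))

  # reversing predictions reverses the bin membership
  set.seed(8)
  p0 <- runif(400)
  yy <- survivalOutcome(rexp(400), rbinom(400, 1, 0.8))
  tA <- calibrationQuartiles(p0, yy, 0.5)
  tB <- calibrationQuartiles(1 - p0, yy, 0.5)
  expect_equal(tA$meanPredicted, rev(1 - tB$meanPredicted), tolerance = 1e-12)
})

test_that("bootstrap optimism is ~0 for fixed rules and positive when overfit", {
  cfg <- scenarioConfig(n = 120, p = 30, a = 2, seed = 91)
  d <- genDataset(cfg)
  v <- genoValues(d$train$geno)
  y <- d$train$outcome

  fixedPipeline <- function(X, outcome, seed) coxRefit(X, outcome, 1:6)
  resFix <- bootstrapOptimism(v, y, fixedPipeline, B = 20, seed = 2)
  expect_lt(abs(resFix$optimism), 0.05)
  expect_equal(resFix$cCorrected, resFix$cApparent - resFix$optimism)

  # unpenalized fit on many noise columns is optimistic
  overfitPipeline <- function(X, outcome, seed)
    coxRefit(X, outcome, seq_len(ncol(X)))
  resOver <- bootstrapOptimism(v, y, overfitPipeline, B = 20, seed = 3)
  expect_gt(resOver$optimism, 0)

  # a pipeline that breaks on resamples (duplicated rows) is surfaced
  failing <- function(X, outcome, seed) {
    if (any(duplicated(X))) stop("cannot handle ties")
    coxRefit(X, outcome, 1:6)
  }
  expect_error(bootstrapOptimism(v, y, failing, B = 10, seed = 4),
               "failed")
})

test_that("evaluateModel applies the null-model conventions", {
  cfg <- scenarioConfig(n = 200, p = 10, a = 2, seed = 14)
  d <- genDataset(cfg, includeTest = TRUE)
  fit <- coxRefit(d$train$geno, d$train$outcome, integer(0))
  ev <- evaluateModel(fit, d$test$geno, d$test$outcome, 2)
  expect_equal(ev@cIndex, 0.5)
  expect_equal(ev@r2bs, 0)
  expect_true(is.na(ev@calSlope))
})
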