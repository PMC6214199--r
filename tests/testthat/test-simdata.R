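# Synthetic data generator: HWE genotypes, signed coefficients, Weibull
# failure times, censoring calibration.

test_that("genotypes follow the Hardy-Weinberg class probabilities", {
  expect_equal(hweProbs(0.15), c(0.7225, 0.2550, 0.0225))
  expect_error(hweProbs(0.7))
  expect_error(genGenotypes(0, 5, 0.15))

  g <- genGenotypes(10000, 10, q = 0.15, seed = 3)
  v <- genoValues(g)
  # mean code = 2q within 3 binomial-style SEs
  se <- sqrt(2 * 0.15 * (1 - 0.15) / length(v)) # conservative
  expect_lt(abs(mean(v) - 0.30), 3 * sqrt(0.3 / length(v)) + 3 * se)

  # chi-square goodness of fit not rejected at alpha = 0.01 on 1e5 draws
  obs <- tabulate(as.vector(v) + 1L, 3L)
  p <- hweProbs(0.15)
  stat <- sum((obs - length(v) * p)^2 / (length(v) * p))
  expect_gt(pchisq(stat, df = 2, lower.tail = FALSE), 0.01)

  # symmetric case q = 0.5
  g2 <- genGenotypes(20000, 5, q = 0.5, seed = 4)
  fr <- tabulate(as.vector(genoValues(g2)) + 1L, 3L) / 1e5
  se2 <- 3 * sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 1e5)
  expect_true(all(abs(fr - c(0.25, 0.5, 0.25)) < se2))

  # seeded determinism
  expect_identical(genoValues(genGenotypes(50, 20, 0.15, seed = 9)),
                   genoValues(genGenotypes(50, 20, 0.15, seed = 9)))
})

test_that("true coefficients have the stated magnitude, sign and fixtures", {
  expect_equal(betaFixture("strong")@beta[1:6],
               c(2.527186, 2.443898, 2.152147, -2.388758, 2.156502,
                 -2.003314))
  expect_equal(betaFixture("weak")@beta[1:6],
               c(1.036478, -1.073296, -1.250946, 1.138729, -1.128361,
                 1.145263))
  expect_identical(betaFixture("strong", p = 100)@informativeIdx, 1:6)
  expect_true(all(betaFixture("strong", p = 100)@beta[7:100] == 0))

  for (seed in 1:20) {
    m <- genBeta(6, a = 2, seed = seed)
    expect_true(all(abs(m@beta[1:6]) >= 2))
  }
  # signs are balanced across draws
  signs <- unlist(lapply(1:40, function(s) sign(genBeta(6, 1, s)@beta[1:6])))
  expect_gt(mean(signs == 1), 0.35)
  expect_lt(mean(signs == 1), 0.65)
})

test_that("failure times follow the Weibull proportional-hazards model", {
  m0 <- new("TrueModel", beta = 0, informativeIdx = 1L) # null effect
  g <- genGenotypes(50000, 1, q = 0.15, seed = 5)
  tt <- genFailureTimes(g, m0, tau = 1.5, seed = 6)
  # closed-form Weibull median (log 2)^(2/3)
  expect_lt(abs(median(tt) - log(2)^(2 / 3)), 0.01)

  # tau = 1 reduces to the standard exponential
  t1 <- genFailureTimes(g, m0, tau = 1, seed = 7)
  expect_lt(abs(mean(t1) - 1), 3 / sqrt(50000))

  # proportional-hazards identity: shifting x'beta by log(2)/tau doubles
  # the hazard, so S2(t) = S1(t)^2
  tau <- 1.5
  mShift <- new("TrueModel", beta = log(2) / tau, informativeIdx = 1L)
  gOne <- genotypeMatrix(matrix(1, 50000, 1))
  tA <- genFailureTimes(gOne, m0, tau = tau, seed = 8)
  tB <- genFailureTimes(gOne, mShift, tau = tau, seed = 9)
  t0 <- 0.7
  expect_lt(abs(mean(tB > t0) - mean(tA > t0)^2), 0.01)
})

test_that("censoring-bound calibration hits the target and is monotone", {
  # closed-form oracle for the null model at tau = 1:
  # P(T > C) = (1 - exp(-theta)) / theta, solved independently
  cfgNull <- scenarioConfig(n = 100, p = 1, pStar = 1, a = 1, tau = 1,
                            censRate = 0.20, maf = 0.15, seed = 1)
  mNull <- new("TrueModel", beta = 0, informativeIdx = 1L)
  thetaPkg <- calibrateThetaC(cfgNull, mNull)
  thetaOracle <- uniroot(function(th) (1 - exp(-th)) / th - 0.20,
                         c(1e-3, 100), tol = 1e-12)$root
  expect_lt(abs(thetaPkg - thetaOracle), 1e-4)

  # Monte-Carlo check at the study conditions (weak fixture)
  cfg <- scenarioConfig(n = 20000, p = 6, a = 1, seed = 33)
  model <- betaFixture("weak", p = 6)
  theta <- calibrateThetaC(cfg, model)
  d <- genDataset(cfg, model = model, thetaC = theta)
  censFrac <- mean(1 - eventStatus(d$train$outcome))
  expect_lt(abs(censFrac - 0.20), 0.01)

  # analytic and Monte-Carlo calibration agree
  thetaMC <- calibrateThetaC(cfg, model, method = "mc")
  expect_lt(abs(theta - thetaMC) / theta, 0.02)

  # achieved censoring decreases as theta grows
  dLow <- genDataset(scenarioConfig(5000, 6, a = 1, seed = 12),
                     model = model, thetaC = theta / 2)
  dHigh <- genDataset(scenarioConfig(5000, 6, a = 1, seed = 12),
                      model = model, thetaC = theta * 2)
  expect_gt(mean(1 - eventStatus(dLow$train$outcome)),
            mean(1 - eventStatus(dHigh$train$outcome)))
})

test_that("datasets are reproducible and internally consistent", {
  cfg <- scenarioConfig(n = 150, p = 1000, a = 2, seed = 1)
  d1 <- genDataset(cfg, includeTest = TRUE)
  d2 <- genDataset(cfg, includeTest = TRUE)
  expect_identical(genoValues(d1$train$geno), genoValues(d2$train$geno))
  expect_identical(obsTime(d1$train$outcome), obsTime(d2$train$outcome))
  expect_identical(genoValues(d1$test$geno), genoValues(d2$test$geno))

  # event rows carry the generated failure time
  ev <- eventStatus(d1$train$outcome) == 1L
  expect_equal(obsTime(d1$train$outcome)[ev], d1$train$failureTime[ev])

  # test set differs from training but shares the model
  expect_false(identical(genoValues(d1$train$geno)[1:10, 1:10],
                         genoValues(d1$test$geno)[1:10, 1:10]))
  expect_identical(d1$model@beta, betaFixture("strong", p = 1000)@beta)

  # average censoring over replicates stays near the target
  fr <- vapply(1:20, function(s) {
    d <- genDataset(scenarioConfig(n = 300, p = 6, a = 2, seed = s),
                    thetaC = d1$thetaC)
    mean(1 - eventStatus(d$train$outcome))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.20), 3 * sqrt(0.2 * 0.8 / (20 * 300)))
})

test_that("config invariants are enforced", {
  expect_error(scenarioConfig(100, 10, pStar = 20))
  expect_error(scenarioConfig(100, 10, maf = 0.6))
  expect_error(scenarioConfig(100, 10, censRate = 1))
  expect_error(scenarioConfig(100, 10, tau = 0))
})
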