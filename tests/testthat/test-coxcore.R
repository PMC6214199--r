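# Marginal Cox partial-likelihood engine.

test_that("log partial likelihood matches hand expansion and null formula", {
  # two subjects, times (1,2), both events, x = (1,0), beta = 1:
  # l = 1 - log(e + 1) by direct expansion of the two risk-set terms
  y <- survivalOutcome(c(1, 2), c(1, 1))
  expect_equal(coxLogPL(c(1, 0), y, 1), 1 - log(1 + exp(1)))
  expect_equal(coxLogPL(c(1, 0), y, 1),
               bruteLogPL(c(1, 0), c(1, 2), c(1, 1), 1))

  # at beta = 0 the exp terms collapse to risk-set sizes
  d <- smallSurvData(40, seed = 11)
  y <- survivalOutcome(d$time, d$event)
  rsizes <- vapply(which(d$event == 1),
                   function(i) sum(d$time >= d$time[i]), numeric(1))
  expect_equal(coxLogPL(d$x, y, 0), -sum(log(rsizes)))

  # constant covariate: flat in beta
  expect_equal(coxLogPL(rep(2, 40), y, 0.7), coxLogPL(rep(2, 40), y, -1.3))

  # no events is degenerate
  expect_error(coxLogPL(d$x, survivalOutcome(d$time, rep(0L, 40)), 1),
               "no events")
})

test_that("marginal fit agrees with dense grid search on small instances", {
  for (seed in c(3, 17, 29)) {
    d <- smallSurvData(30, seed = seed, beta1 = runif(1, -1, 1))
    y <- survivalOutcome(d$time, d$event)
    fit <- fitMarginal(d$x, y)
    oracle <- gridMaxLogPL(d$x, d$time, d$event)
    expect_equal(fit@betaHat, oracle$beta, tolerance = 1e-3)
    expect_equal(fit@utility, oracle$utility, tolerance = 1e-3)
  }
})

test_that("marginal fit agrees with coxph to 1e-6 on non-tied data", {
  set.seed(5)
  n <- 150
  for (xgen in list(function() rnorm(n),
                    function() sample(0:2, n, TRUE, c(.5, .35, .15)))) {
    x <- xgen()
    tt <- rexp(n, exp(0.4 * x))
    cc <- runif(n, 0, 4)
    y <- survivalOutcome(pmin(tt, cc), as.integer(tt <= cc))
    fit <- fitMarginal(x, y)
    cf <- survival::coxph(asSurv(y) ~ x, ties = "breslow")
    expect_equal(fit@betaHat, unname(coef(cf)), tolerance = 1e-6)
    expect_equal(fit@utility, cf$loglik[2], tolerance = 1e-6)
    expect_equal(fit@information,
                 1 / unname(vcov(cf)[1, 1]), tolerance = 1e-4)
  }
})

test_that("marginal fit is consistent at large n", {
  d <- smallSurvData(2000, seed = 8, beta1 = 0.5)
  y <- survivalOutcome(d$time, d$event)
  fit <- fitMarginal(d$x, y)
  se <- fit@information^(-1 / 2)
  expect_lt(abs(fit@betaHat - 0.5), 3 * se)
})

test_that("degenerate and extreme covariates follow the stated conventions", {
  d <- smallSurvData(50, seed = 2)
  y <- survivalOutcome(d$time, d$event)
  fit <- fitMarginal(rep(1, 50), y)
  expect_equal(fit@betaHat, 0)
  expect_equal(fit@utility, fit@nullLogLik)
  expect_equal(fit@information, 0)
  expect_false(fit@converged)

  # monotone likelihood: perfect risk ordering drives beta to the cap
  n <- 20
  y2 <- survivalOutcome(seq_len(n), rep(1L, n))
  xsep <- rev(seq_len(n)) / n # earliest death has the largest x
  fit2 <- fitMarginal(xsep, y2)
  expect_false(fit2@converged)
  expect_equal(abs(fit2@betaHat), 15)
})

test_that("Newton trajectory of accepted steps is non-decreasing", {
  for (seed in c(1, 9, 23)) {
    d <- smallSurvData(60, seed = seed, beta1 = 1.5)
    y <- survivalOutcome(d$time, d$event)
    tr <- attr(fitMarginal(d$x, y), "trace")
    expect_false(is.unsorted(tr))
  }
})

test_that("vectorized utilities equal a loop of marginal fits exactly", {
  set.seed(77)
  g <- genGenotypes(60, 50, q = 0.25, seed = 14)
  v <- genoValues(g)
  tt <- rexp(60, exp(0.8 * v[, 1]))
  cc <- runif(60, 0, 3)
  y <- survivalOutcome(pmin(tt, cc), as.integer(tt <= cc))
  u <- marginalUtilities(g, y)
  uLoop <- vapply(seq_len(50),
                  function(k) fitMarginal(v[, k], y)@utility, numeric(1))
  expect_identical(u, uLoop)

  # permuting columns permutes utilities identically
  perm <- sample(50)
  expect_identical(marginalUtilities(v[, perm], y), u[perm])

  # single-column consistency
  expect_identical(marginalUtilities(v[, 3, drop = FALSE], y), u[3])
})

test_that("subsampled utilities are computed on the subsample only", {
  d <- smallSurvData(80, seed = 31)
  y <- survivalOutcome(d$time, d$event)
  rows <- 1:40
  u <- marginalUtilities(matrix(d$x), y, rows = rows)
  ySub <- survivalOutcome(d$time[rows], d$event[rows])
  expect_identical(u, marginalUtilities(matrix(d$x[rows]), ySub))
})

test_that("conditional utilities reduce, detect redundancy, and rank signal", {
  set.seed(12)
  g <- genGenotypes(100, 8, q = 0.3, seed = 21)
  v <- genoValues(g)
  tt <- rexp(100, exp(0.9 * v[, 1] + 0.9 * v[, 2]))
  cc <- runif(100, 0, 3)
  y <- survivalOutcome(pmin(tt, cc), as.integer(tt <= cc))

  # empty conditioning set reduces to marginal utilities
  u0 <- conditionalUtilities(g, y, integer(0))
  expect_equal(unname(u0), marginalUtilities(g, y), ignore_attr = TRUE)

  # a candidate duplicating a conditioning variable gains ~nothing
  vDup <- cbind(v, v[, 1])
  uD <- conditionalUtilities(vDup, y, conditioningSet = 1L)
  det <- conditionalUtilities(vDup, y, conditioningSet = 1L, details = TRUE)
  dupPos <- which(attr(uD, "candidates") == 9L)
  expect_lt(abs(uD[[dupPos]] - det$nullLogLik), 1e-6)

  # the true candidate outranks pure noise in nearly all replicates
  hits <- 0L
  for (r in 1:100) {
    gr <- genGenotypes(100, 7, q = 0.3, seed = 1000 + r)
    vr <- genoValues(gr)
    ttr <- rexp(100, exp(1.2 * vr[, 1] + 1.2 * vr[, 2]))
    ccr <- runif(100, 0, 3)
    yr <- survivalOutcome(pmin(ttr, ccr), as.integer(ttr <= ccr))
    ur <- conditionalUtilities(vr, yr, conditioningSet = 1L)
    cand <- attr(ur, "candidates")
    if (all(ur[[which(cand == 2L)]] > ur[cand != 2L])) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
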