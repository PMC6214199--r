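# Synthetic SNP-survival data: Hardy-Weinberg genotypes, signed true
# coefficients, Weibull failure times and uniform censoring calibrated to a
# target censoring rate.

#' Construct a simulation scenario
#'
#' @param n training sample size.
#' @param p number of variables.
#' @param pStar number of informative variables.
#' @param a signal-strength offset (1 = weak, 2 = strong).
#' @param tau Weibull shape parameter.
#' @param censRate target censoring proportion in \eqn{[0, 1)}.
#' @param maf minor allele frequency in \eqn{(0, 0.5]}.
#' @param seed integer RNG seed.
#' @param testN independent test-set size.
#' @return a [ScenarioConfig-class].
#' @examples
#' scenarioConfig(n = 300, p = 1000, a = 2, seed = 1)
#' @export
scenarioConfig <- function(n, p, pStar = 6L, a = 2, tau = 1.5,
                           censRate = 0.20, maf = 0.15, seed = 1L,
                           testN = 2000L) {
  new("ScenarioConfig",
      n = as.integer(n), p = as.integer(p), pStar = as.integer(pStar),
      a = as.numeric(a), tau = as.numeric(tau),
      censRate = as.numeric(censRate), maf = as.numeric(maf),
      seed = as.integer(seed), testN = as.integer(testN))
}

#' Construct a genotype matrix object
#'
#' @param values numeric matrix of genotype codes (samples by variants).
#' @param maf per-variant generating MAF, or NA when unknown.
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(values, maf = NA_real_) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("v%d", seq_len(ncol(values)))
  new("GenotypeMatrix", values = values, maf = as.numeric(maf))
}

#' Construct a survival outcome object
#'
#' @param time positive observed times.
#' @param event 0/1 event indicators.
#' @return a [SurvivalOutcome-class].
#' @export
survivalOutcome <- function(time, event) {
  new("SurvivalOutcome", time = as.numeric(time), event = as.integer(event))
}

#' Hardy-Weinberg genotype class probabilities
#'
#' For minor allele frequency \eqn{q}, the additive codes 0, 1, 2 occur with
#' probabilities \eqn{(1-q)^2}, \eqn{2q(1-q)}, \eqn{q^2}.
#'
#' @param q minor allele frequency in \eqn{(0, 0.5]}.
#' @return numeric vector of the three class probabilities.
#' @examples
#' hweProbs(0.15) # 0.7225 0.2550 0.0225
#' @export
hweProbs <- function(q) {
  stopifnot(is.numeric(q), q > 0, q <= 0.5)
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

#' Generate i.i.d. Hardy-Weinberg genotypes
#'
#' Draws an \code{n x p} matrix of additive genotype codes, each entry
#' independently multinomial with the [hweProbs()] class probabilities.
#'
#' @param n number of samples.
#' @param p number of variants.
#' @param q minor allele frequency.
#' @param seed integer seed; the draw is reproducible.
#' @return a [GenotypeMatrix-class] with integer codes.
#' @export
genGenotypes <- function(n, p, q = 0.15, seed = 1L) {
  stopifnot(n >= 1, p >= 1)
  pr <- hweProbs(q)
  set.seed(as.integer(seed))
  codes <- sample.int(3L, n * p, replace = TRUE, prob = pr) - 1L
  m <- matrix(codes, nrow = n, ncol = p)
  colnames(m) <- sprintf("v%d", seq_len(p))
  new("GenotypeMatrix", values = m, maf = rep(q, p))
}

#' Draw signed true coefficients
#'
#' Each informative coefficient is \eqn{(-1)^u (a + |z|)} with
#' \eqn{u \sim \mathrm{Bernoulli}(1/2)} and \eqn{z \sim N(0, 1)}, so every
#' nonzero coefficient has magnitude at least \code{a} and a random sign.
#'
#' @param pStar number of informative variables.
#' @param a positive signal-strength offset.
#' @param seed integer seed.
#' @param p total number of variables (the remaining \code{p - pStar}
#'   coefficients are zero); defaults to \code{pStar}.
#' @return a [TrueModel-class] whose informative variables are the first
#'   \code{pStar} columns.
#' @export
genBeta <- function(pStar = 6L, a = 1, seed = 1L, p = pStar) {
  stopifnot(a > 0, pStar >= 1, p >= pStar)
  set.seed(as.integer(seed))
  u <- stats::rbinom(pStar, 1L, 0.5)
  z <- stats::rnorm(pStar)
  b <- (-1)^u * (a + abs(z))
  beta <- numeric(p)
  beta[seq_len(pStar)] <- b
  new("TrueModel", beta = beta, informativeIdx = seq_len(as.integer(pStar)))
}

#' Fixed study coefficient vectors
#'
#' The two six-variable coefficient vectors used throughout the simulation
#' study, one draw per signal strength, kept fixed so every scenario is
#' reproducible.
#'
#' @param strength \code{"strong"} (offset a = 2) or \code{"weak"} (a = 1).
#' @param p total number of variables; the six informative coefficients
#'   occupy the first six positions.
#' @return a [TrueModel-class].
#' @examples
#' betaFixture("weak")
#' @export
betaFixture <- function(strength = c("strong", "weak"), p = 6L) {
  strength <- match.arg(strength)
  b <- switch(strength,
    strong = c(2.527186, 2.443898, 2.152147, -2.388758, 2.156502, -2.003314),
    weak   = c(1.036478, -1.073296, -1.250946, 1.138729, -1.128361, 1.145263)
  )
  stopifnot(p >= 6L)
  beta <- numeric(p)
  beta[1:6] <- b
  new("TrueModel", beta = beta, informativeIdx = 1:6)
}

# Linear predictor x'beta over the informative columns only (the rest are 0).
.trueLP <- function(X, model) {
  idx <- model@informativeIdx
  v <- genoValues(X)
  stopifnot(ncol(v) >= max(idx))
  as.vector(v[, idx, drop = FALSE] %*% model@beta[idx])
}

#' Generate Weibull proportional-hazards failure times
#'
#' Failure times follow the hazard
#' \eqn{h(t \mid x) = \tau t^{\tau-1} \exp\{\tau x'\beta\}}, i.e. cumulative
#' hazard \eqn{H(t \mid x) = t^\tau e^{\tau x'\beta}}, inverted as
#' \eqn{T = (-\log U)^{1/\tau} e^{-x'\beta}} for \eqn{U \sim U(0,1)}.
#'
#' @param X a [GenotypeMatrix-class] with at least
#'   \code{max(informativeIdx)} columns.
#' @param model a [TrueModel-class].
#' @param tau Weibull shape.
#' @param seed optional integer seed.
#' @return numeric vector of failure times.
#' @export
genFailureTimes <- function(X, model, tau = 1.5, seed = NULL) {
  stopifnot(tau > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lp <- .trueLP(X, model)
  u <- stats::runif(length(lp))
  (-log(u))^(1 / tau) * exp(-lp)
}

# P(T > C) for C ~ U(0, theta) and T Weibull with S(t|x) = exp(-lambda t^tau),
# lambda = exp(tau * x'beta). The inner integral has the closed form
# (1/theta) * lambda^(-1/tau)/tau * Gamma(1/tau) * pgamma(lambda theta^tau, 1/tau).
.pCensGivenTheta <- function(theta, lambda, weights, tau) {
  I <- lambda^(-1 / tau) / tau * gamma(1 / tau) *
    stats::pgamma(lambda * theta^tau, 1 / tau)
  sum(weights * I) / theta
}

#' Calibrate the uniform censoring bound
#'
#' Finds \eqn{\theta_c} such that, with censoring times
#' \eqn{C \sim U(0, \theta_c)} independent of the Weibull failure times, the
#' marginal censoring probability \eqn{P(T > C)} (expectation over the
#' Hardy-Weinberg genotype distribution of the informative variables) equals
#' the target rate. The achieved censoring probability is monotone
#' decreasing in \eqn{\theta_c}, so a bracketed root search is used.
#'
#' The default \code{"analytic"} mode sums the closed-form conditional
#' integral over all \eqn{3^{p^*}} informative-genotype combinations; the
#' \code{"mc"} mode replaces the genotype expectation with a large
#' fixed-seed Monte-Carlo sample (used when \eqn{p^*} is large).
#'
#' @param config a [ScenarioConfig-class] (uses \code{censRate}, \code{maf},
#'   \code{tau}).
#' @param model a [TrueModel-class].
#' @param method \code{"analytic"} or \code{"mc"}.
#' @param mcSize Monte-Carlo sample size for \code{method = "mc"}.
#' @param tol root-finding tolerance on the censoring probability.
#' @return the calibrated bound \eqn{\theta_c}.
#' @export
calibrateThetaC <- function(config, model, method = c("analytic", "mc"),
                            mcSize = 200000L, tol = 1e-10) {
  method <- match.arg(method)
  target <- config@censRate
  stopifnot(target > 0, target < 1)
  tau <- config@tau
  idx <- model@informativeIdx
  b <- model@beta[idx]
  pr <- hweProbs(config@maf)
  if (method == "analytic" && length(idx) <= 10L) {
    g <- as.matrix(expand.grid(rep(list(0:2), length(idx))))
    w <- apply(g, 1L, function(x) prod(pr[x + 1L]))
    lambda <- exp(tau * as.vector(g %*% b))
  } else {
    # fixed internal seed: the calibration itself is deterministic
    set.seed(761051L)
    g <- matrix(sample.int(3L, mcSize * length(idx), replace = TRUE,
                           prob = pr) - 1L, nrow = mcSize)
    w <- rep(1 / mcSize, mcSize)
    lambda <- exp(tau * as.vector(g %*% b))
  }
  f <- function(theta) .pCensGivenTheta(theta, lambda, w, tau) - target
  lo <- 1e-6
  hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 4
  if (f(hi) > 0)
    stop("censoring calibration: could not bracket the root; ",
         "achieved censoring at theta=", hi, " is ",
         signif(f(hi) + target, 4))
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# Independent sub-seeds for the generator components, derived from the
# scenario seed so each component is reproducible in isolation.
.subSeeds <- function(seed) {
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 7L)
  names(s) <- c("geno", "beta", "fail", "cens",
                "testGeno", "testFail", "testCens")
  s
}

.genArm <- function(n, config, model, thetaC, seeds) {
  geno <- genGenotypes(n, config@p, config@maf, seed = seeds[1])
  Tt <- genFailureTimes(geno, model, tau = config@tau, seed = seeds[2])
  set.seed(as.integer(seeds[3]))
  Cc <- stats::runif(n, 0, thetaC)
  list(geno = geno,
       outcome = survivalOutcome(pmin(Tt, Cc), as.integer(Tt <= Cc)),
       failureTime = Tt)
}

#' Generate a complete scenario dataset
#'
#' Draws the training data (and, on request, an independent test set from
#' the same joint distribution and the same true model). Genotypes, true
#' coefficients, failure times and censoring times come from independent
#' sub-streams derived from the scenario seed. The censoring bound is
#' calibrated once per scenario unless supplied.
#'
#' @param config a [ScenarioConfig-class].
#' @param model optional [TrueModel-class]; by default the fixed study
#'   coefficient vector for the scenario's signal strength
#'   (\code{a = 2} strong, otherwise weak) when \code{pStar = 6}, else a
#'   fresh [genBeta()] draw.
#' @param thetaC optional pre-calibrated censoring bound.
#' @param includeTest also generate the independent test set of size
#'   \code{testN}.
#' @return a list with elements \code{train} (and \code{test}) each holding
#'   \code{geno}, \code{outcome} and the latent \code{failureTime}, plus
#'   \code{model}, \code{thetaC} and \code{config}.
#' @examples
#' d <- genDataset(scenarioConfig(n = 60, p = 20, seed = 7))
#' d$train$outcome
#' @export
genDataset <- function(config, model = NULL, thetaC = NULL,
                       includeTest = FALSE) {
  seeds <- .subSeeds(config@seed)
  if (is.null(model)) {
    model <- if (config@pStar == 6L && config@a %in% c(1, 2)) {
      betaFixture(if (config@a == 2) "strong" else "weak", p = config@p)
    } else {
      genBeta(config@pStar, config@a, seed = seeds["beta"], p = config@p)
    }
  }
  if (is.null(thetaC)) thetaC <- calibrateThetaC(config, model)
  out <- list(
    train = .genArm(config@n, config, model, thetaC,
                    seeds[c("geno", "fail", "cens")]),
    model = model, thetaC = thetaC, config = config
  )
  if (includeTest) {
    out$test <- .genArm(config@testN, config, model, thetaC,
                        seeds[c("testGeno", "testFail", "testCens")])
  }
  out
}
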