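# Model-performance metrics: Harrell's concordance for discrimination, the
# IPCW Brier-score R^2 for overall performance at a horizon, the
# calibration slope and quartile calibration table, and Harrell-style
# bootstrap optimism correction.

#' Harrell's concordance index
#'
#' Proportion of concordant pairs among comparable pairs. A pair is
#' comparable when the smaller observed time belongs to an event (pairs
#' with tied observed event times are not comparable); it is concordant
#' when the subject with the shorter survival carries the larger risk
#' score, and predictor ties count one half.
#'
#' @param lp risk scores (higher = shorter expected survival).
#' @param outcome a [SurvivalOutcome-class].
#' @return the c-index in \eqn{[0, 1]}.
#' @examples
#' y <- survivalOutcome(1:4, rep(1, 4))
#' harrellC(c(4, 3, 1, 2), y) # 5/6
#' @export
harrellC <- function(lp, outcome) {
  t <- obsTime(outcome)
  d <- eventStatus(outcome)
  n <- length(t)
  stopifnot(length(lp) == n)
  evIdx <- which(d == 1L)
  conc <- 0
  comp <- 0
  block <- 256L
  for (start in seq(1L, length(evIdx), by = block)) {
    ii <- evIdx[start:min(start + block - 1L, length(evIdx))]
    later <- outer(t[ii], t, "<") # strictly later observed time
    nComp <- rowSums(later)
    gt <- outer(lp[ii], lp, ">") & later
    eq <- outer(lp[ii], lp, "==") & later
    comp <- comp + sum(nComp)
    conc <- conc + sum(gt) + 0.5 * sum(eq)
  }
  if (comp == 0) stop("no comparable pairs; c-index undefined")
  conc / comp
}

# Reverse Kaplan-Meier of the censoring distribution, with right-continuous
# evaluation G(t) and left-limit evaluation G(t-).
.censoringKM <- function(outcome) {
  t <- obsTime(outcome)
  d <- eventStatus(outcome)
  g <- survival::survfit(survival::Surv(t, 1 - d) ~ 1)
  list(
    at = function(x) .stepAt(x, g$time, g$surv, 1),
    atMinus = function(x) {
      i <- findInterval(x, g$time, left.open = TRUE)
      c(1, g$surv)[i + 1L]
    }
  )
}

#' Brier-score R-squared at a horizon
#'
#' \eqn{R^2_{BS}(t^*) = 1 - BS_{model}(t^*) / BS_{null}(t^*)}, where the
#' Brier scores are inverse-probability-of-censoring weighted: subjects
#' with an event by \eqn{t^*} contribute \eqn{\hat S(t^*|x)^2 / G(t_i^-)},
#' subjects still under observation at \eqn{t^*} contribute
#' \eqn{(1 - \hat S(t^*|x))^2 / G(t^*)}, and subjects censored before
#' \eqn{t^*} contribute through the weights alone. \eqn{G} is the reverse
#' Kaplan-Meier of the censoring distribution on the evaluation set; the
#' null model predicts the marginal Kaplan-Meier survival at \eqn{t^*} for
#' everyone. Positive values mean the model beats the null model; negative
#' values mean it does worse.
#'
#' @param predSurv predicted survival probabilities at \code{tStar}, in
#'   \eqn{[0, 1]}.
#' @param outcome a [SurvivalOutcome-class].
#' @param tStar evaluation horizon.
#' @return \eqn{R^2_{BS}(t^*)} (at most 1; may be negative).
#' @export
brierR2 <- function(predSurv, outcome, tStar = 2) {
  stopifnot(all(predSurv >= 0 & predSurv <= 1))
  t <- obsTime(outcome)
  d <- eventStatus(outcome)
  n <- length(t)
  stopifnot(length(predSurv) == n)
  if (!any(t >= tStar))
    stop("no subjects at risk at the horizon; Brier score undefined")
  G <- .censoringKM(outcome)
  Gt <- G$at(tStar)
  if (Gt <= 0)
    stop("censoring survival is zero at the horizon; weights undefined")
  km <- survival::survfit(asSurv(outcome) ~ 1)
  sNull <- .stepAt(tStar, km$time, km$surv, 1)

  ipcwBS <- function(s) {
    died <- t <= tStar & d == 1L
    alive <- t > tStar
    w <- numeric(n)
    w[died] <- 1 / G$atMinus(t[died])
    w[alive] <- 1 / Gt
    contrib <- numeric(n)
    contrib[died] <- s[died]^2
    contrib[alive] <- (1 - s[alive])^2
    sum(w * contrib) / n
  }
  bs0 <- ipcwBS(rep(sNull, n))
  if (bs0 == 0) stop("null-model Brier score is zero; R2 undefined")
  1 - ipcwBS(predSurv) / bs0
}

#' Calibration slope
#'
#' The coefficient of the prognostic index in a proportional-hazards
#' regression of new (test) outcomes on that single covariate. A slope of 1
#' indicates agreement between predicted and observed risk ordering
#' magnitudes; slopes below 1 indicate overfitting of the training model.
#'
#' @param lp the prognostic index evaluated on the test subjects (from
#'   [prognosticIndex()]).
#' @param outcome the test [SurvivalOutcome-class].
#' @return the calibration slope.
#' @export
calibrationSlope <- function(lp, outcome) {
  if (stats::sd(lp) == 0)
    stop("prognostic index is constant; calibration slope undefined")
  f <- survival::coxph(asSurv(outcome) ~ lp, ties = "breslow")
  unname(stats::coef(f))
}

#' Quartile calibration table
#'
#' Subjects are split into quartiles of predicted survival at the horizon
#' (ranked; bin 1 = lowest predicted survival, i.e. highest risk); each bin
#' reports the mean predicted survival and the observed (Kaplan-Meier)
#' survival at the horizon. A bin with nobody under observation at the
#' horizon is flagged with \code{NA} observed survival. The table is
#' plot-ready for an observed-versus-predicted calibration figure.
#'
#' @param predSurv predicted survival probabilities at \code{tStar}.
#' @param outcome a [SurvivalOutcome-class].
#' @param tStar horizon.
#' @return data.frame with columns \code{bin}, \code{n},
#'   \code{meanPredicted}, \code{observed}.
#' @export
calibrationQuartiles <- function(predSurv, outcome, tStar = 2) {
  n <- length(predSurv)
  stopifnot(n >= 8L)
  ord <- order(predSurv)
  grp <- integer(n)
  grp[ord] <- ceiling(4 * seq_len(n) / n)
  t <- obsTime(outcome)
  d <- eventStatus(outcome)
  rows <- lapply(1:4, function(g) {
    i <- which(grp == g)
    obs <- NA_real_
    if (any(t[i] >= tStar)) {
      km <- survival::survfit(survival::Surv(t[i], d[i]) ~ 1)
      obs <- .stepAt(tStar, km$time, km$surv, 1)
    }
    data.frame(bin = g, n = length(i),
               meanPredicted = mean(predSurv[i]), observed = obs)
  })
  do.call(rbind, rows)
}

#' Bootstrap optimism of the c-index
#'
#' Harrell-style internal validation: the full screening + selection +
#' refit pipeline is repeated on each bootstrap resample; the optimism is
#' the mean excess of the resample c-index over the c-index of the
#' resample-trained model applied to the original data, and is subtracted
#' from the apparent c-index. Resamples where the pipeline fails are
#' dropped and counted; more than 20\% failures is an error.
#'
#' @param X original [GenotypeMatrix-class] or matrix.
#' @param outcome original [SurvivalOutcome-class].
#' @param pipeline function \code{(X, outcome, seed) -> "survscreenFit"}.
#' @param B number of bootstrap resamples.
#' @param seed integer seed (resampling and pipeline seeds derive from it).
#' @return list with \code{optimism}, \code{cApparent}, \code{cCorrected}
#'   and \code{nFailed}.
#' @export
bootstrapOptimism <- function(X, outcome, pipeline, B = 100L, seed = 1L) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  n <- nrow(v)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, B + 1L)
  fitFull <- pipeline(v, outcome, seeds[B + 1L])
  cApp <- harrellC(prognosticIndex(fitFull, v), outcome)
  opt <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      yb <- survivalOutcome(obsTime(outcome)[idx], eventStatus(outcome)[idx])
      fb <- pipeline(v[idx, , drop = FALSE], yb, seeds[b])
      cBoot <- harrellC(prognosticIndex(fb, v[idx, , drop = FALSE]), yb)
      cOrig <- harrellC(prognosticIndex(fb, v), outcome)
      cBoot - cOrig
    }, error = function(e) NA_real_)
    opt[b] <- res
  }
  nFailed <- sum(is.na(opt))
  if (nFailed > 0.2 * B)
    stop("bootstrap validation failed on ", nFailed, " of ", B,
         " resamples")
  optimism <- mean(opt, na.rm = TRUE)
  list(optimism = optimism, cApparent = cApp,
       cCorrected = cApp - optimism, nFailed = nFailed)
}

#' Evaluate a fitted model on a dataset
#'
#' Convenience wrapper producing an [EvalReport-class]: c-index from the
#' prognostic index, Brier-score R-squared and quartile calibration from
#' the predicted survival at the horizon, and the calibration slope. For a
#' null model (empty selection) the report records the null conventions:
#' c-index 0.5, \eqn{R^2_{BS}} 0, undefined slope.
#'
#' @param fit a \code{"survscreenFit"}.
#' @param X evaluation covariates.
#' @param outcome evaluation [SurvivalOutcome-class].
#' @param tStar horizon.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(fit, X, outcome, tStar = 2) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  lp <- prognosticIndex(fit, v)
  ps <- pmin(pmax(predictSurvival(fit, v, tStar), 0), 1)
  if (fit$null || stats::sd(lp) == 0) {
    cI <- 0.5
    slope <- NA_real_
    r2 <- 0
  } else {
    cI <- harrellC(lp, outcome)
    slope <- calibrationSlope(lp, outcome)
    r2 <- brierR2(ps, outcome, tStar)
  }
  new("EvalReport", cIndex = cI, r2bs = r2, calSlope = slope,
      calTable = calibrationQuartiles(ps, outcome, tStar),
      optimism = NA_real_, cCorrected = NA_real_)
}
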