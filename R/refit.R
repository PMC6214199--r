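# Post-selection prediction layer: an unpenalized proportional-hazards
# refit on the selected variables supplies the prognostic index, and the
# Breslow baseline cumulative hazard from the training fit supplies
# predicted survival probabilities at a horizon. An empty selection yields
# the null model (marginal Kaplan-Meier predictions, zero prognostic index).

#' Refit a proportional-hazards model on a selected set
#'
#' @param X training [GenotypeMatrix-class] or matrix.
#' @param outcome training [SurvivalOutcome-class].
#' @param sel integer indices of the selected columns; empty gives the null
#'   model.
#' @return an object of class \code{"survscreenFit"} holding the selected
#'   indices, refit coefficients, the Breslow baseline cumulative hazard
#'   and the training Kaplan-Meier curve (for null predictions).
#' @export
coxRefit <- function(X, outcome, sel) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  sel <- sort(as.integer(sel))
  y <- asSurv(outcome)
  km <- survival::survfit(y ~ 1)
  fit <- list(selected = sel, km = list(time = km$time, surv = km$surv))
  if (length(sel) == 0L) {
    fit$null <- TRUE
    fit$coef <- numeric(0)
  } else {
    m <- v[, sel, drop = FALSE]
    cf <- survival::coxph(y ~ m, ties = "breslow")
    beta <- as.numeric(stats::coef(cf))
    beta[is.na(beta)] <- 0 # aliased columns drop out of the index
    bh <- survival::basehaz(cf, centered = FALSE)
    fit$null <- FALSE
    fit$coef <- stats::setNames(beta, colnames(v)[sel])
    fit$baseline <- list(time = bh$time, hazard = bh$hazard)
  }
  class(fit) <- "survscreenFit"
  fit
}

#' @export
print.survscreenFit <- function(x, ...) {
  if (x$null) cat("survscreenFit: null model (no variables)\n")
  else cat(sprintf("survscreenFit: %d variables, coefficients %s\n",
                   length(x$selected),
                   paste(signif(x$coef, 4), collapse = ", ")))
  invisible(x)
}

#' Prognostic index of a refit model
#'
#' @param fit a \code{"survscreenFit"} from [coxRefit()].
#' @param X a [GenotypeMatrix-class] or matrix with the same columns as the
#'   training data.
#' @return the linear predictor \eqn{x'\hat\beta} (zero for the null model).
#' @export
prognosticIndex <- function(fit, X) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  if (fit$null) return(numeric(nrow(v)))
  as.vector(v[, fit$selected, drop = FALSE] %*% fit$coef)
}

# Right-continuous step lookup: value of (times, values) step function at t,
# with the given value before the first jump.
.stepAt <- function(t, times, values, before) {
  i <- findInterval(t, times)
  c(before, values)[i + 1L]
}

#' Predicted survival probabilities at a horizon
#'
#' For a fitted model, \eqn{\hat S(t^* \mid x) = \exp\{-\hat H_0(t^*)
#' e^{x'\hat\beta}\}} using the Breslow baseline from the training fit; for
#' the null model, the training Kaplan-Meier survival at \eqn{t^*} for
#' every subject.
#'
#' @param fit a \code{"survscreenFit"}.
#' @param X covariates of the subjects to predict.
#' @param tStar horizon.
#' @return numeric vector of predicted survival probabilities.
#' @export
predictSurvival <- function(fit, X, tStar = 2) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  if (fit$null) {
    s <- .stepAt(tStar, fit$km$time, fit$km$surv, 1)
    return(rep(s, nrow(v)))
  }
  H0 <- .stepAt(tStar, fit$baseline$time, fit$baseline$hazard, 0)
  lp <- prognosticIndex(fit, v)
  exp(-H0 * exp(lp))
}
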