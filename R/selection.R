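# Final-model variable selection: L1-penalized Cox (LASSO), adaptively
# weighted L1 (ALASSO), and random-survival-forest minimal-depth
# thresholding. The penalized paths are fitted by glmnet, which maximizes
# (2/n) l(beta) - lambda P_alpha(W, beta) with alpha = 1; W = I for LASSO
# and W = diag(1/|beta~|) for ALASSO.

# Stratified CV fold assignment: events and censored rows are spread across
# folds separately so every fold sees events.
.cvFoldid <- function(event, nFolds, seed) {
  set.seed(as.integer(seed))
  fid <- integer(length(event))
  ev <- event == 1L
  fid[ev] <- sample(rep(seq_len(nFolds), length.out = sum(ev)))
  fid[!ev] <- sample(rep(seq_len(nFolds), length.out = sum(!ev)))
  fid
}

# Path resolution: glmnet defaults for reduced inputs; a coarser 50-value
# path down to 0.05*lambda_max for high-dimensional (p >= 1000) fits.
.pathArgs <- function(p, nlambda, lambdaMinRatio) {
  if (is.null(nlambda)) nlambda <- if (p >= 1000L) 50L else 100L
  args <- list(nlambda = nlambda)
  if (!is.null(lambdaMinRatio)) args$lambda.min.ratio <- lambdaMinRatio
  else if (p >= 1000L) args$lambda.min.ratio <- 0.05
  args
}

.penalizedCox <- function(X, outcome, nFolds, seed, penaltyFactor,
                          method, meta = list(),
                          nlambda = NULL, lambdaMinRatio = NULL) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  n <- nrow(v)
  p <- ncol(v)
  ev <- eventStatus(outcome)
  if (sum(ev) < nFolds)
    stop("need at least nFolds (", nFolds, ") events; got ", sum(ev))
  if (p == 0L)
    return(new("SelectionResult", selected = integer(0),
               coefficients = numeric(0), lambdaChosen = NA_real_,
               depthThreshold = NA_real_, method = method, meta = meta))
  if (p == 1L) {
    # glmnet needs >= 2 columns; retain the single candidate at its MPLE
    f <- fitMarginal(v[, 1], outcome)
    return(new("SelectionResult", selected = 1L,
               coefficients = stats::setNames(f@betaHat,
                                              colnames(v) %||% "v1"),
               lambdaChosen = NA_real_, depthThreshold = NA_real_,
               method = method, meta = c(meta, list(degeneratePath = TRUE))))
  }
  fid <- .cvFoldid(ev, nFolds, seed)
  y <- asSurv(outcome)
  if (is.null(penaltyFactor)) penaltyFactor <- rep(1, p)
  pa <- .pathArgs(p, nlambda, lambdaMinRatio)
  cv <- do.call(glmnet::cv.glmnet,
                c(list(x = v, y = y, family = "cox", foldid = fid,
                       penalty.factor = penaltyFactor,
                       type.measure = "deviance"), pa))
  co <- as.vector(stats::coef(cv, s = "lambda.min"))
  sel <- which(co != 0)
  new("SelectionResult",
      selected = as.integer(sel),
      coefficients = stats::setNames(co[sel], colnames(v)[sel]),
      lambdaChosen = cv$lambda.min,
      depthThreshold = NA_real_, method = method, meta = meta)
}

#' LASSO-penalized Cox selection
#'
#' L1-penalized Cox path with the penalty value chosen to minimize the
#' 10-fold cross-validated partial-likelihood deviance; variables with
#' nonzero coefficients at that penalty are selected. Columns are
#' standardized inside the solver and coefficients returned on the original
#' scale. An empty active set at the chosen penalty is a valid (empty)
#' selection.
#'
#' @param X a [GenotypeMatrix-class] or numeric matrix (the screened or
#'   full candidate set).
#' @param outcome a [SurvivalOutcome-class].
#' @param nFolds number of cross-validation folds (stratified by event
#'   status, seeded).
#' @param seed integer seed for fold assignment.
#' @param nlambda,lambdaMinRatio optional penalty-path resolution overrides.
#' @return a [SelectionResult-class].
#' @export
lassoCox <- function(X, outcome, nFolds = 10L, seed = 1L,
                     nlambda = NULL, lambdaMinRatio = NULL) {
  .penalizedCox(X, outcome, nFolds, seed, penaltyFactor = NULL,
                method = "LASSO", nlambda = nlambda,
                lambdaMinRatio = lambdaMinRatio)
}

#' Adaptive-LASSO-penalized Cox selection
#'
#' As [lassoCox()] but with per-coefficient penalty weights
#' \eqn{w_k = 1/|\tilde\beta_k|}. The initial estimate \eqn{\tilde\beta} is
#' the joint unpenalized MPLE of the reduced model when the input is low
#' dimensional (\eqn{p < n/2}); otherwise the marginal (univariate) MPLEs
#' keep the weights defined at any \eqn{p}. The weight source is recorded
#' in the result metadata.
#'
#' @inheritParams lassoCox
#' @param weights optional user initial estimates \eqn{\tilde\beta}
#'   (reciprocals become the penalty weights).
#' @return a [SelectionResult-class].
#' @export
alassoCox <- function(X, outcome, nFolds = 10L, seed = 1L, weights = NULL,
                      nlambda = NULL, lambdaMinRatio = NULL) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  n <- nrow(v)
  p <- ncol(v)
  src <- "user"
  if (is.null(weights) && p > 0L) {
    if (p < n / 2) {
      bt <- tryCatch(
        suppressWarnings(stats::coef(
          survival::coxph(asSurv(outcome) ~ v, ties = "breslow"))),
        error = function(e) NULL)
      if (!is.null(bt) && !anyNA(bt)) {
        weights <- as.numeric(bt)
        src <- "jointMPLE"
      }
    }
    if (is.null(weights)) {
      weights <- marginalUtilities(v, outcome, details = TRUE)$beta
      src <- "marginalMPLE"
    }
  }
  pf <- 1 / abs(weights)
  pf[!is.finite(pf)] <- 1e8 # degenerate/zero initial estimates: excluded
  .penalizedCox(v, outcome, nFolds, seed, penaltyFactor = pf,
                method = "ALASSO", meta = list(weightsFrom = src),
                nlambda = nlambda, lambdaMinRatio = lambdaMinRatio)
}
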