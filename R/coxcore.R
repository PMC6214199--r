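# Vectorized univariate Cox partial-likelihood engine. Marginal utilities
# over tens of thousands of columns are the inner loop of the screening
# layer, so the Newton iteration is vectorized across columns with an
# active-set scheme and a step-halving safeguard. Risk sets follow
# R(y_i) = {j : y_j >= y_i}; ties use the Breslow convention.

# Column-wise cumulative sums of a matrix via a single cumsum over the
# column-major vector, correcting each column by the previous column totals.
.colCumsum <- function(M) {
  n <- nrow(M)
  cs <- matrix(cumsum(M), nrow = n)
  if (ncol(cs) > 1L)
    cs <- cs - rep(c(0, cs[n, -ncol(cs)]), each = n)
  cs
}

# Shared risk-set geometry: rows sorted by decreasing time so the risk set
# of the event at sorted position i is rows 1..riskEnd[i] (riskEnd extends
# over tied times).
.riskGeometry <- function(time, event) {
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  n <- length(ts)
  idx <- seq_len(n)
  riskEnd <- stats::ave(idx, match(ts, unique(ts)), FUN = max)
  list(ord = ord, riskEnd = riskEnd, evPos = which(event[ord] == 1L))
}

#' Cox log partial likelihood
#'
#' Evaluates the log partial likelihood
#' \deqn{l(\beta) = \sum_i \delta_i x_i'\beta -
#'   \sum_i \delta_i \log \sum_{j \in R(y_i)} e^{x_j'\beta}}
#' with risk sets \eqn{R(y_i) = \{j : y_j \ge y_i\}} and Breslow handling of
#' ties. \code{x} may be a single covariate vector or a matrix whose columns
#' match \code{beta}.
#'
#' @param x covariate vector or n-by-k matrix.
#' @param outcome a [SurvivalOutcome-class].
#' @param beta coefficient(s), length equal to \code{ncol(x)}.
#' @param offset optional per-subject linear offset.
#' @return the scalar log partial likelihood.
#' @examples
#' y <- survivalOutcome(c(1, 2), c(1, 1))
#' coxLogPL(c(1, 0), y, 1)  # 1 - log(1 + e)
#' @export
coxLogPL <- function(x, outcome, beta, offset = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(obsTime(outcome)) == n, length(beta) == ncol(x))
  if (sum(eventStatus(outcome)) == 0L)
    stop("degenerate input: no events in the outcome")
  if (is.null(offset)) offset <- numeric(n)
  lp <- as.vector(x %*% beta) + offset
  geom <- .riskGeometry(obsTime(outcome), eventStatus(outcome))
  lps <- lp[geom$ord]
  ev <- geom$evPos
  S0 <- cumsum(exp(lps))[geom$riskEnd[ev]]
  sum(lps[ev]) - sum(log(S0))
}

# Fast path for three-level (genotype-coded) covariates. Because x only
# takes the values 0, 1, 2, the risk-set sums factor as
#   S0(i) = A0(i) + A1(i) e^b + A2(i) e^{2b},
#   S1(i) =         A1(i) e^b + 2 A2(i) e^{2b},
#   S2(i) =         A1(i) e^b + 4 A2(i) e^{2b},
# where A_k(i) is the cumulative offset-weight of the risk set's class-k
# members. The A_k are fixed across Newton iterations, so after one
# cumulative-sum precomputation every iteration is elementwise arithmetic
# with a single exponential per column.
.engineCore3 <- function(Xs, off, ev, evRE, act0, l0, tol, maxIter, cap,
                         trace, p) {
  n <- nrow(Xs)
  w0 <- exp(off)
  A0 <- .colCumsum(w0 * (Xs == 0))[evRE, , drop = FALSE]
  A1 <- .colCumsum(w0 * (Xs == 1))[evRE, , drop = FALSE]
  A2 <- .colCumsum(w0 * (Xs == 2))[evRE, , drop = FALSE]
  sx <- colSums(Xs[ev, , drop = FALSE])
  offEv <- sum(off[ev])
  nev <- length(ev)

  beta <- numeric(p)
  conv <- rep(TRUE, p)
  info <- numeric(p)
  traj <- if (trace) rep(list(l0), p) else NULL
  lAcc <- rep(l0, p)
  bAcc <- numeric(p)
  maxHalf <- 30L
  halved <- integer(p)
  act <- act0
  it <- 0L
  while (length(act) && it < maxIter + maxHalf) {
    it <- it + 1L
    ba <- beta[act]
    e1 <- rep(exp(ba), each = nev)
    e2 <- rep(exp(2 * ba), each = nev)
    T1 <- A1[, act, drop = FALSE] * e1
    T2 <- A2[, act, drop = FALSE] * e2
    S0 <- A0[, act, drop = FALSE] + T1 + T2
    r <- (T1 + 2 * T2) / S0
    lcur <- sx[act] * ba + offEv - colSums(log(S0))
    score <- sx[act] - colSums(r)
    ii <- colSums((T1 + 4 * T2) / S0 - r * r)

    lcur[!is.finite(lcur)] <- -Inf # overflow guard: reject the step
    worse <- (lcur < lAcc[act] - 1e-12) & (halved[act] < maxHalf)
    good <- !worse & is.finite(score) & is.finite(ii)
    gi <- act[good]
    lAcc[gi] <- lcur[good]
    bAcc[gi] <- ba[good]
    info[gi] <- ii[good]
    halved[gi] <- 0L
    if (trace) for (j in which(good)) {
      k <- act[j]
      traj[[k]] <- c(traj[[k]], lcur[j])
    }
    done <- good & (abs(score) < tol)
    atCap <- good & !done & (abs(ba) >= cap) & (sign(score) == sign(ba))
    conv[act[atCap]] <- FALSE
    wi <- which(worse)
    beta[act[wi]] <- (beta[act[wi]] + bAcc[act[wi]]) / 2
    halved[act[wi]] <- halved[act[wi]] + 1L
    mi <- which(good & !done & !atCap)
    beta[act[mi]] <- pmin(pmax(ba[mi] + score[mi] /
                                 pmax(ii[mi], 1e-12), -cap), cap)
    act <- act[!(done | atCap)]
  }
  conv[act] <- FALSE
  list(beta = bAcc, lAcc = lAcc, info = info, conv = conv, traj = traj)
}

# The vectorized engine. Returns per-column MPLE, utility, observed
# information, the shared null log partial likelihood, and flags.
#
# One fused pass per Newton iteration computes, for every active column,
# the log partial likelihood at the current iterate together with the
# score and observed information, so the step-halving safeguard costs no
# extra likelihood evaluations: a step that lowered the likelihood is
# detected on the next pass, reverted halfway, and retried. The accepted
# trajectory is therefore non-decreasing. Converged columns leave the
# active set; monotone likelihoods are clamped at +/- cap and flagged.
.marginalEngine <- function(X, time, event, offset = NULL,
                            tol = 1e-8, maxIter = 50L, cap = 15,
                            trace = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(time) == n)
  if (sum(event) == 0L) stop("degenerate input: no events")
  if (is.null(offset)) offset <- numeric(n)
  geom <- .riskGeometry(time, event)
  Xs <- X[geom$ord, , drop = FALSE]
  # centring the offset leaves every log partial likelihood unchanged but
  # keeps exp(offset) away from overflow when a conditioning fit diverged
  off <- offset[geom$ord]
  off <- off - mean(off)
  ev <- geom$evPos
  rEnd <- geom$riskEnd
  evRE <- rEnd[ev]

  degenerate <- colSums(Xs != rep(Xs[1L, ], each = n)) == 0L
  l0 <- sum(off[ev]) - sum(log(cumsum(exp(off))[evRE]))
  act0 <- which(!degenerate)
  threeLevel <- all(Xs == 0 | Xs == 1 | Xs == 2)
  core <- if (threeLevel) .engineCore3 else .engineCoreGen
  r <- core(Xs, off, ev, evRE, act0, l0, tol, maxIter, cap, trace, p)
  util <- r$lAcc
  util[degenerate] <- l0
  beta <- r$beta
  beta[degenerate] <- 0
  info <- r$info
  info[degenerate] <- 0
  list(beta = beta, utility = util, information = info,
       nullLogLik = l0, degenerate = degenerate, converged = r$conv,
       trace = r$traj)
}

# Generic-covariate core: same iteration scheme as .engineCore3 but with
# the risk-set sums recomputed by cumulative sums at every iteration.
.engineCoreGen <- function(Xs, off, ev, evRE, act0, l0, tol, maxIter, cap,
                           trace, p) {
  n <- nrow(Xs)
  beta <- numeric(p)
  conv <- rep(TRUE, p)
  info <- numeric(p)
  traj <- if (trace) rep(list(l0), p) else NULL
  lAcc <- rep(l0, p)
  bAcc <- numeric(p)
  maxHalf <- 30L
  halved <- integer(p)
  act <- act0
  it <- 0L
  while (length(act) && it < maxIter + maxHalf) {
    it <- it + 1L
    Xa <- Xs[, act, drop = FALSE]
    ba <- beta[act]
    E <- exp(Xa * rep(ba, each = n) + off)
    XE <- Xa * E
    S0 <- .colCumsum(E)[evRE, , drop = FALSE]
    S1 <- .colCumsum(XE)[evRE, , drop = FALSE]
    S2 <- .colCumsum(Xa * XE)[evRE, , drop = FALSE]
    r <- S1 / S0
    lcur <- colSums(Xa[ev, , drop = FALSE] * rep(ba, each = length(ev))) +
      sum(off[ev]) - colSums(log(S0))
    score <- colSums(Xa[ev, , drop = FALSE]) - colSums(r)
    ii <- colSums(S2 / S0 - r * r)

    lcur[!is.finite(lcur)] <- -Inf # overflow guard: reject the step
    worse <- (lcur < lAcc[act] - 1e-12) & (halved[act] < maxHalf)
    good <- !worse & is.finite(score) & is.finite(ii)
    gi <- act[good]
    lAcc[gi] <- lcur[good]
    bAcc[gi] <- ba[good]
    info[gi] <- ii[good]
    halved[gi] <- 0L
    if (trace) for (j in which(good)) {
      k <- act[j]
      traj[[k]] <- c(traj[[k]], lcur[j])
    }
    done <- good & (abs(score) < tol)
    atCap <- good & !done & (abs(ba) >= cap) & (sign(score) == sign(ba))
    conv[act[atCap]] <- FALSE
    # overshooting columns retreat halfway towards the accepted iterate
    wi <- which(worse)
    beta[act[wi]] <- (beta[act[wi]] + bAcc[act[wi]]) / 2
    halved[act[wi]] <- halved[act[wi]] + 1L
    mi <- which(good & !done & !atCap)
    beta[act[mi]] <- pmin(pmax(ba[mi] + score[mi] /
                                 pmax(ii[mi], 1e-12), -cap), cap)
    act <- act[!(done | atCap)]
  }
  conv[act] <- FALSE # ran out of iterations
  list(beta = bAcc, lAcc = lAcc, info = info, conv = conv, traj = traj)
}

#' Fit the marginal Cox model for one covariate
#'
#' Newton-Raphson maximization of the univariate log partial likelihood with
#' step-halving (the accepted likelihood trajectory is non-decreasing) and
#' the estimate capped at \code{cap} to tame monotone likelihoods. A
#' constant covariate is degenerate by convention: \eqn{\hat\beta = 0},
#' utility equal to the null log partial likelihood, zero information.
#'
#' @param x covariate vector.
#' @param outcome a [SurvivalOutcome-class].
#' @param offset optional fixed linear offset (used by the conditional
#'   utilities of iterative screening).
#' @param tol convergence tolerance on the score.
#' @param maxIter maximum Newton iterations.
#' @param cap bound on \eqn{|\hat\beta|}.
#' @return a [MarginalFit-class]; the accepted log-partial-likelihood
#'   trajectory is attached as attribute \code{"trace"}.
#' @export
fitMarginal <- function(x, outcome, offset = NULL, tol = 1e-8,
                        maxIter = 50L, cap = 15) {
  r <- .marginalEngine(matrix(as.numeric(x), ncol = 1L),
                       obsTime(outcome), eventStatus(outcome),
                       offset = offset, tol = tol, maxIter = maxIter,
                       cap = cap, trace = TRUE)
  fit <- new("MarginalFit",
             betaHat = r$beta[1], utility = r$utility[1],
             information = r$information[1],
             converged = r$converged[1] && !r$degenerate[1],
             nullLogLik = r$nullLogLik)
  attr(fit, "trace") <- r$trace[[1]]
  fit
}

#' Marginal utilities for every column
#'
#' Computes the maximized univariate log partial likelihood \eqn{u_k} for
#' each column of the genotype matrix, optionally on a row subsample (a
#' screening partition). Vectorized across columns; column-for-column
#' identical to [fitMarginal()].
#'
#' Degenerate columns (constant within the subsample) are assigned the null
#' log partial likelihood so they rank last, never raising an error during
#' screening.
#'
#' @param X a [GenotypeMatrix-class] or numeric matrix.
#' @param outcome a [SurvivalOutcome-class] for all rows of \code{X}.
#' @param rows optional integer subset of rows (partition).
#' @param offset optional per-subject offset, aligned with \code{rows} after
#'   subsetting (length \code{length(rows)}) or with all rows.
#' @param details return the full list (beta, information, flags) instead of
#'   just the utility vector.
#' @return numeric vector \eqn{u_k} over all columns, or a detail list when
#'   \code{details = TRUE}.
#' @export
marginalUtilities <- function(X, outcome, rows = NULL, offset = NULL,
                              details = FALSE) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  time <- obsTime(outcome)
  event <- eventStatus(outcome)
  if (!is.null(rows)) {
    v <- v[rows, , drop = FALSE]
    if (!is.null(offset) && length(offset) == length(time))
      offset <- offset[rows]
    time <- time[rows]
    event <- event[rows]
  }
  r <- .marginalEngine(v, time, event, offset = offset)
  if (details) r else r$utility
}

#' Conditional utilities given an already-selected set
#'
#' For iterative screening: the conditioning set is fitted once (an
#' unpenalized proportional-hazards fit on the subsample) and its linear
#' predictor is frozen as an offset; each remaining candidate's utility is
#' then the maximized log partial likelihood of the offset model plus that
#' single candidate. A joint-refit mode (candidate and conditioning set
#' maximized together) is available behind \code{jointRefit = TRUE}.
#'
#' @param X a [GenotypeMatrix-class] or numeric matrix.
#' @param outcome a [SurvivalOutcome-class].
#' @param conditioningSet integer indices of the already-selected columns.
#' @param rows optional row subsample (partition).
#' @param jointRefit refit the conditioning coefficients for every candidate
#'   (slow; one coxph per candidate).
#' @param details as in [marginalUtilities()].
#' @return utilities for the candidate columns (all columns not in the
#'   conditioning set), named by column index; attribute
#'   \code{"candidates"} carries the indices.
#' @export
conditionalUtilities <- function(X, outcome, conditioningSet,
                                 rows = NULL, jointRefit = FALSE,
                                 details = FALSE) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  conditioningSet <- as.integer(conditioningSet)
  cand <- setdiff(seq_len(ncol(v)), conditioningSet)
  if (is.null(rows)) rows <- seq_len(nrow(v))
  time <- obsTime(outcome)[rows]
  event <- eventStatus(outcome)[rows]
  ySub <- survivalOutcome(time, event)
  if (length(conditioningSet) == 0L) {
    r <- .marginalEngine(v[rows, cand, drop = FALSE], time, event)
  } else if (!jointRefit) {
    base <- survival::coxph(
      asSurv(ySub) ~ v[rows, conditioningSet, drop = FALSE],
      ties = "breslow")
    cf <- stats::coef(base)
    cf[is.na(cf)] <- 0 # aliased conditioning columns drop out
    off <- as.vector(v[rows, conditioningSet, drop = FALSE] %*% cf)
    r <- .marginalEngine(v[rows, cand, drop = FALSE], time, event,
                         offset = off)
  } else {
    ys <- asSurv(ySub)
    fits <- lapply(cand, function(k) {
      m <- v[rows, c(conditioningSet, k), drop = FALSE]
      f <- tryCatch(survival::coxph(ys ~ m, ties = "breslow"),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$loglik[2]
    })
    u <- unlist(fits)
    r <- list(utility = u, beta = rep(NA_real_, length(cand)),
              information = rep(NA_real_, length(cand)),
              nullLogLik = NA_real_,
              degenerate = is.na(u), converged = !is.na(u))
  }
  out <- if (details) r else r$utility
  if (!details) names(out) <- as.character(cand)
  attr(out, "candidates") <- cand
  out
}
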