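# Dimension reduction from ultra-high p: aggressive SIS (two-partition
# intersection), iterative SIS (conditional screening interleaved with a
# selector), and principled SIS (standardized-statistic cutoff).

#' Aggressive-SIS subset size
#'
#' The per-partition retention size \eqn{s = \lfloor n / \log n \rfloor}
#' (natural logarithm), with \code{n} the full sample size.
#'
#' @param n sample size.
#' @return integer \eqn{s}.
#' @examples
#' sisSubsetSize(300) # 52
#' @export
sisSubsetSize <- function(n) as.integer(floor(n / log(n)))

# Top-s column indices by utility; ties at the boundary break by lower
# column index (sort by (-utility, index)).
.topS <- function(utility, idx, s) {
  s <- min(s, length(idx))
  ord <- order(-utility, idx)
  sort(idx[ord[seq_len(s)]])
}

# Seeded half-sample split: ceiling(n/2) and floor(n/2) by random permutation.
.splitHalves <- function(n, seed) {
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n1 <- ceiling(n / 2)
  list(perm[seq_len(n1)], perm[(n1 + 1L):n])
}

#' Aggressive sure independence screening
#'
#' Randomly splits the sample into two halves, ranks every variable within
#' each half by its marginal utility (maximized univariate Cox log partial
#' likelihood), keeps the top \eqn{s = \lfloor n/\log n\rfloor} per half,
#' and returns the intersection of the two top sets.
#'
#' @param X a [GenotypeMatrix-class] or numeric matrix.
#' @param outcome a [SurvivalOutcome-class].
#' @param seed integer seed for the half-sample split.
#' @param s per-partition retention size; defaults to
#'   [sisSubsetSize()] of the full sample size.
#' @param conditioningSet optional already-selected set: utilities become
#'   conditional (offset) utilities and the conditioning columns are not
#'   candidates (used by [isis()]).
#' @return a [ScreenResult-class] with \code{selected} the intersection,
#'   \code{perPartitionTop} the two top sets, and \code{cutoffs} the
#'   s-th-ranked utility in each partition.
#' @export
sisAggressive <- function(X, outcome, seed = 1L, s = NULL,
                          conditioningSet = integer(0)) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  n <- nrow(v)
  if (n < 20L) stop("aggressive SIS needs n >= 20")
  if (is.null(s)) s <- sisSubsetSize(n)
  halves <- .splitHalves(n, seed)
  ev <- eventStatus(outcome)
  if (any(vapply(halves, function(h) sum(ev[h]) == 0L, logical(1))))
    stop("a partition contains no events; re-split with a new seed")
  tops <- vector("list", 2L)
  cuts <- numeric(2L)
  conditioningSet <- as.integer(conditioningSet)
  for (k in 1:2) {
    if (length(conditioningSet)) {
      u <- conditionalUtilities(v, outcome, conditioningSet,
                                rows = halves[[k]])
      cand <- attr(u, "candidates")
    } else {
      u <- marginalUtilities(v, outcome, rows = halves[[k]])
      cand <- seq_len(ncol(v))
    }
    tops[[k]] <- .topS(as.numeric(u), cand, s)
    cuts[k] <- min(as.numeric(u)[match(tops[[k]], cand)])
  }
  new("ScreenResult",
      selected = intersect(tops[[1]], tops[[2]]),
      method = "SIS",
      perPartitionTop = list(I1 = tops[[1]], I2 = tops[[2]]),
      cutoffs = cuts, nIterations = 1L, trace = list())
}

# Resolve a selector argument ("LASSO"/"ALASSO"/"RSF" or a function
# (X, outcome, seed) -> SelectionResult).
.resolveSelector <- function(selector, params = list()) {
  if (is.function(selector)) return(selector)
  selector <- match.arg(selector, c("LASSO", "ALASSO", "RSF"))
  nFolds <- params$nFolds %||% 10L
  nTrees <- params$nTrees %||% 100L
  nSplit <- params$nSplit %||% 10L
  switch(selector,
    LASSO = function(X, outcome, seed)
      lassoCox(X, outcome, nFolds = nFolds, seed = seed),
    ALASSO = function(X, outcome, seed)
      alassoCox(X, outcome, nFolds = nFolds, seed = seed),
    RSF = function(X, outcome, seed)
      rsfMinimalDepth(X, outcome, nTrees = nTrees, nSplit = nSplit,
                      seed = seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterative sure independence screening
#'
#' Iteration 1 is aggressive SIS followed by one pass of the selector,
#' giving \eqn{O_1}. Each later iteration re-splits the sample, screens the
#' remaining columns by conditional utility given the current set, and
#' applies the selector to the union of the new screened intersection and
#' the current set. Stops at a fixed point (\eqn{O_{j-1} = O_j}) or after
#' \code{maxIter} iterations.
#'
#' An empty selection at iteration 1 is a valid outcome (weak-signal,
#' small-n scenarios produce mean model sizes below one) and is returned as
#' an empty result with its trace.
#'
#' @param X a [GenotypeMatrix-class] or numeric matrix.
#' @param outcome a [SurvivalOutcome-class].
#' @param selector \code{"LASSO"}, \code{"ALASSO"}, \code{"RSF"}, or a
#'   function \code{(X, outcome, seed) -> } [SelectionResult-class].
#' @param maxIter maximum number of iterations.
#' @param seed integer seed; split and selector seeds are derived from it.
#' @param params selector parameters passed through
#'   (\code{nFolds}, \code{nTrees}, \code{nSplit}).
#' @return a [ScreenResult-class] with \code{method = "ISIS"}; the trace
#'   holds each iteration's selected set and the final
#'   [SelectionResult-class] (element \code{"selection"}).
#' @export
isis <- function(X, outcome, selector = "LASSO", maxIter = 5L, seed = 1L,
                 params = list()) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  p <- ncol(v)
  selFun <- .resolveSelector(selector, params)
  set.seed(as.integer(seed))
  subSeeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * maxIter),
                     nrow = maxIter)
  O <- integer(0)
  trace <- list(sets = list())
  lastSel <- NULL
  nIter <- 0L
  for (j in seq_len(maxIter)) {
    nIter <- j
    scr <- sisAggressive(v, outcome, seed = subSeeds[j, 1],
                         conditioningSet = O)
    pool <- sort(union(selected(scr), O))
    if (length(pool) == 0L) {
      newO <- integer(0)
    } else if (length(pool) == 1L) {
      lastSel <- selFun(v[, pool, drop = FALSE], outcome, subSeeds[j, 2])
      newO <- pool[selected(lastSel)]
    } else {
      lastSel <- selFun(v[, pool, drop = FALSE], outcome, subSeeds[j, 2])
      newO <- pool[selected(lastSel)]
    }
    trace$sets[[j]] <- newO
    if (setequal(newO, O)) {
      O <- newO
      break
    }
    O <- newO
    if (length(O) == 0L && j == 1L) break # empty first pass: valid outcome
  }
  trace$selection <- lastSel
  new("ScreenResult", selected = sort(as.integer(O)), method = "ISIS",
      perPartitionTop = list(), cutoffs = numeric(0),
      nIterations = nIter, trace = trace)
}

#' Principled sure independence screening
#'
#' Fits every marginal MPLE on the full sample (no splitting) and keeps the
#' columns whose standardized statistic
#' \eqn{I_k(\hat\beta_k)^{1/2} |\hat\beta_k|} reaches the standard-normal
#' quantile \eqn{\gamma_m = \Phi^{-1}(1 - q_m/2)}, controlling the marginal
#' false-positive rate at \eqn{q_m}.
#'
#' @param X a [GenotypeMatrix-class] or numeric matrix.
#' @param outcome a [SurvivalOutcome-class].
#' @param qm marginal false-positive rate in \eqn{(0, 1]}.
#' @return a [ScreenResult-class] with \code{cutoffs} = \eqn{\gamma_m}.
#' @export
psis <- function(X, outcome, qm = 0.001) {
  stopifnot(qm > 0, qm <= 1)
  det <- marginalUtilities(X, outcome, details = TRUE)
  gamma <- stats::qnorm(1 - qm / 2)
  stat <- sqrt(pmax(det$information, 0)) * abs(det$beta)
  keep <- which(stat >= gamma & !det$degenerate)
  new("ScreenResult", selected = as.integer(keep), method = "PSIS",
      perPartitionTop = list(), cutoffs = gamma,
      nIterations = 1L, trace = list())
}
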