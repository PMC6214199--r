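#' @import methods
NULL

#' Simulation scenario configuration
#'
#' Holds every knob of the SNP-survival simulation design: sample size,
#' dimensionality, number of informative variables, signal-strength offset,
#' Weibull shape, target censoring proportion, minor allele frequency, the
#' scenario seed and the independent test-set size.
#'
#' @slot n training sample size.
#' @slot p number of variables (SNPs).
#' @slot pStar number of informative variables (nonzero coefficients).
#' @slot a signal-strength offset: coefficients are drawn as
#'   \eqn{(-1)^u (a + |z|)}, so \code{a = 1} gives weak and \code{a = 2}
#'   strong signals.
#' @slot tau Weibull shape parameter of the failure-time distribution.
#' @slot censRate target censoring proportion in \eqn{[0, 1)}.
#' @slot maf minor allele frequency \eqn{q \in (0, 0.5]} shared by all
#'   simulated variants.
#' @slot seed integer RNG seed for the scenario.
#' @slot testN size of the independent test set.
#'
#' @seealso [scenarioConfig()], [genDataset()]
#' @export
setClass("ScenarioConfig",
  representation(
    n = "integer", p = "integer", pStar = "integer",
    a = "numeric", tau = "numeric", censRate = "numeric",
    maf = "numeric", seed = "integer", testN = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (object@pStar > object@p) msg <- c(msg, "pStar must not exceed p")
  if (object@maf <= 0 || object@maf > 0.5)
    msg <- c(msg, "maf must lie in (0, 0.5]")
  if (object@censRate < 0 || object@censRate >= 1)
    msg <- c(msg, "censRate must lie in [0, 1)")
  if (object@tau <= 0) msg <- c(msg, "tau must be positive")
  if (object@n < 1L || object@p < 1L) msg <- c(msg, "n and p must be positive")
  if (length(msg)) msg else TRUE
})

#' Genotype code matrix
#'
#' An \code{n x p} matrix of additive genotype codes. Generated matrices hold
#' integer codes in \{0, 1, 2\} (copies of the minor allele); matrices read
#' from disk may contain \code{NA} for missing calls, and mean imputation
#' produces fractional values in \eqn{[0, 2]}.
#'
#' @slot values numeric matrix, rows are samples, columns are variants.
#' @slot maf per-variant minor allele frequency used for generation
#'   (\code{NA} for data read from files).
#'
#' @seealso [genGenotypes()], [readGenotypes()], [imputeMean()]
#' @export
setClass("GenotypeMatrix",
  representation(values = "matrix", maf = "numeric")
)

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    return("genotype codes must lie in [0, 2] (or NA)")
  if (length(object@maf) > 1L && length(object@maf) != ncol(v))
    return("maf must be length 1 or ncol(values)")
  TRUE
})

#' True generating model of a simulation scenario
#'
#' @slot beta full-length coefficient vector (log-hazard scale before the
#'   Weibull shape multiplier); zero outside \code{informativeIdx}.
#' @slot informativeIdx indices of the variables with nonzero coefficients.
#'
#' @seealso [genBeta()], [betaFixture()]
#' @export
setClass("TrueModel",
  representation(beta = "numeric", informativeIdx = "integer")
)

setValidity("TrueModel", function(object) {
  out <- setdiff(which(object@beta != 0), object@informativeIdx)
  if (length(out)) return("beta must be zero outside informativeIdx")
  if (any(object@informativeIdx > length(object@beta)))
    return("informativeIdx out of range")
  TRUE
})

#' Right-censored survival outcome
#'
#' Observed times \eqn{t_i = \min(T_i, C_i)} and event indicators
#' \eqn{\delta_i = I(T_i \le C_i)}.
#'
#' @slot time positive observed times.
#' @slot event 0/1 event indicators.
#' @export
setClass("SurvivalOutcome",
  representation(time = "numeric", event = "integer")
)

setValidity("SurvivalOutcome", function(object) {
  if (length(object@time) != length(object@event))
    return("time and event must have equal length")
  if (any(object@time <= 0)) return("times must be positive")
  if (!all(object@event %in% c(0L, 1L))) return("event must be 0/1")
  TRUE
})

#' Marginal Cox fit for a single variable
#'
#' Result of maximizing the univariate Cox log partial likelihood: the MPLE
#' \eqn{\hat\beta_k}, the marginal utility \eqn{u_k} (the maximized log
#' partial likelihood), and the observed information at the maximum.
#'
#' @slot betaHat coefficient estimate.
#' @slot utility maximized log partial likelihood.
#' @slot information negative second derivative at the maximum.
#' @slot converged logical; \code{FALSE} for monotone likelihoods (estimate
#'   capped) and for degenerate (constant) covariates.
#' @slot nullLogLik log partial likelihood at \eqn{\beta = 0}.
#' @export
setClass("MarginalFit",
  representation(
    betaHat = "numeric", utility = "numeric", information = "numeric",
    converged = "logical", nullLogLik = "numeric"
  )
)

#' Screening result
#'
#' @slot selected integer indices of the retained variables (into the
#'   original columns).
#' @slot method one of \code{"SIS"}, \code{"ISIS"}, \code{"PSIS"}.
#' @slot perPartitionTop for SIS, the two per-partition top-\eqn{s} index
#'   sets \eqn{I_1} and \eqn{I_2}.
#' @slot cutoffs the utility (SIS) or standardized-statistic (PSIS) cutoffs
#'   actually applied.
#' @slot nIterations number of ISIS iterations run.
#' @slot trace per-iteration selected sets (ISIS).
#' @export
setClass("ScreenResult",
  representation(
    selected = "integer", method = "character",
    perPartitionTop = "list", cutoffs = "numeric",
    nIterations = "integer", trace = "list"
  )
)

setValidity("ScreenResult", function(object) {
  if (anyDuplicated(object@selected)) return("selected must be unique")
  TRUE
})

#' Variable-selection result
#'
#' @slot selected indices of the selected variables (into the columns of the
#'   matrix handed to the selector).
#' @slot coefficients penalized coefficient estimates on the selected set
#'   (empty for the random-survival-forest selector).
#' @slot lambdaChosen penalty value minimizing the cross-validated partial
#'   likelihood deviance (penalized methods; \code{NA} otherwise).
#' @slot depthThreshold forest-averaged mean minimal depth under the null
#'   (RSF; \code{NA} otherwise).
#' @slot method selector label.
#' @slot meta list of method details (e.g. the source of adaptive weights).
#' @export
setClass("SelectionResult",
  representation(
    selected = "integer", coefficients = "numeric",
    lambdaChosen = "numeric", depthThreshold = "numeric",
    method = "character", meta = "list"
  )
)

setValidity("SelectionResult", function(object) {
  if (length(object@coefficients) &&
      length(object@coefficients) != length(object@selected))
    return("coefficients must align with selected")
  if (!is.na(object@depthThreshold) && object@depthThreshold < 0)
    return("depthThreshold must be nonnegative")
  TRUE
})

#' Model performance report
#'
#' @slot cIndex Harrell's concordance index.
#' @slot r2bs Brier-score R-squared at the evaluation horizon (may be
#'   negative when the model predicts worse than the null model).
#' @slot calSlope calibration slope.
#' @slot calTable per-quartile mean predicted vs observed survival.
#' @slot optimism mean bootstrap optimism of the c-index (NA unless a
#'   bootstrap validation was run).
#' @slot cCorrected optimism-corrected c-index.
#' @export
setClass("EvalReport",
  representation(
    cIndex = "numeric", r2bs = "numeric", calSlope = "numeric",
    calTable = "data.frame", optimism = "numeric", cCorrected = "numeric"
  )
)

setValidity("EvalReport", function(object) {
  if (!is.na(object@cIndex) && (object@cIndex < 0 || object@cIndex > 1))
    return("cIndex must lie in [0, 1]")
  if (!is.na(object@r2bs) && object@r2bs > 1)
    return("r2bs cannot exceed 1")
  TRUE
})

#' Quality-control report
#'
#' Per-filter removal counts from sequential application of the call-rate,
#' Hardy-Weinberg and minor-allele-frequency filters (plus an optional
#' a-priori ID exclusion, e.g. non-autosomal variants).
#'
#' @slot nInput variants before filtering.
#' @slot nRemovedExcluded removed by the ID exclusion list.
#' @slot nRemovedCallRate removed by the call-rate filter.
#' @slot nRemovedHWE removed by the Hardy-Weinberg test.
#' @slot nRemovedMAF removed by the MAF filter.
#' @slot nPass variants surviving all filters.
#' @slot thresholds the thresholds applied.
#' @export
setClass("QCReport",
  representation(
    nInput = "integer", nRemovedExcluded = "integer",
    nRemovedCallRate = "integer", nRemovedHWE = "integer",
    nRemovedMAF = "integer", nPass = "integer", thresholds = "numeric"
  )
)

setValidity("QCReport", function(object) {
  tot <- object@nRemovedExcluded + object@nRemovedCallRate +
    object@nRemovedHWE + object@nRemovedMAF
  if (object@nPass != object@nInput - tot)
    return("nPass must equal nInput minus the sequential removals")
  TRUE
})

#' Method combination specification
#'
#' A screening stage paired with a selection stage. The thirteen study
#' combinations are expressible: SIS, PSIS, LASSO and ALASSO alone, and the
#' nine screen-times-selector pairs. ISIS cannot run alone because its
#' iterations interleave screening with a selector.
#'
#' @slot screen \code{"none"}, \code{"SIS"}, \code{"ISIS"} or \code{"PSIS"}.
#' @slot select \code{"none"}, \code{"LASSO"}, \code{"ALASSO"} or \code{"RSF"}.
#' @slot params named list of method parameters (\code{qm}, \code{maxIter},
#'   \code{nTrees}, \code{nSplit}, \code{nFolds}).
#' @seealso [methodSpec()], [runMethod()]
#' @export
setClass("MethodSpec",
  representation(screen = "character", select = "character", params = "list")
)

setValidity("MethodSpec", function(object) {
  if (!object@screen %in% c("none", "SIS", "ISIS", "PSIS"))
    return("unknown screen stage")
  if (!object@select %in% c("none", "LASSO", "ALASSO", "RSF"))
    return("unknown select stage")
  if (object@screen == "ISIS" && object@select == "none")
    return("ISIS requires a selector; it cannot run alone")
  TRUE
})
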