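# Generics and accessors. Slots are never reached into from user code;
# these accessors are the supported surface.

#' Selected variable indices
#'
#' @param object a [ScreenResult-class] or [SelectionResult-class].
#' @return sorted integer indices of the retained variables.
#' @export
setGeneric("selected", function(object) standardGeneric("selected"))

#' @rdname selected
#' @export
setMethod("selected", "ScreenResult", function(object) object@selected)

#' @rdname selected
#' @export
setMethod("selected", "SelectionResult", function(object) object@selected)

#' Genotype codes as a base matrix
#'
#' @param object a [GenotypeMatrix-class].
#' @return the underlying numeric matrix (samples by variants).
#' @export
setGeneric("genoValues", function(object) standardGeneric("genoValues"))

#' @rdname genoValues
#' @export
setMethod("genoValues", "GenotypeMatrix", function(object) object@values)

#' Generating minor allele frequencies
#'
#' @param object a [GenotypeMatrix-class].
#' @return numeric vector of per-variant MAFs (NA when unknown).
#' @export
setGeneric("genoMAF", function(object) standardGeneric("genoMAF"))

#' @rdname genoMAF
#' @export
setMethod("genoMAF", "GenotypeMatrix", function(object) object@maf)

#' Observed times and event indicators
#'
#' @param object a [SurvivalOutcome-class].
#' @return numeric vector of observed times.
#' @export
setGeneric("obsTime", function(object) standardGeneric("obsTime"))

#' @rdname obsTime
#' @export
setMethod("obsTime", "SurvivalOutcome", function(object) object@time)

#' @rdname obsTime
#' @return for `eventStatus`, integer 0/1 event indicators.
#' @export
setGeneric("eventStatus", function(object) standardGeneric("eventStatus"))

#' @rdname obsTime
#' @export
setMethod("eventStatus", "SurvivalOutcome", function(object) object@event)

#' Coerce an outcome to a survival::Surv object
#'
#' @param object a [SurvivalOutcome-class].
#' @return a right-censored [survival::Surv] object.
#' @export
setGeneric("asSurv", function(object) standardGeneric("asSurv"))

#' @rdname asSurv
#' @export
setMethod("asSurv", "SurvivalOutcome", function(object) {
  survival::Surv(object@time, object@event)
})

#' Coefficients of a selection result
#'
#' @param object a [SelectionResult-class].
#' @param ... ignored.
#' @return named numeric vector of nonzero penalized coefficients.
#' @export
setMethod("coef", "SelectionResult", function(object, ...) object@coefficients)

#' @rdname selected
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))

#' @rdname selected
#' @export
setMethod("nIterations", "ScreenResult", function(object) object@nIterations)

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: n=%d p=%d p*=%d a=%g tau=%g C=%g maf=%g testN=%d seed=%d\n",
    object@n, object@p, object@pStar, object@a, object@tau,
    object@censRate, object@maf, object@testN, object@seed
  ))
})

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@values
  cat(sprintf(
    "GenotypeMatrix: %d samples x %d variants (%d missing calls)\n",
    nrow(v), ncol(v), sum(is.na(v))
  ))
})

setMethod("show", "SurvivalOutcome", function(object) {
  cat(sprintf(
    "SurvivalOutcome: %d subjects, %d events (%.1f%% censored)\n",
    length(object@time), sum(object@event),
    100 * mean(1 - object@event)
  ))
})

setMethod("show", "TrueModel", function(object) {
  cat(sprintf(
    "TrueModel: p=%d with %d informative variables\n  beta[informative]: %s\n",
    length(object@beta), length(object@informativeIdx),
    paste(signif(object@beta[object@informativeIdx], 5), collapse = ", ")
  ))
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf(
    "ScreenResult [%s]: %d variables selected%s\n",
    object@method, length(object@selected),
    if (object@method == "ISIS")
      sprintf(" after %d iteration(s)", object@nIterations) else ""
  ))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s]: %d variables\n",
              object@method, length(object@selected)))
  if (length(object@coefficients))
    cat("  coefficients:",
        paste(signif(object@coefficients, 4), collapse = ", "), "\n")
  if (!is.na(object@depthThreshold))
    cat(sprintf("  minimal-depth threshold: %.4f\n", object@depthThreshold))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: c-index=%.4f  R2_BS=%.4f  calibration slope=%.4f\n",
    object@cIndex, object@r2bs, object@calSlope
  ))
  if (!is.na(object@optimism))
    cat(sprintf("  optimism=%.4f  corrected c-index=%.4f\n",
                object@optimism, object@cCorrected))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf(
    paste0("QCReport: %d variants in; removed %d (excluded) + %d (call rate)",
           " + %d (HWE) + %d (MAF); %d pass\n"),
    object@nInput, object@nRemovedExcluded, object@nRemovedCallRate,
    object@nRemovedHWE, object@nRemovedMAF, object@nPass
  ))
})

setMethod("show", "MethodSpec", function(object) {
  cat(sprintf("MethodSpec: screen=%s select=%s\n",
              object@screen, object@select))
})
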