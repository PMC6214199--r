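# Benchmark orchestration: method combinations, single-replicate execution
# (screen -> select -> refit -> evaluate on train and test), and the
# replicated scenario grid with deterministic per-replicate seeding so
# results are invariant to the worker count.

#' Construct a method combination
#'
#' @param screen screening stage: \code{"none"}, \code{"SIS"},
#'   \code{"ISIS"} or \code{"PSIS"}.
#' @param select selection stage: \code{"none"}, \code{"LASSO"},
#'   \code{"ALASSO"} or \code{"RSF"}. ISIS requires a selector.
#' @param params named list of method parameters: \code{qm} (PSIS
#'   false-positive rate), \code{maxIter} (ISIS), \code{nFolds} (CV),
#'   \code{nTrees}, \code{nSplit} (RSF).
#' @return a [MethodSpec-class].
#' @examples
#' methodSpec("ISIS", "LASSO")
#' @export
methodSpec <- function(screen = "none", select = "none", params = list()) {
  new("MethodSpec", screen = screen, select = select, params = params)
}

#' Method label
#' @param method a [MethodSpec-class].
#' @return a human-readable label like \code{"ISIS-LASSO"}.
#' @export
methodLabel <- function(method) {
  s1 <- method@screen
  s2 <- method@select
  if (s1 == "none" && s2 == "none") return("null")
  if (s1 == "none") return(s2)
  if (s2 == "none") return(s1)
  paste(s1, s2, sep = "-")
}

#' Run one method combination on one dataset
#'
#' Applies the screening stage (if any), then the selection stage (if any),
#' refits an unpenalized proportional-hazards model on the selected
#' variables, and evaluates discrimination, overall performance and
#' calibration on the training and test sets. An empty selection yields the
#' null model and the null-model metrics (c-index 0.5, \eqn{R^2_{BS}} 0,
#' undefined slope). Component failures are recorded as a status code with
#' missing metric cells rather than raised.
#'
#' @param train list with \code{geno} and \code{outcome}.
#' @param test list with \code{geno} and \code{outcome}, or \code{NULL} to
#'   skip test-set metrics.
#' @param method a [MethodSpec-class].
#' @param seed integer seed (stage seeds derive from it).
#' @param tStar evaluation horizon for \eqn{R^2_{BS}}.
#' @param trueModel optional [TrueModel-class]: adds the count of truly
#'   informative variables among the selected.
#' @return one-row data.frame of the replicate record; the fitted
#'   \code{"survscreenFit"} and selected set ride along as attributes
#'   \code{"fit"} and \code{"selected"}.
#' @export
runMethod <- function(train, test = NULL, method, seed = 1L, tStar = 2,
                      trueModel = NULL) {
  set.seed(as.integer(seed))
  stageSeeds <- sample.int(.Machine$integer.max - 1L, 3L)
  X <- train$geno
  y <- train$outcome
  p <- ncol(genoValues(X))
  qm <- method@params$qm %||% 0.001
  maxIter <- method@params$maxIter %||% 5L
  status <- "ok"
  sel <- integer(0)

  sel <- tryCatch({
    if (method@screen == "ISIS") {
      scr <- isis(X, y, selector = method@select, maxIter = maxIter,
                  seed = stageSeeds[1], params = method@params)
      selected(scr)
    } else {
      cand <- switch(method@screen,
        none = seq_len(p),
        SIS = selected(sisAggressive(X, y, seed = stageSeeds[1])),
        PSIS = selected(psis(X, y, qm = qm)))
      if (method@select == "none") {
        if (method@screen == "none") integer(0) else cand
      } else if (length(cand) == 0L) {
        integer(0)
      } else {
        selFun <- .resolveSelector(method@select, method@params)
        sub <- genoValues(X)[, cand, drop = FALSE]
        cand[selected(selFun(sub, y, stageSeeds[2]))]
      }
    }
  }, error = function(e) {
    status <<- paste0("screen/select failed: ", conditionMessage(e))
    integer(0)
  })

  rec <- data.frame(
    method = methodLabel(method), seed = as.integer(seed),
    status = status, sizeSelected = length(sel),
    nInformative = if (is.null(trueModel)) NA_integer_ else
      length(intersect(sel, trueModel@informativeIdx)),
    cTrain = NA_real_, r2Train = NA_real_,
    cTest = NA_real_, r2Test = NA_real_, calSlope = NA_real_,
    stringsAsFactors = FALSE
  )
  fit <- NULL
  tryCatch({
    fit <- coxRefit(X, y, sel)
    evTr <- evaluateModel(fit, X, y, tStar)
    rec$cTrain <- evTr@cIndex
    rec$r2Train <- evTr@r2bs
    if (!is.null(test)) {
      evTe <- evaluateModel(fit, test$geno, test$outcome, tStar)
      rec$cTest <- evTe@cIndex
      rec$r2Test <- evTe@r2bs
      rec$calSlope <- evTe@calSlope
    }
  }, error = function(e) {
    rec$status <<- paste0("evaluation failed: ", conditionMessage(e))
  })
  attr(rec, "fit") <- fit
  attr(rec, "selected") <- sel
  rec
}

#' Run a replicated benchmark over scenarios and methods
#'
#' For each scenario, the censoring bound is calibrated once and every
#' replicate draws fresh training and test data from the scenario's true
#' model. All replicate and method seeds are derived from the master seed
#' up front, so the per-replicate records are bit-identical for any worker
#' count, and aggregates are recomputable exactly from the records.
#'
#' @param scenarios list of [ScenarioConfig-class] objects.
#' @param methods list of [MethodSpec-class] objects.
#' @param reps replicates per scenario.
#' @param seed master seed.
#' @param workers parallel workers (forked; results identical to serial).
#' @param tStar evaluation horizon.
#' @return list with \code{records} (tidy per-replicate data.frame; one row
#'   per scenario x replicate x method) and \code{summary} (mean/SD table
#'   from [summarizeBenchmark()]).
#' @export
runBenchmark <- function(scenarios, methods, reps = 25L, seed = 1L,
                         workers = 1L, tStar = 2) {
  stopifnot(reps >= 1L)
  if (is(scenarios, "ScenarioConfig")) scenarios <- list(scenarios)
  if (is(methods, "MethodSpec")) methods <- list(methods)
  nS <- length(scenarios)
  nM <- length(methods)
  set.seed(as.integer(seed))
  dataSeeds <- matrix(sample.int(.Machine$integer.max - 1L, nS * reps),
                      nrow = nS)
  methodSeeds <- array(sample.int(.Machine$integer.max - 1L, nS * reps * nM),
                       dim = c(nS, reps, nM))
  prep <- lapply(scenarios, function(cfg) {
    model <- if (cfg@pStar == 6L && cfg@a %in% c(1, 2))
      betaFixture(if (cfg@a == 2) "strong" else "weak", p = cfg@p)
    else genBeta(cfg@pStar, cfg@a, seed = cfg@seed, p = cfg@p)
    list(model = model, thetaC = calibrateThetaC(cfg, model))
  })
  grid <- expand.grid(s = seq_len(nS), r = seq_len(reps))
  oneCell <- function(g) {
    si <- grid$s[g]
    ri <- grid$r[g]
    cfg <- scenarios[[si]]
    cfgR <- scenarioConfig(cfg@n, cfg@p, cfg@pStar, cfg@a, cfg@tau,
                           cfg@censRate, cfg@maf,
                           seed = dataSeeds[si, ri], testN = cfg@testN)
    d <- genDataset(cfgR, model = prep[[si]]$model,
                    thetaC = prep[[si]]$thetaC, includeTest = TRUE)
    recs <- lapply(seq_len(nM), function(mi) {
      r <- runMethod(d$train, d$test, methods[[mi]],
                     seed = methodSeeds[si, ri, mi], tStar = tStar,
                     trueModel = d$model)
      attr(r, "fit") <- NULL
      attr(r, "selected") <- NULL
      cbind(data.frame(scenario = si, rep = ri), r)
    })
    do.call(rbind, recs)
  }
  cells <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(grid)), oneCell, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(grid)), oneCell)
  }
  records <- do.call(rbind, cells)
  rownames(records) <- NULL
  list(records = records, summary = summarizeBenchmark(records))
}

#' Aggregate per-replicate benchmark records
#'
#' Mean and standard deviation of every metric column by scenario and
#' method; a single replicate leaves the SD as \code{NA}.
#'
#' @param records the per-replicate data.frame from [runBenchmark()].
#' @return data.frame keyed by scenario and method.
#' @export
summarizeBenchmark <- function(records) {
  metrics <- c("sizeSelected", "nInformative", "cTrain", "r2Train",
               "cTest", "r2Test", "calSlope")
  metrics <- intersect(metrics, names(records))
  sp <- split(records, list(records$scenario, records$method), drop = TRUE)
  rows <- lapply(sp, function(d) {
    out <- data.frame(scenario = d$scenario[1], method = d$method[1],
                      nReps = nrow(d), nFailed = sum(d$status != "ok"))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]][!is.na(d[[m]])])
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$scenario, res$method), ]
}

#' Write benchmark outputs
#'
#' Tab-delimited per-replicate records and summary tables plus a small JSON
#' run manifest (scenarios, seed, package and R versions).
#'
#' @param result the list from [runBenchmark()].
#' @param dir output directory (created if needed).
#' @param seed the master seed used (recorded in the manifest).
#' @param scenarios the scenario list (recorded in the manifest).
#' @return \code{dir}, invisibly.
#' @export
writeBenchmark <- function(result, dir, seed = NA_integer_,
                           scenarios = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$records, file.path(dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = seed,
    scenarios = lapply(scenarios, function(cfg)
      list(n = cfg@n, p = cfg@p, pStar = cfg@pStar, a = cfg@a,
           tau = cfg@tau, censRate = cfg@censRate, maf = cfg@maf,
           testN = cfg@testN)),
    package = as.character(utils::packageVersion("survscreen")),
    r = R.version.string
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
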