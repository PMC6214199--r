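# Readers/writers for the plain-text genotype + outcome formats, the SNP
# quality-control filters (call rate, Hardy-Weinberg, MAF), mean imputation
# of missing calls, and the train/test split.

#' Write a genotype matrix to a tab-delimited file
#'
#' Rows are samples, columns are variants; the header row carries the
#' variant IDs and missing calls are written as \code{NA}.
#'
#' @param X a [GenotypeMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(X, path) {
  utils::write.table(genoValues(X), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a genotype matrix from a tab-delimited file
#'
#' Parses the dialect written by [writeGenotypes()]: a header row of
#' variant IDs and entries in \{0, 1, 2\} (fractional values in \eqn{[0,2]}
#' from prior imputation are accepted) or the missing token \code{NA}.
#' Malformed rows raise a parse error naming the offending line.
#'
#' @param path input file path.
#' @return a [GenotypeMatrix-class] (MAF unknown, missing entries NA).
#' @export
readGenotypes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("genotype file has no data rows: ", path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  p <- length(ids)
  rows <- vector("list", length(lines) - 1L)
  for (i in 2:length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != p)
      stop("parse error at line ", i, ": expected ", p, " fields, got ",
           length(f))
    x <- suppressWarnings(as.numeric(f))
    bad <- which(!(f == "NA" | (!is.na(x) & x >= 0 & x <= 2)))
    if (length(bad))
      stop("parse error at line ", i, ": invalid genotype code '",
           f[bad[1]], "'")
    rows[[i - 1L]] <- x
  }
  m <- do.call(rbind, rows)
  colnames(m) <- ids
  new("GenotypeMatrix", values = m, maf = NA_real_)
}

#' Write / read survival outcomes
#'
#' Two-column tab-delimited file with header \code{time} and \code{event}.
#'
#' @param outcome a [SurvivalOutcome-class].
#' @param path file path.
#' @return `writeOutcome` returns \code{path} invisibly; `readOutcome`
#'   returns a [SurvivalOutcome-class].
#' @export
writeOutcome <- function(outcome, path) {
  utils::write.table(
    data.frame(time = obsTime(outcome), event = eventStatus(outcome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOutcome
#' @export
readOutcome <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("time", "event") %in% names(d)))
  survivalOutcome(d$time, d$event)
}

#' Write / read a scenario configuration as JSON
#'
#' A flat key-value JSON file mirroring the [ScenarioConfig-class] fields.
#'
#' @param config a [ScenarioConfig-class].
#' @param path file path.
#' @return `writeScenarioConfig` returns \code{path} invisibly;
#'   `readScenarioConfig` returns a [ScenarioConfig-class].
#' @export
writeScenarioConfig <- function(config, path) {
  jsonlite::write_json(
    list(n = config@n, p = config@p, pStar = config@pStar, a = config@a,
         tau = config@tau, censRate = config@censRate, maf = config@maf,
         seed = config@seed, testN = config@testN),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScenarioConfig
#' @export
readScenarioConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenarioConfig(n = j$n, p = j$p, pStar = j$pStar %||% 6L, a = j$a %||% 2,
                 tau = j$tau %||% 1.5, censRate = j$censRate %||% 0.20,
                 maf = j$maf %||% 0.15, seed = j$seed %||% 1L,
                 testN = j$testN %||% 2000L)
}

# Hardy-Weinberg goodness-of-fit: 1-df chi-square of the observed genotype
# counts against expectations from the estimated allele frequency.
.hwePvalue <- function(n0, n1, n2) {
  m <- n0 + n1 + n2
  if (m == 0L) return(1)
  qhat <- (n1 + 2 * n2) / (2 * m)
  if (qhat == 0 || qhat == 1) return(1) # monomorphic: no HWE deviation
  e <- m * c((1 - qhat)^2, 2 * qhat * (1 - qhat), qhat^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Quality-control filtering of a genotype matrix
#'
#' Sequentially removes variants failing (1) the call-rate threshold
#' (proportion of non-missing calls), (2) the Hardy-Weinberg equilibrium
#' test (1-df chi-square on the three genotype counts) and (3) the minor
#' allele frequency threshold, in that order so no variant is counted
#' twice. Non-autosomal or otherwise a-priori excluded variants can be
#' removed first through an ID list.
#'
#' @param X a [GenotypeMatrix-class] (may contain missing calls).
#' @param callRateMin minimum call rate.
#' @param hwePMin minimum HWE p-value.
#' @param mafMin minimum minor allele frequency.
#' @param exclude optional character vector of variant IDs to drop first.
#' @return list with the filtered \code{geno} and a [QCReport-class]
#'   \code{report}.
#' @export
qcFilter <- function(X, callRateMin = 0.99, hwePMin = 1e-8,
                     mafMin = 0.05, exclude = NULL) {
  v <- genoValues(X)
  maf <- genoMAF(X)
  nInput <- ncol(v)
  nExc <- 0L
  if (!is.null(exclude)) {
    drop <- which(colnames(v) %in% exclude)
    nExc <- length(drop)
    if (nExc) {
      v <- v[, -drop, drop = FALSE]
      if (length(maf) > 1L) maf <- maf[-drop]
    }
  }
  callRate <- colMeans(!is.na(v))
  failCR <- callRate < callRateMin
  nCR <- sum(failCR)
  v <- v[, !failCR, drop = FALSE]
  if (length(maf) > 1L) maf <- maf[!failCR]

  counts <- vapply(seq_len(ncol(v)), function(k) {
    x <- v[, k]
    c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
      sum(x == 2, na.rm = TRUE))
  }, numeric(3))
  hweP <- vapply(seq_len(ncol(v)), function(k)
    .hwePvalue(counts[1, k], counts[2, k], counts[3, k]), numeric(1))
  failHWE <- hweP < hwePMin
  nHWE <- sum(failHWE)
  v <- v[, !failHWE, drop = FALSE]
  counts <- counts[, !failHWE, drop = FALSE]
  if (length(maf) > 1L) maf <- maf[!failHWE]

  m <- colSums(counts)
  qhat <- ifelse(m > 0, (counts[2, ] + 2 * counts[3, ]) / (2 * m), 0)
  mafHat <- pmin(qhat, 1 - qhat)
  failMAF <- mafHat < mafMin
  nMAF <- sum(failMAF)
  v <- v[, !failMAF, drop = FALSE]
  if (length(maf) > 1L) maf <- maf[!failMAF]

  report <- new("QCReport",
    nInput = nInput, nRemovedExcluded = nExc,
    nRemovedCallRate = as.integer(nCR), nRemovedHWE = as.integer(nHWE),
    nRemovedMAF = as.integer(nMAF), nPass = ncol(v),
    thresholds = c(callRateMin = callRateMin, hwePMin = hwePMin,
                   mafMin = mafMin))
  list(geno = new("GenotypeMatrix", values = v, maf = maf),
       report = report)
}

#' Mean imputation of missing genotype calls
#'
#' Replaces each missing call with the mean of the variant's non-missing
#' calls; observed calls are untouched and column means are preserved
#' exactly. Imputed values are fractional genotype doses, accepted by the
#' penalized models and forests downstream.
#'
#' @param X a [GenotypeMatrix-class] with missing entries.
#' @return a complete [GenotypeMatrix-class].
#' @export
imputeMean <- function(X) {
  v <- genoValues(X)
  miss <- is.na(v)
  if (!any(miss)) return(X)
  full <- which(colSums(miss) == nrow(v))
  if (length(full))
    stop("variant(s) entirely missing: ",
         paste(colnames(v)[full], collapse = ", "))
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  v[miss] <- mu[idx[, 2]]
  new("GenotypeMatrix", values = v, maf = genoMAF(X))
}

#' Seeded train/test split
#'
#' Random partition of the samples into a training set of
#' \eqn{\lceil \mathrm{ratio} \cdot n \rceil} rows and a test set of the
#' remainder. Disjoint and exhaustive.
#'
#' @param X a [GenotypeMatrix-class].
#' @param outcome a [SurvivalOutcome-class].
#' @param ratio training proportion in \eqn{(0, 1)}.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test}, each holding
#'   \code{geno}, \code{outcome} and the row indices \code{idx}.
#' @export
splitTrainTest <- function(X, outcome, ratio = 2 / 3, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  v <- genoValues(X)
  n <- nrow(v)
  set.seed(as.integer(seed))
  trainIdx <- sort(sample.int(n, ceiling(ratio * n)))
  testIdx <- setdiff(seq_len(n), trainIdx)
  sub <- function(i) list(
    geno = new("GenotypeMatrix", values = v[i, , drop = FALSE],
               maf = genoMAF(X)),
    outcome = survivalOutcome(obsTime(outcome)[i], eventStatus(outcome)[i]),
    idx = i)
  list(train = sub(trainIdx), test = sub(testIdx))
}
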