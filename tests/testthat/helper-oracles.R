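# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (explicit loops, no shared code with the package
# internals beyond exported constructors).

# Naive Cox log partial likelihood: explicit risk-set loop, Breslow ties.
bruteLogPL <- function(x, time, event, beta, offset = NULL) {
  n <- length(time)
  if (is.null(offset)) offset <- numeric(n)
  lp <- x * beta + offset
  s <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1) {
      R <- which(time >= time[i])
      s <- s + lp[i] - log(sum(exp(lp[R])))
    }
  }
  s
}

# Dense grid-search maximizer of the univariate log partial likelihood.
gridMaxLogPL <- function(x, time, event, lo = -10, hi = 10, step = 1e-3) {
  bs <- seq(lo, hi, by = step)
  best <- -Inf
  bstar <- 0
  for (b in bs) {
    l <- bruteLogPL(x, time, event, b)
    if (l > best) {
      best <- l
      bstar <- b
    }
  }
  list(beta = bstar, utility = best)
}

# Exhaustive-pair concordance: smaller observed time must be an event; tied
# observed times are not comparable; predictor ties count one half.
pairOracleC <- function(lp, time, event) {
  n <- length(time)
  conc <- 0
  comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j # earlier subject
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next
      comp <- comp + 1
      if (lp[a] > lp[b]) conc <- conc + 1
      else if (lp[a] == lp[b]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Independent IPCW Brier score at t*, spreadsheet style: reverse KM for the
# censoring distribution computed with survival::survfit.
spreadsheetBrier <- function(predSurv, time, event, tStar) {
  g <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gat <- function(x) { # right-continuous
    i <- findInterval(x, g$time)
    c(1, g$surv)[i + 1]
  }
  GatMinus <- function(x) {
    i <- findInterval(x, g$time, left.open = TRUE)
    c(1, g$surv)[i + 1]
  }
  n <- length(time)
  tot <- 0
  for (i in seq_len(n)) {
    if (time[i] <= tStar && event[i] == 1) {
      tot <- tot + predSurv[i]^2 / GatMinus(time[i])
    } else if (time[i] > tStar) {
      tot <- tot + (1 - predSurv[i])^2 / Gat(tStar)
    }
  }
  tot / n
}

# Small genotype-survival dataset with a single informative column.
smallSurvData <- function(n, seed, beta1 = 0.5, q = 0.3, censScale = 3) {
  set.seed(seed)
  x <- sample(0:2, n, TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  tt <- rexp(n, rate = exp(beta1 * x))
  cc <- runif(n, 0, censScale)
  list(x = x, time = pmin(tt, cc), event = as.integer(tt <= cc))
}
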