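# Random-survival-forest minimal-depth selection. Trees are grown by
# ranger (log-rank statistic evaluated at a fixed number of random split
# points per candidate); the per-variable minimal depths, the per-tree
# topology (nodes per depth level) and the null minimal-depth threshold are
# computed here by traversing the exported tree structures.

#' Null distribution of the minimal depth of a noise variable
#'
#' Given a tree with \eqn{l_d} nodes at depth \eqn{d} (for
#' \eqn{d = 0, \dots, D(S)-1}) and \eqn{p} candidate variables, the minimal
#' depth \eqn{D_v} of a noise variable \eqn{v} has
#' \deqn{P(D_v = d) = (1 - 1/p)^{L_d} \{1 - (1 - 1/p)^{l_d}\}, \quad
#'   L_d = \sum_{i<d} l_i,}
#' for \eqn{d < D(S)}, with the remaining mass
#' \eqn{P(D_v = D(S)) = (1 - 1/p)^{L_{D(S)}}} at the tree depth itself
#' (the variable never splits). The masses telescope and sum to one.
#'
#' @param levelCounts integer vector \eqn{(l_0, \dots, l_{D(S)-1})} of
#'   non-terminal node counts per depth level.
#' @param p number of candidate variables.
#' @return list with \code{prob} (masses over \eqn{d = 0..D(S)}),
#'   \code{depths} and \code{mean} (the null mean minimal depth).
#' @examples
#' nullDepthDistribution(c(1, 2), p = 2)
#' @export
nullDepthDistribution <- function(levelCounts, p) {
  stopifnot(p >= 1, all(levelCounts >= 0))
  D <- length(levelCounts)
  q <- 1 - 1 / p
  Ld <- c(0, cumsum(levelCounts)) # L_0 .. L_D
  prob <- q^Ld[seq_len(D)] * (1 - q^levelCounts)
  prob <- c(prob, q^Ld[D + 1L])
  depths <- 0:D
  list(prob = prob, depths = depths, mean = sum(depths * prob))
}

# Parse one ranger treeInfo data.frame: node depths, per-depth non-terminal
# counts, tree depth D(S), and per-variable minimal depth (NA if unused).
.treeTopology <- function(ti, p) {
  nn <- nrow(ti)
  depth <- integer(nn) # node ids are 0-based row order
  for (i in seq_len(nn)) {
    if (!ti$terminal[i]) {
      depth[ti$leftChild[i] + 1L] <- depth[i] + 1L
      depth[ti$rightChild[i] + 1L] <- depth[i] + 1L
    }
  }
  DS <- max(depth)
  internal <- !ti$terminal
  lev <- tabulate(depth[internal] + 1L, nbins = max(DS, 1L))
  minDepth <- rep(NA_real_, p)
  if (any(internal)) {
    sv <- ti$splitvarID[internal] + 1L
    dv <- depth[internal]
    agg <- tapply(dv, sv, min)
    minDepth[as.integer(names(agg))] <- as.numeric(agg)
  }
  list(levelCounts = lev, DS = DS, minDepth = minDepth)
}

#' Random-survival-forest minimal-depth selection
#'
#' Grows a survival forest (log-rank splitting with \code{nSplit} random
#' split points per candidate variable), computes each variable's
#' forest-averaged minimal depth — variables never split upon in a tree are
#' assigned that tree's depth \eqn{D(S)}, the end of the null support — and
#' selects the variables whose average minimal depth is at or below the
#' forest-averaged mean of the null minimal-depth distribution
#' ([nullDepthDistribution()]) evaluated on each tree's observed topology.
#'
#' @param X a [GenotypeMatrix-class] or numeric matrix with at least two
#'   columns.
#' @param outcome a [SurvivalOutcome-class].
#' @param nTrees number of trees.
#' @param nSplit number of random split points per candidate.
#' @param seed integer seed (forest growth is deterministic given it).
#' @return a [SelectionResult-class]; \code{depthThreshold} holds the null
#'   mean threshold and the metadata carries the per-variable average
#'   minimal depths.
#' @export
rsfMinimalDepth <- function(X, outcome, nTrees = 100L, nSplit = 10L,
                            seed = 1L) {
  v <- if (is(X, "GenotypeMatrix")) genoValues(X) else as.matrix(X)
  p <- ncol(v)
  stopifnot(p >= 2L)
  df <- as.data.frame(v)
  names(df) <- sprintf("x%d", seq_len(p))
  rf <- ranger::ranger(
    x = df, y = asSurv(outcome),
    num.trees = nTrees, splitrule = "extratrees",
    num.random.splits = nSplit, seed = as.integer(seed),
    num.threads = 1L
  )
  depthSum <- numeric(p)
  nullMeanSum <- 0
  nUsable <- 0L
  for (b in seq_len(rf$num.trees)) {
    ti <- ranger::treeInfo(rf, b)
    topo <- .treeTopology(ti, p)
    if (topo$DS == 0L) next # stump with no split
    nUsable <- nUsable + 1L
    md <- topo$minDepth
    md[is.na(md)] <- topo$DS
    depthSum <- depthSum + md
    nullMeanSum <- nullMeanSum +
      nullDepthDistribution(topo$levelCounts, p)$mean
  }
  if (nUsable == 0L) {
    warning("forest contains no valid splits; empty selection")
    return(new("SelectionResult", selected = integer(0),
               coefficients = numeric(0), lambdaChosen = NA_real_,
               depthThreshold = NA_real_, method = "RSF",
               meta = list(nUsableTrees = 0L)))
  }
  avgDepth <- depthSum / nUsable
  threshold <- nullMeanSum / nUsable
  sel <- which(avgDepth <= threshold)
  new("SelectionResult",
      selected = as.integer(sel), coefficients = numeric(0),
      lambdaChosen = NA_real_, depthThreshold = threshold,
      method = "RSF",
      meta = list(avgMinimalDepth = avgDepth, nUsableTrees = nUsable))
}
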