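#' Logarithmic weight-to-distance transform
#'
#' Maps connection weights to path lengths so stronger connections are
#' shorter: length `-log(w)` for `w` in (0, 1). Non-positive weights are
#' removed (length `+Inf`, only non-negative edges enter the graph); weights
#' at or above 1 are clipped to `1 - 1e-10` before the transform. The
#' diagonal is 0.
#'
#' @param fc symmetric weight matrix (correlations).
#' @return distance matrix of the same dimension.
#' @examples
#' weightsToDistances(matrix(c(1, exp(-1), exp(-1), 1), 2))[1, 2]  # 1
#' @export
weightsToDistances <- function(fc) {
  fc <- as.matrix(fc)
  d <- matrix(Inf, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  pos <- fc > 0
  d[pos] <- -log(pmin(fc[pos], 1 - 1e-10))
  diag(d) <- 0
  d
}

#' All-pairs shortest path lengths (Floyd-Warshall)
#'
#' Closes a distance matrix under relaying: the returned entry (i, j) is the
#' length of the shortest path from i to j; unreachable pairs stay `+Inf`.
#'
#' @param dist nonnegative symmetric distance matrix, 0 diagonal, `+Inf` for
#'   absent edges.
#' @return shortest-path distance matrix.
#' @export
shortestPaths <- function(dist) {
  dist <- as.matrix(dist)
  stopifnot(nrow(dist) == ncol(dist))
  out <- .floydWarshallCpp(dist)
  dimnames(out) <- dimnames(dist)
  out
}

#' Weighted global efficiency
#'
#' Mean of inverse shortest path lengths, `Eg = mean(1 / d(i, j))` over the
#' selected ordered pairs, with unreachable pairs contributing 0 (they stay in
#' the denominator, keeping Eg comparable across graphs of equal size).
#'
#' @param spl closed shortest-path matrix (see [shortestPaths()]).
#' @param pairMask optional logical matrix selecting the pairs that enter the
#'   average (the diagonal is always excluded); default: all pairs `i != j`.
#' @return scalar efficiency.
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 1
#' globalEfficiency(shortestPaths(weightsToDistances(w)))  # 1/log(2)
#' @export
globalEfficiency <- function(spl, pairMask = NULL) {
  spl <- as.matrix(spl)
  if (is.null(pairMask)) pairMask <- matrix(TRUE, nrow(spl), ncol(spl))
  keep <- pairMask & !diag(TRUE, nrow(spl))
  if (!any(keep)) stop("empty pair mask")
  inv <- 1 / spl[keep]
  inv[is.infinite(spl[keep])] <- 0
  mean(inv)
}

#' Weight-distribution-preserving null model
#'
#' Randomly permutes the upper-triangular off-diagonal weights as a multiset
#' and mirrors them to the lower triangle. The exact multiset of weights (and
#' the node count) is preserved; the degree sequence is not.
#'
#' @param fc symmetric weight matrix.
#' @return shuffled symmetric matrix with the same weight multiset.
#' @export
shuffleWeights <- function(fc) {
  fc <- as.matrix(fc)
  ut <- upper.tri(fc)
  v <- fc[ut]
  fc[ut] <- if (length(v) > 1L) sample(v) else v
  fc[lower.tri(fc)] <- t(fc)[lower.tri(fc)]
  fc
}

.nodeSpecMask <- function(n1, n2) {
  # joint submatrix = [set1, set2]; TRUE for cross-set pairs only
  g <- rep(c(1L, 2L), c(n1, n2))
  outer(g, g, `!=`)
}

#' Null-normalized efficiency for a node-set specification
#'
#' Computes raw weighted global efficiency for the whole graph (`set1` and
#' `set2` both `NULL`), a within-set analysis (`set1` only: the submatrix of
#' those nodes), or a between-set analysis (both sets: the joint submatrix of
#' the two disjoint sets, with within-set pairs excluded from the average so
#' only cross-set inverse path lengths are pooled -- paths may still relay
#' through within-set edges). The value is normalized by the mean efficiency
#' of `nNull` weight-shuffled surrogate graphs; shuffling is applied to the
#' (sub)matrix before the distance transform.
#'
#' @param fc symmetric ROI x ROI weight matrix.
#' @param set1,set2 integer ROI indices (or `NULL`); between-set requires
#'   disjoint sets.
#' @param nNull number of null realizations (draws from R's RNG stream).
#' @return an [EfficiencyResult-class].
#' @export
normalizedEfficiency <- function(fc, set1 = NULL, set2 = NULL, nNull = 100L) {
  fc <- as.matrix(fc)
  if (is.null(set1) && !is.null(set2)) stop("set2 given without set1")
  if (is.null(set1)) {
    sub <- fc
    mask <- matrix(TRUE, nrow(sub), ncol(sub))
    spec <- sprintf("whole graph (%d nodes)", nrow(fc))
  } else if (is.null(set2)) {
    if (length(set1) < 2L) stop("within-set analysis needs >= 2 nodes")
    sub <- fc[set1, set1, drop = FALSE]
    mask <- matrix(TRUE, nrow(sub), ncol(sub))
    spec <- sprintf("within-set (%d nodes)", length(set1))
  } else {
    if (length(intersect(set1, set2)))
      stop("between-set analysis needs disjoint sets")
    idx <- c(set1, set2)
    sub <- fc[idx, idx, drop = FALSE]
    mask <- .nodeSpecMask(length(set1), length(set2))
    spec <- sprintf("between-set (%d x %d nodes)", length(set1), length(set2))
  }
  res <- .effNormCpp(sub, mask, as.integer(nNull))
  egRand <- as.numeric(res$egRand)
  mu <- mean(egRand)
  new("EfficiencyResult", eg = res$eg, egRand = egRand,
      egNorm = if (isTRUE(mu > 0)) res$eg / mu else NA_real_,
      nNull = as.integer(nNull), nodeSpec = spec)
}

#' @rdname EfficiencyResult-class
#' @aliases egNorm,EfficiencyResult-method
setMethod("egNorm", "EfficiencyResult", function(x) x@egNorm)

setMethod("show", "EfficiencyResult", function(object) {
  cat(sprintf("EfficiencyResult [%s]: eg = %.5f, egRand = %.5f (n = %d), egNorm = %.5f\n",
              object@nodeSpec, object@eg, mean(object@egRand), object@nNull,
              object@egNorm))
})

#' Null-normalized efficiency at all three spatial levels
#'
#' Applies [normalizedEfficiency()] to the whole brain, to every hierarchy
#' analysis (within unimodal/attention/transmodal and the three between
#' pairs) and to all 28 network analyses (7 within, 21 between). The global
#' within/between-network scalars are the unweighted means of the 7 and 21
#' normalized network values.
#'
#' @param fc symmetric ROI x ROI matrix.
#' @param partition a [NetworkPartition-class].
#' @param nNull null realizations per analysis.
#' @return a [LevelSummary-class] of normalized efficiencies.
#' @export
efficiencyLevels <- function(fc, partition, nNull = 100L) {
  stopifnot(is(partition, "NetworkPartition"))
  if (nrow(fc) != nRois(partition))
    stop("fc dimension does not match the partition")
  nets <- networkNames()
  members <- lapply(setNames(nets, nets),
                    function(nw) networkMembers(partition, nw))
  # fixed analysis order (whole brain, hierarchy, network) so a seeded run
  # is reproducible spec by spec
  wholeBrain <- normalizedEfficiency(fc, nNull = nNull)@egNorm
  hier <- vapply(.hierarchyContrasts(), function(hc) {
    if (hc[1L] == hc[2L])
      normalizedEfficiency(fc, hierarchyMembers(partition, hc[1L]),
                           nNull = nNull)@egNorm
    else
      normalizedEfficiency(fc, hierarchyMembers(partition, hc[1L]),
                           hierarchyMembers(partition, hc[2L]),
                           nNull = nNull)@egNorm
  }, 0)
  netMat <- matrix(NA_real_, 7L, 7L, dimnames = list(nets, nets))
  for (i in seq_len(7L)) for (j in i:7L) {
    r <- if (i == j) normalizedEfficiency(fc, members[[i]], nNull = nNull)
         else normalizedEfficiency(fc, members[[i]], members[[j]],
                                   nNull = nNull)
    netMat[i, j] <- netMat[j, i] <- r@egNorm
  }
  glob <- c(whole_brain = wholeBrain,
            within_network = mean(diag(netMat)),
            between_network = mean(netMat[upper.tri(netMat)]))
  new("LevelSummary", global = glob, hierarchy = hier, network = netMat)
}
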