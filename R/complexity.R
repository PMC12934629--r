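#' Non-overlapping window index ranges
#'
#' Segments `nFrames` frames into `floor(nFrames / width)` consecutive
#' disjoint windows of `width` frames; the trailing remainder is dropped.
#'
#' @param nFrames number of frames.
#' @param width frames per window (default 5 TRs).
#' @return list of integer frame-index vectors.
#' @examples
#' length(makeWindows(203, 5))  # 40; frames 201-203 dropped
#' @export
makeWindows <- function(nFrames, width = 5L) {
  width <- as.integer(width)
  if (width < 2L) stop("window width must be >= 2")
  if (nFrames < width)
    stop("nFrames (", nFrames, ") smaller than window width (", width, ")")
  nWin <- nFrames %/% width
  lapply(seq_len(nWin) - 1L, function(k) (k * width + 1L):((k + 1L) * width))
}

#' Windowed interaction matrix
#'
#' Cross-product of two windowed time-series blocks,
#' `M[i, j] = sum_t X1[t, i] * X2[t, j]`, optionally mean-centered by
#' subtracting the scalar global mean of `M` from every entry. With
#' `X1 == X2` the result is a symmetric square self-interaction matrix.
#'
#' @param x1,x2 numeric matrices over the same frame range (frames x ROIs of
#'   set 1 and set 2).
#' @param center subtract the global mean (default `TRUE`).
#' @return `n1 x n2` interaction matrix.
#' @export
interactionMatrix <- function(x1, x2, center = TRUE) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) != nrow(x2))
    stop("x1 and x2 must cover the same frame range")
  M <- crossprod(x1, x2)
  if (center) M <- M - mean(M)
  M
}

#' Normalized entropy of the singular-value spectrum
#'
#' The interaction-complexity statistic of one matrix:
#' `C = -(1/log2 K) * sum_k p_k log2 p_k` with `p_k = s_k / sum_j s_j`,
#' `s_k` the singular values, `K = min(nrow, ncol)` their count (zeros
#' contribute nothing to the sum but keep the `log2 K` scale), and
#' `0 * log 0 = 0`. `C` is 0 when a single mode dominates (rank-1 `M`) and 1
#' when all `K` modes contribute equally; it always lies in [0, 1].
#'
#' @param M numeric matrix with `min(dim(M)) >= 2`.
#' @return scalar in [0, 1], or `NA` for an all-zero matrix (undefined
#'   complexity; windowed callers skip such windows).
#' @examples
#' singularEntropy(diag(c(3, 3, 3, 3)))  # 1: uniform spectrum
#' singularEntropy(diag(c(3, 0, 0, 0)))  # 0: rank-1 dominance
#' @export
singularEntropy <- function(M) {
  M <- as.matrix(M)
  K <- min(dim(M))
  if (K < 2L) stop("need min(dim(M)) >= 2 singular values")
  s <- svd(M, nu = 0L, nv = 0L)$d
  tot <- sum(s)
  if (!(tot > 0)) return(NA_real_)
  p <- s / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(K)
}

#' Windowed interaction complexity of one recording
#'
#' Segments the time series into non-overlapping windows, builds the
#' mean-centered interaction matrix of (`set1`, `set2`) for each window,
#' scores each with [singularEntropy()], and averages over the valid windows
#' (all-zero windows are skipped).
#'
#' @param ts frames x ROIs matrix.
#' @param set1,set2 integer ROI column indices (each of size >= 2);
#'   `set1 == set2` gives the self-interaction (square symmetric) variant.
#' @param width frames per window.
#' @return a [ComplexityResult-class].
#' @export
interactionComplexity <- function(ts, set1, set2, width = 5L) {
  ts <- as.matrix(ts)
  if (length(set1) < 2L || length(set2) < 2L)
    stop("both node sets need >= 2 ROIs")
  win <- makeWindows(nrow(ts), width)
  perWindow <- vapply(win, function(fr) {
    singularEntropy(interactionMatrix(ts[fr, set1, drop = FALSE],
                                      ts[fr, set2, drop = FALSE]))
  }, 0)
  valid <- perWindow[!is.na(perWindow)]
  if (!length(valid)) stop("no window yields a defined complexity value")
  new("ComplexityResult", perWindow = valid, cMean = mean(valid),
      nodeSpec = sprintf("(%d x %d nodes), %d/%d windows of %d frames",
                         length(set1), length(set2), length(valid),
                         length(win), width))
}

#' @rdname ComplexityResult-class
#' @aliases cMean,ComplexityResult-method
setMethod("cMean", "ComplexityResult", function(x) x@cMean)

setMethod("show", "ComplexityResult", function(object) {
  cat(sprintf("ComplexityResult %s: C = %.5f\n", object@nodeSpec,
              object@cMean))
})

## list of the 35 node-set specs (whole brain, 6 hierarchy, 28 network) in a
## fixed order; shared by complexityLevels and the C++ sweep
.levelSpecs <- function(partition) {
  nets <- networkNames()
  members <- lapply(setNames(nets, nets),
                    function(nw) networkMembers(partition, nw))
  set1 <- list(seq_len(nRois(partition)))
  set2 <- list(seq_len(nRois(partition)))
  labels <- data.frame(level = "global", contrast = "whole_brain")
  for (hc in names(.hierarchyContrasts())) {
    h <- .hierarchyContrasts()[[hc]]
    set1 <- c(set1, list(hierarchyMembers(partition, h[1L])))
    set2 <- c(set2, list(hierarchyMembers(partition, h[2L])))
    labels <- rbind(labels, data.frame(level = "hierarchy", contrast = hc))
  }
  for (np in names(.networkPairs())) {
    p <- .networkPairs()[[np]]
    set1 <- c(set1, list(members[[p[1L]]]))
    set2 <- c(set2, list(members[[p[2L]]]))
    labels <- rbind(labels, data.frame(level = "network", contrast = np))
  }
  list(set1 = set1, set2 = set2, labels = labels)
}

#' Interaction complexity at all three spatial levels
#'
#' Whole-brain self-interaction, the six hierarchy analyses and all 28
#' network analyses (within-network self-interactions on the diagonal,
#' rectangular between-network interactions off it); the global
#' within/between-network scalars are the unweighted means of the 7 and 21
#' network values. Identical windowing is applied to every analysis.
#'
#' @param ts frames x ROIs matrix.
#' @param partition a [NetworkPartition-class].
#' @param width frames per window.
#' @return a [LevelSummary-class] of window-averaged complexities.
#' @export
complexityLevels <- function(ts, partition, width = 5L) {
  ts <- as.matrix(ts)
  stopifnot(is(partition, "NetworkPartition"))
  if (ncol(ts) != nRois(partition))
    stop("ts columns do not match the partition")
  makeWindows(nrow(ts), width)  # validates frame count
  specs <- .levelSpecs(partition)
  vals <- .windowComplexityCpp(ts, specs$set1, specs$set2, as.integer(width))
  lab <- specs$labels
  netMat <- matrix(NA_real_, 7L, 7L,
                   dimnames = list(networkNames(), networkNames()))
  for (k in which(lab$level == "network")) {
    nm <- strsplit(lab$contrast[k], "-", fixed = TRUE)[[1L]]
    netMat[nm[1L], nm[2L]] <- netMat[nm[2L], nm[1L]] <- vals[k]
  }
  hier <- setNames(vals[lab$level == "hierarchy"],
                   lab$contrast[lab$level == "hierarchy"])
  glob <- c(whole_brain = vals[lab$level == "global"],
            within_network = mean(diag(netMat)),
            between_network = mean(netMat[upper.tri(netMat)]))
  names(glob) <- c("whole_brain", "within_network", "between_network")
  new("LevelSummary", global = glob, hierarchy = hier, network = netMat)
}
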