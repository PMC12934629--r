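#' Signed effect-size ranks per analysis-metric pair
#'
#' Within each analysis-metric pair (the 3 global and 6 hierarchy analyses of
#' each metric: 27 pairs for three metrics), ranks the states by the signed
#' Cohen's d value -- not its magnitude -- so rank 1 is the most negative and
#' the highest rank the most positive effect; ties receive average ranks.
#'
#' @param effectTable output of [buildEffectTable()]; must contain every
#'   state for every global/hierarchy analysis.
#' @return data.frame with columns `metric`, `analysis` (level:contrast),
#'   `state`, `d`, `rank`.
#' @export
rankStates <- function(effectTable) {
  tab <- effectTable[effectTable$level %in% c("global", "hierarchy"), ]
  if (!nrow(tab)) stop("no global/hierarchy rows in the effect table")
  if (any(tab$undefined))
    stop("undefined effects in the table; cannot rank")
  tab$analysis <- paste(tab$level, tab$contrast, sep = ":")
  states <- unique(tab$state)
  pairs <- unique(tab[c("metric", "analysis")])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- tab$metric == pairs$metric[i] & tab$analysis == pairs$analysis[i]
    sub <- tab[sel, ]
    if (!setequal(sub$state, states) || nrow(sub) != length(states))
      stop("analysis ", pairs$analysis[i], " (", pairs$metric[i],
           ") does not cover every state exactly once")
    data.frame(metric = sub$metric, analysis = sub$analysis,
               state = sub$state, d = sub$d, rank = rank(sub$d))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Composite (average) rank of each state
#'
#' Arithmetic mean of a state's ranks across all analysis-metric pairs.
#'
#' @param rankTable output of [rankStates()].
#' @return data.frame `state`, `meanRank`, sorted by decreasing mean rank.
#' @export
compositeRank <- function(rankTable) {
  nPairs <- nrow(unique(rankTable[c("metric", "analysis")]))
  counts <- table(rankTable$state)
  if (length(unique(counts)) != 1L || counts[1L] != nPairs)
    stop("incomplete rank table: every state needs one rank per pair")
  mr <- tapply(rankTable$rank, rankTable$state, mean)
  out <- data.frame(state = names(mr), meanRank = as.numeric(mr))
  out[order(-out$meanRank), , drop = FALSE]
}

#' Kendall's tau agreement of each analysis-metric ranking with the composite
#'
#' Tie-corrected Kendall's tau (tau-b) between each pair's state ranking and
#' the composite ranking.
#'
#' @param rankTable output of [rankStates()].
#' @param composite optional output of [compositeRank()]; computed if absent.
#' @return data.frame `metric`, `analysis`, `tau` (`NA` for a constant
#'   ranking, flagged by `undefined`).
#' @export
rankAgreement <- function(rankTable, composite = NULL) {
  if (is.null(composite)) composite <- compositeRank(rankTable)
  ref <- setNames(composite$meanRank, composite$state)
  pairs <- unique(rankTable[c("metric", "analysis")])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- rankTable$metric == pairs$metric[i] &
      rankTable$analysis == pairs$analysis[i]
    sub <- rankTable[sel, ]
    tau <- if (sd(sub$rank) == 0 || sd(ref[sub$state]) == 0) NA_real_
           else cor(sub$rank, ref[sub$state], method = "kendall")
    data.frame(metric = pairs$metric[i], analysis = pairs$analysis[i],
               tau = tau, undefined = is.na(tau))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

## canonical feature ordering: metric-major, then the 28 upper-triangular
## network pairs (diagonal included) in canonical network order
.featureInfo <- function(metrics = c("FC", "EFF", "CPLX")) {
  pairs <- .networkPairs()
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(metric = m,
               net1 = vapply(pairs, `[`, "", 1L),
               net2 = vapply(pairs, `[`, "", 2L),
               contrast = names(pairs), row.names = NULL)
  }))
}

#' Network-level effect feature matrix
#'
#' Concatenates, per state, the 28 upper-triangular entries (diagonal
#' included) of the 7 x 7 network effect-size matrix of each metric, in the
#' fixed metric-major order FC, EFF, CPLX, yielding an 84 x 9 features x
#' states matrix.
#'
#' @param effectTable output of [buildEffectTable()] with network-level rows
#'   for all 28 pairs x 3 metrics x all states.
#' @return numeric matrix (features x states) with a `featureInfo` attribute.
#' @export
buildFeatureMatrix <- function(effectTable) {
  tab <- effectTable[effectTable$level == "network", ]
  states <- unique(tab$state)
  info <- .featureInfo(intersect(c("FC", "EFF", "CPLX"), unique(tab$metric)))
  key <- paste(tab$metric, tab$contrast)
  X <- matrix(NA_real_, nrow(info), length(states),
              dimnames = list(paste(info$metric, info$contrast, sep = "|"),
                              states))
  for (j in seq_along(states)) {
    sel <- tab$state == states[j]
    idx <- match(paste(info$metric, info$contrast), key[sel])
    if (anyNA(idx))
      stop("missing network-level cell(s) for state ", states[j])
    X[, j] <- tab$d[sel][idx]
  }
  attr(X, "featureInfo") <- info
  X
}

#' Uncentered principal component analysis of state effect profiles
#'
#' Singular decomposition of the raw feature x state matrix -- no centering,
#' because a zero effect is meaningful and must stay at the origin. States
#' are the observations (columns of `X`), features the variables. Explained
#' variance is defined as squared singular value over the total sum of
#' squares (not variance about a mean). Each component's sign is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param X features x states matrix from [buildFeatureMatrix()].
#' @return a [StatePCA-class].
#' @export
pcaUncentered <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (all(X == 0)) stop("all-zero feature matrix")
  D <- t(X)                         # observations (states) x variables
  sv <- svd(D)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(D)
  rownames(loadings) <- colnames(D)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(sv$d))
  fi <- attr(X, "featureInfo")
  new("StatePCA", scores = scores, loadings = loadings,
      singularValues = sv$d, varExplained = sv$d^2 / sum(sv$d^2),
      featureInfo = if (is.null(fi)) data.frame() else fi)
}

setMethod("show", "StatePCA", function(object) {
  cat("StatePCA:", nrow(object@scores), "states,",
      nrow(object@loadings), "features\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of total sum of squares\n",
              100 * object@varExplained[1L], 100 * object@varExplained[2L]))
})

#' Reshape PC1 loadings into per-metric network matrices
#'
#' Inverts the feature ordering of [buildFeatureMatrix()]: the PC1 loading of
#' each feature is placed at its (network_i, network_j) cell of the metric's
#' 7 x 7 upper-triangular map.
#'
#' @param pca a [StatePCA-class] built from the 84-feature matrix.
#' @param component which component's loadings to reshape (default 1).
#' @return named list of three 7 x 7 matrices (upper triangle incl. diagonal
#'   filled, remainder `NA`).
#' @export
pc1LoadingMatrices <- function(pca, component = 1L) {
  stopifnot(is(pca, "StatePCA"))
  info <- pca@featureInfo
  if (!nrow(info))
    stop("this StatePCA carries no feature metadata")
  if (nrow(info) != nrow(pca@loadings))
    stop("feature metadata does not match the loading matrix")
  v <- pca@loadings[, component]
  nets <- networkNames()
  out <- list()
  for (m in unique(info$metric)) {
    M <- matrix(NA_real_, 7L, 7L, dimnames = list(nets, nets))
    sel <- info$metric == m
    M[cbind(match(info$net1[sel], nets), match(info$net2[sel], nets))] <-
      v[sel]
    out[[m]] <- M
  }
  out
}
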