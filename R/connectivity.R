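#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlation between all ROI time series of one recording.
#' The result is forced exactly symmetric with a unit diagonal.
#'
#' @param ts numeric matrix, frames x ROIs (at least 2 frames, every column
#'   with nonzero variance).
#' @return symmetric ROI x ROI correlation matrix.
#' @examples
#' computeFC(cbind(a = c(0, 1, 2), b = c(0, 2, 1)))["a", "b"]  # 0.5
#' @export
computeFC <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("need at least 2 frames")
  v <- apply(ts, 2L, sd)
  if (any(v == 0)) {
    bad <- if (is.null(colnames(ts))) which(v == 0) else colnames(ts)[v == 0]
    stop("zero-variance ROI time series: ", paste(bad, collapse = ", "))
  }
  fc <- cor(ts)
  fc <- (fc + t(fc)) / 2
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  diag(fc) <- 1
  fc
}

#' Mean connectivity over a block of ROI pairs
#'
#' Averages matrix entries over all unordered ROI pairs \{i, j\} with
#' `i` in `rows`, `j` in `cols`, each unordered pair counted once, excluding
#' self-pairs when `excludeSelf` (the default). With `rows = cols` covering
#' all ROIs this is the whole-brain average excluding self-connections.
#'
#' @param fc symmetric matrix.
#' @param rows,cols integer index vectors (or ROI names) of the two sets.
#' @param excludeSelf drop pairs with `i == j`.
#' @return scalar mean.
#' @examples
#' m <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3)
#' meanBlock(m, 1:3, 1:3)  # mean of .1, .2, .3
#' @export
meanBlock <- function(fc, rows, cols, excludeSelf = TRUE) {
  if (is.character(rows)) rows <- match(rows, rownames(fc))
  if (is.character(cols)) cols <- match(cols, colnames(fc))
  if (!length(rows) || !length(cols) || anyNA(rows) || anyNA(cols))
    stop("rows and cols must be nonempty sets of valid ROIs")
  sel <- matrix(FALSE, nrow(fc), ncol(fc))
  sel[rows, cols] <- TRUE
  sel <- sel | t(sel)               # unordered pairs
  keep <- sel & upper.tri(sel, diag = FALSE)
  if (!excludeSelf) {
    d <- intersect(rows, cols)
    keep[cbind(d, d)] <- TRUE
  }
  if (!any(keep)) stop("no ROI pairs selected")
  mean(fc[keep])
}

.hierarchyContrasts <- function() {
  list(`U-U` = c("unimodal", "unimodal"),
       `A-A` = c("attention", "attention"),
       `T-T` = c("transmodal", "transmodal"),
       `U-A` = c("unimodal", "attention"),
       `U-T` = c("unimodal", "transmodal"),
       `A-T` = c("attention", "transmodal"))
}

.networkPairs <- function() {
  nets <- networkNames()
  out <- list()
  for (i in seq_len(7L)) for (j in i:7L)
    out[[paste(nets[i], nets[j], sep = "-")]] <- c(nets[i], nets[j])
  out
}

#' Multi-level summary of a connectivity matrix
#'
#' Fills the three spatial levels used throughout the package. The whole-brain
#' value is the mean of all unique off-diagonal pairs; hierarchy contrasts
#' pool ROI pairs within/between the unimodal, attention and transmodal
#' classes (limbic ROIs excluded); the network level is the 7 x 7 matrix of
#' block means. The global within/between-network scalars are, by default,
#' the unweighted means of the 7 diagonal and 21 off-diagonal network-level
#' entries (`pooling = "block"`); `pooling = "pairs"` pools ROI pairs
#' directly instead.
#'
#' @param fc symmetric ROI x ROI matrix.
#' @param partition a [NetworkPartition-class] covering the ROIs of `fc`.
#' @param pooling convention for the global within/between-network scalars.
#' @return a [LevelSummary-class].
#' @export
summarizeLevels <- function(fc, partition, pooling = c("block", "pairs")) {
  pooling <- match.arg(pooling)
  stopifnot(is(partition, "NetworkPartition"))
  if (nrow(fc) != nRois(partition))
    stop("fc dimension does not match the partition (",
         nrow(fc), " vs ", nRois(partition), " ROIs)")
  nets <- networkNames()
  members <- lapply(setNames(nets, nets),
                    function(nw) networkMembers(partition, nw))
  netMat <- matrix(NA_real_, 7L, 7L, dimnames = list(nets, nets))
  for (i in seq_len(7L)) for (j in i:7L) {
    netMat[i, j] <- netMat[j, i] <-
      meanBlock(fc, members[[i]], members[[j]])
  }
  hier <- vapply(.hierarchyContrasts(), function(hc) {
    meanBlock(fc, hierarchyMembers(partition, hc[1L]),
              hierarchyMembers(partition, hc[2L]))
  }, 0)
  off <- upper.tri(netMat)
  glob <- if (pooling == "block") {
    c(whole_brain = meanBlock(fc, seq_len(nrow(fc)), seq_len(nrow(fc))),
      within_network = mean(diag(netMat)),
      between_network = mean(netMat[off]))
  } else {
    wiPairs <- unlist(lapply(members, function(ix) {
      m <- fc[ix, ix]
      m[upper.tri(m)]
    }))
    bePairs <- unlist(lapply(which(off), function(k) {
      ij <- arrayInd(k, dim(netMat))
      fc[members[[ij[1L]]], members[[ij[2L]]]]
    }))
    c(whole_brain = meanBlock(fc, seq_len(nrow(fc)), seq_len(nrow(fc))),
      within_network = mean(wiPairs),
      between_network = mean(bePairs))
  }
  new("LevelSummary", global = glob, hierarchy = hier, network = netMat)
}

#' @rdname LevelSummary-class
#' @aliases globalLevel,LevelSummary-method
setMethod("globalLevel", "LevelSummary", function(x) x@global)

#' @rdname LevelSummary-class
setMethod("hierarchyLevel", "LevelSummary", function(x) x@hierarchy)

#' @rdname LevelSummary-class
setMethod("networkLevel", "LevelSummary", function(x) x@network)

setMethod("show", "LevelSummary", function(object) {
  cat("LevelSummary\n  global:   ",
      paste(sprintf("%s=%.4f", names(object@global), object@global),
            collapse = "  "), "\n  hierarchy:",
      paste(sprintf("%s=%.4f", names(object@hierarchy), object@hierarchy),
            collapse = "  "), "\n  network:   7 x 7 block-mean matrix\n")
})

## long-format rows of one LevelSummary (internal glue shared by the metric
## stages and the pipeline)
.levelsToLong <- function(ls, metric) {
  rbind(
    data.frame(metric = metric, level = "global",
               contrast = names(ls@global), value = unname(ls@global)),
    data.frame(metric = metric, level = "hierarchy",
               contrast = names(ls@hierarchy), value = unname(ls@hierarchy)),
    {
      off <- which(upper.tri(ls@network, diag = TRUE), arr.ind = TRUE)
      data.frame(metric = metric, level = "network",
                 contrast = paste(rownames(ls@network)[off[, 1L]],
                                  colnames(ls@network)[off[, 2L]], sep = "-"),
                 value = ls@network[off])
    })
}
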