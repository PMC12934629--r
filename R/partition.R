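#' Build a network partition from contiguous blocks
#'
#' Assigns `nRois` ROIs to the seven canonical networks as contiguous blocks
#' in the fixed order VIS, SMN, DAN, VAN, LIM, FPN, DMN, and attaches the
#' three-tier hierarchy labels (unimodal = VIS+SMN, attention = DAN+VAN,
#' transmodal = FPN+DMN; LIM carries none).
#'
#' @param nRois total number of ROIs.
#' @param networkSizes integer vector of 7 block sizes summing to `nRois`,
#'   each at least 2 (block averages and within-set efficiency need two
#'   nodes).
#' @param roiIds optional ROI identifiers; defaults to `ROI001, ...`.
#' @return a [NetworkPartition-class].
#' @examples
#' p <- makePartition(14, rep(2, 7))
#' networkOf(p)
#' hierarchyMembers(p, "unimodal")
#' @export
makePartition <- function(nRois, networkSizes,
                          roiIds = sprintf("ROI%03d", seq_len(nRois))) {
  if (length(networkSizes) != 7L)
    stop("networkSizes must have length 7 (one per canonical network)")
  networkSizes <- as.integer(networkSizes)
  if (any(networkSizes < 2L))
    stop("every network needs at least 2 ROIs")
  if (sum(networkSizes) != nRois)
    stop("networkSizes must sum to nRois (got ", sum(networkSizes),
         " vs ", nRois, ")")
  if (length(roiIds) != nRois) stop("roiIds must have length nRois")
  new("NetworkPartition", roiIds = as.character(roiIds),
      network = rep(networkNames(), networkSizes))
}

#' @rdname NetworkPartition-class
#' @aliases roiIds,NetworkPartition-method
setMethod("roiIds", "NetworkPartition", function(x) x@roiIds)

#' @rdname NetworkPartition-class
setMethod("nRois", "NetworkPartition", function(x) length(x@roiIds))

#' @rdname NetworkPartition-class
setMethod("networkOf", "NetworkPartition",
          function(x) setNames(x@network, x@roiIds))

#' @rdname NetworkPartition-class
setMethod("hierarchyOf", "NetworkPartition",
          function(x) setNames(unname(.hierarchyMap[x@network]), x@roiIds))

#' @rdname NetworkPartition-class
setMethod("networkMembers", "NetworkPartition", function(x, network) {
  network <- match.arg(network, networkNames())
  which(x@network == network)
})

#' @rdname NetworkPartition-class
setMethod("hierarchyMembers", "NetworkPartition", function(x, hierarchy) {
  hierarchy <- match.arg(hierarchy, hierarchyNames())
  h <- unname(.hierarchyMap[x@network])
  which(!is.na(h) & h == hierarchy)
})

setMethod("show", "NetworkPartition", function(object) {
  sizes <- table(factor(object@network, levels = networkNames()))
  cat("NetworkPartition:", length(object@roiIds), "ROIs in 7 networks\n")
  cat(" ", paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "), "\n")
})

#' Read and write partition tables
#'
#' The partition file contract: a TSV with columns `roi_id`, `network` and
#' `hierarchy` (the latter derived, written for human consumption and checked
#' on read).
#'
#' @param x a [NetworkPartition-class].
#' @param path file path.
#' @return `readPartition` returns a [NetworkPartition-class];
#'   `writePartition` returns `path` invisibly.
#' @export
writePartition <- function(x, path) {
  stopifnot(is(x, "NetworkPartition"))
  df <- data.frame(roi_id = x@roiIds, network = x@network,
                   hierarchy = unname(.hierarchyMap[x@network]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("roi_id", "network") %in% names(df)))
    stop("partition file needs columns roi_id and network: ", path)
  p <- new("NetworkPartition", roiIds = as.character(df$roi_id),
           network = df$network)
  if ("hierarchy" %in% names(df)) {
    want <- unname(.hierarchyMap[p@network])
    got <- df$hierarchy
    got[got %in% c("", "NA", "none")] <- NA_character_
    if (!identical(is.na(got), is.na(want)) ||
        !all(got[!is.na(got)] == want[!is.na(want)]))
      stop("hierarchy column disagrees with the canonical network-to-",
           "hierarchy map in ", path)
  }
  p
}
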