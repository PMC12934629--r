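#' @useDynLib BrainStates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor filter p.adjust pt rnorm sd setNames
#' @importFrom utils read.delim write.table head combn
NULL

## Canonical network and hierarchy vocabulary -------------------------------

#' Canonical network and hierarchy labels
#'
#' The seven canonical cortical networks, in the fixed order used throughout
#' the package, and the three-tier cortical hierarchy they map onto
#' (unimodal = VIS, SMN; attention = DAN, VAN; transmodal = FPN, DMN; the
#' limbic network carries no hierarchy label).
#'
#' @return `networkNames()` returns a character vector of length 7;
#'   `hierarchyNames()` a character vector of length 3.
#' @examples
#' networkNames()
#' hierarchyNames()
#' @export
networkNames <- function() c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN")

#' @rdname networkNames
#' @export
hierarchyNames <- function() c("unimodal", "attention", "transmodal")

.hierarchyMap <- c(VIS = "unimodal", SMN = "unimodal",
                   DAN = "attention", VAN = "attention",
                   LIM = NA_character_,
                   FPN = "transmodal", DMN = "transmodal")

## NetworkPartition ----------------------------------------------------------

#' NetworkPartition: ROI-to-network assignment
#'
#' Maps each region of interest (ROI) of a parcellation onto one of the seven
#' canonical networks, from which the three-tier cortical hierarchy labels are
#' derived. This object is the backbone of all level-wise averaging: every
#' global, hierarchy and network summary is defined relative to it.
#'
#' @slot roiIds character vector of unique ROI identifiers, in matrix column
#'   order.
#' @slot network character vector parallel to `roiIds`, each entry one of
#'   [networkNames()].
#' @seealso [makePartition()]
#' @export
setClass("NetworkPartition",
         slots = c(roiIds = "character", network = "character"))

setValidity("NetworkPartition", function(object) {
  msg <- character()
  if (length(object@roiIds) != length(object@network))
    msg <- c(msg, "roiIds and network must have equal length")
  if (anyDuplicated(object@roiIds))
    msg <- c(msg, "roiIds must be unique")
  bad <- setdiff(unique(object@network), networkNames())
  if (length(bad))
    msg <- c(msg, paste0("unknown network label(s): ",
                         paste(bad, collapse = ", ")))
  sizes <- table(factor(object@network, levels = networkNames()))
  if (any(sizes < 2))
    msg <- c(msg, paste0("every network needs >= 2 ROIs; too small: ",
                         paste(names(sizes)[sizes < 2], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

## StateCohort ---------------------------------------------------------------

#' StateCohort: a paired multi-subject, multi-state recording collection
#'
#' Holds one standardized BOLD-like time-series matrix (frames x ROIs) per
#' recording, together with the manifest that pairs every altered-state
#' recording with its own-subject baseline, the [NetworkPartition-class], and
#' the generating parameters when the cohort is synthetic.
#'
#' @slot series named list of numeric matrices (frames x ROIs), names matching
#'   `manifest$id`.
#' @slot manifest data.frame with columns `id`, `subject`, `state`, `class`,
#'   `condition` ("baseline" or "altered").
#' @slot partition a [NetworkPartition-class].
#' @slot params list of generator parameters (may be empty for external data).
#' @seealso [simulateCohort()], [readCohort()]
#' @export
setClass("StateCohort",
         slots = c(series = "list", manifest = "data.frame",
                   partition = "NetworkPartition", params = "list"))

setValidity("StateCohort", function(object) {
  msg <- character()
  man <- object@manifest
  need <- c("id", "subject", "state", "class", "condition")
  if (!all(need %in% names(man)))
    return(paste("manifest must have columns:", paste(need, collapse = ", ")))
  if (!setequal(names(object@series), man$id))
    msg <- c(msg, "series names must match manifest$id")
  alt <- man[man$condition == "altered", ]
  base <- man[man$condition == "baseline", ]
  key <- function(d) paste(d$subject, d$state)
  if (anyDuplicated(key(base)))
    msg <- c(msg, "duplicated baseline recording for a subject-state pair")
  if (!all(key(alt) %in% key(base)))
    msg <- c(msg, "altered recording without a same-subject baseline partner")
  nc <- vapply(object@series, ncol, 0L)
  if (length(nc) && any(nc != length(object@partition@roiIds)))
    msg <- c(msg, "every series must have one column per partition ROI")
  if (length(msg)) msg else TRUE
})

## LevelSummary --------------------------------------------------------------

#' LevelSummary: one metric summarized at the three spatial levels
#'
#' Container for the global level (whole-brain, global within-network, global
#' between-network scalars), the six hierarchy contrasts (U-U, A-A, T-T, U-A,
#' U-T, A-T; limbic ROIs excluded), and the 7 x 7 symmetric network matrix
#' whose diagonal holds within-network values.
#'
#' @slot global named numeric of length 3
#'   (`whole_brain`, `within_network`, `between_network`).
#' @slot hierarchy named numeric of length 6.
#' @slot network symmetric 7 x 7 numeric matrix with network dimnames.
#' @export
setClass("LevelSummary",
         slots = c(global = "numeric", hierarchy = "numeric",
                   network = "matrix"))

setValidity("LevelSummary", function(object) {
  msg <- character()
  if (!identical(names(object@global),
                 c("whole_brain", "within_network", "between_network")))
    msg <- c(msg, "global must be named whole_brain/within_network/between_network")
  if (!identical(names(object@hierarchy),
                 c("U-U", "A-A", "T-T", "U-A", "U-T", "A-T")))
    msg <- c(msg, "hierarchy must be named U-U, A-A, T-T, U-A, U-T, A-T")
  if (!all(dim(object@network) == c(7L, 7L)))
    msg <- c(msg, "network matrix must be 7 x 7")
  if (length(msg)) msg else TRUE
})

## EfficiencyResult ----------------------------------------------------------

#' EfficiencyResult: raw and null-normalized weighted global efficiency
#'
#' @slot eg raw efficiency of the observed graph.
#' @slot egRand numeric vector of null-model efficiencies (one per shuffled
#'   surrogate).
#' @slot egNorm `eg / mean(egRand)`; `NA` when the null mean is zero.
#' @slot nNull number of null realizations.
#' @slot nodeSpec human-readable description of the node set specification.
#' @export
setClass("EfficiencyResult",
         slots = c(eg = "numeric", egRand = "numeric", egNorm = "numeric",
                   nNull = "integer", nodeSpec = "character"))

## ComplexityResult ----------------------------------------------------------

#' ComplexityResult: windowed interaction complexity
#'
#' @slot perWindow normalized singular-spectrum entropy per valid window.
#' @slot cMean arithmetic mean of `perWindow`.
#' @slot nodeSpec description of the (set1, set2) specification.
#' @export
setClass("ComplexityResult",
         slots = c(perWindow = "numeric", cMean = "numeric",
                   nodeSpec = "character"))

## StatePCA ------------------------------------------------------------------

#' StatePCA: uncentered principal decomposition of state effect profiles
#'
#' Result of the singular decomposition of the raw (uncentered) feature x
#' state effect-size matrix, with states as observations. The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @slot scores states x components projection matrix.
#' @slot loadings features x components orthonormal weight matrix.
#' @slot singularValues nonincreasing singular values.
#' @slot varExplained squared singular values over the total sum of squares.
#' @slot featureInfo data.frame describing each feature row (metric, net1,
#'   net2).
#' @export
setClass("StatePCA",
         slots = c(scores = "matrix", loadings = "matrix",
                   singularValues = "numeric", varExplained = "numeric",
                   featureInfo = "data.frame"))
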