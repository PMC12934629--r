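#' @rdname NetworkPartition-class
#' @param x a package object.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname NetworkPartition-class
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' @rdname NetworkPartition-class
#' @export
setGeneric("networkOf", function(x) standardGeneric("networkOf"))

#' @rdname NetworkPartition-class
#' @export
setGeneric("hierarchyOf", function(x) standardGeneric("hierarchyOf"))

#' @rdname NetworkPartition-class
#' @param network one of [networkNames()].
#' @export
setGeneric("networkMembers",
           function(x, network) standardGeneric("networkMembers"))

#' @rdname NetworkPartition-class
#' @param hierarchy one of [hierarchyNames()].
#' @export
setGeneric("hierarchyMembers",
           function(x, hierarchy) standardGeneric("hierarchyMembers"))

#' @rdname StateCohort-class
#' @param x a [StateCohort-class].
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname StateCohort-class
#' @param id recording identifier from `manifest(x)$id`.
#' @export
setGeneric("getSeries", function(x, id) standardGeneric("getSeries"))

#' @rdname LevelSummary-class
#' @param x a [LevelSummary-class].
#' @export
setGeneric("globalLevel", function(x) standardGeneric("globalLevel"))

#' @rdname LevelSummary-class
#' @export
setGeneric("hierarchyLevel", function(x) standardGeneric("hierarchyLevel"))

#' @rdname LevelSummary-class
#' @export
setGeneric("networkLevel", function(x) standardGeneric("networkLevel"))

#' @rdname EfficiencyResult-class
#' @param x an [EfficiencyResult-class].
#' @export
setGeneric("egNorm", function(x) standardGeneric("egNorm"))

#' @rdname ComplexityResult-class
#' @param x a [ComplexityResult-class].
#' @export
setGeneric("cMean", function(x) standardGeneric("cMean"))
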