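#' @include AllClasses.R
NULL

#' Evaluate a scoring function at metric values
#'
#' @param fn a scoring-function object.
#' @param x numeric vector of metric values.
#' @return numeric vector of scores (capped at the function's maximum, possibly
#'   negative below the clinical goal region).
#' @export
setGeneric("evalScore", function(fn, x) standardGeneric("evalScore"))

#' @rdname accessors
#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeCc", function(x) standardGeneric("voxelVolumeCc"))

#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname accessors
#' @export
setGeneric("criterionScores", function(x) standardGeneric("criterionScores"))

#' @rdname accessors
#' @export
setGeneric("totalScore", function(x) standardGeneric("totalScore"))
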