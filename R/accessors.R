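#' Accessors for aptscore classes
#'
#' Small accessor functions so user code never touches slots directly:
#' \code{doseValues()}, \code{gridSpacing()}, \code{gridOrigin()} and
#' \code{voxelVolumeCc()} for [DoseGrid-class]; \code{structureNames()} for
#' [StructureSet-class]; \code{criterionScores()} and \code{totalScore()} for
#' [ScoreCard-class].
#'
#' @param x an aptscore object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("doseValues", "DoseGrid", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "DoseGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "DoseGrid", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("voxelVolumeCc", "DoseGrid", function(x) prod(x@spacing) / 1000)

#' @rdname accessors
#' @export
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' @rdname accessors
#' @export
setMethod("criterionScores", "ScoreCard", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("totalScore", "ScoreCard", function(x) x@total)

#' Extract a StructureMask from a StructureSet
#' @param x a StructureSet.
#' @param i structure name or index.
#' @export
setMethod("[[", "StructureSet", function(x, i) x@masks[[i]])

#' @rdname accessors
#' @param ... unused.
#' @export
setMethod("length", "StructureSet", function(x) length(x@masks))

#' Structure volume in cm^3
#'
#' Voxel-counting volume of a mask on a grid geometry: voxel count times voxel
#' volume (mm^3) divided by 1000.
#'
#' @param mask a [StructureMask-class] (or logical array).
#' @param grid the congruent [DoseGrid-class] supplying the voxel size.
#' @return volume in cm^3.
#' @export
structureVolumeCc <- function(mask, grid) {
  m <- if (is(mask, "StructureMask")) mask@mask else mask
  stopifnot(identical(dim(m), dim(grid@values)))
  sum(m) * voxelVolumeCc(grid)
}

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DoseGrid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  dose range [%.3f, %.3f] Gy-RBE, voxel volume %.4f cc\n",
              min(object@values), max(object@values), voxelVolumeCc(object)))
})

setMethod("show", "StructureMask", function(object) {
  cat(sprintf("StructureMask '%s' (%s): %d voxels\n",
              object@name, object@role, sum(object@mask)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d structures: %s\n", length(object@masks),
              paste(names(object@masks), collapse = ", ")))
})

setMethod("show", "PiecewiseScoringFunction", function(object) {
  cat(sprintf("PiecewiseScoringFunction [%s, %s-is-better], goal at %g, cap %g\n",
              object@metric, object@direction, object@goal, object@cap))
  k <- object@knots
  cat("  knots:", paste(sprintf("(%g, %g)", k[, 1], k[, 2]), collapse = " "), "\n")
})

setMethod("show", "SerialOrganScoringFunction", function(object) {
  cat(sprintf("SerialOrganScoringFunction [%s]: %g if <= %g Gy-RBE else %g\n",
              object@metric, object@fullScore, object@tolerance, object@penalty))
})

setMethod("show", "ScoreCard", function(object) {
  s <- object@scores
  cat("ScoreCard\n")
  for (nm in names(s))
    cat(sprintf("  %-22s %s\n", nm, ifelse(is.na(s[nm]), "-", sprintf("%6.1f", s[nm]))))
  cat(sprintf("  %-22s %6.1f\n", "total", object@total))
})

setMethod("show", "CourseSummary", function(object) {
  cat(sprintf("CourseSummary [%s]: %d fractions, %d adaptation event(s), total score %.1f\n",
              object@policy, length(object@fractions), nrow(object@events),
              totalScore(object@scorecard)))
})
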