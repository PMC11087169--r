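#' @import methods
NULL

.eps <- 1e-9

#' DoseGrid: an axis-aligned 3D dose field
#'
#' A rectilinear voxel grid of absorbed dose in Gy-RBE. Voxels are addressed by
#' their centers; the physical position of voxel (i, j, k) (1-based) is
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @slot values 3D numeric array of voxel doses (Gy-RBE), all finite and >= 0.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot origin numeric(3), physical position (mm) of the first voxel center.
#'
#' @export
setClass("DoseGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all doses must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "all doses must be >= 0")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseGrid
#'
#' @param values 3D numeric array of voxel doses (Gy-RBE).
#' @param spacing voxel edge lengths in mm (length 3, recycled if length 1).
#' @param origin physical position (mm) of the first voxel center.
#' @return A [DoseGrid-class] object.
#' @examples
#' g <- DoseGrid(array(2, dim = c(4, 4, 4)), spacing = 2.5)
#' voxelVolumeCc(g)
#' @export
DoseGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DoseGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' StructureMask: a boolean voxel mask naming a CTV level or OAR
#'
#' @slot name structure label, e.g. "CTV-High" or "Right Parotid".
#' @slot role "target" or "oar".
#' @slot mask 3D logical array, congruent with its DoseGrid.
#'
#' @export
setClass("StructureMask",
  representation(name = "character", role = "character", mask = "array")
)

setValidity("StructureMask", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@role) != 1L || !object@role %in% c("target", "oar"))
    msg <- c(msg, "'role' must be \"target\" or \"oar\"")
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "'mask' must be a 3D logical array")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureMask
#'
#' @param name structure label.
#' @param role "target" or "oar".
#' @param mask 3D logical array.
#' @export
StructureMask <- function(name, role, mask) {
  new("StructureMask", name = name, role = role, mask = mask)
}

#' StructureSet: a named collection of congruent StructureMasks
#'
#' @slot masks list of [StructureMask-class] objects sharing one grid shape.
#' @export
setClass("StructureSet", representation(masks = "list"))

setValidity("StructureSet", function(object) {
  msg <- character()
  ok <- vapply(object@masks, is, logical(1), class2 = "StructureMask")
  if (!all(ok)) {
    msg <- c(msg, "all elements must be StructureMask objects")
  } else if (length(object@masks) > 1L) {
    dims <- vapply(object@masks, function(m) dim(m@mask), integer(3))
    if (any(dims != dims[, 1]))
      msg <- c(msg, "all masks must share the same grid shape")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StructureSet
#' @param ... StructureMask objects (or a single list of them).
#' @export
StructureSet <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) && !is(masks[[1]], "StructureMask"))
    masks <- masks[[1]]
  names(masks) <- vapply(masks, function(m) m@name, character(1))
  new("StructureSet", masks = masks)
}

#' Prescription: per-target dose levels and fractionation
#'
#' @slot levels named numeric, prescription dose (Gy-RBE) per CTV level
#'   (names among "CTV-High", "CTV-Mid", "CTV-Low").
#' @slot nFractions integer fraction count.
#' @export
setClass("Prescription",
  representation(levels = "numeric", nFractions = "integer")
)

setValidity("Prescription", function(object) {
  msg <- character()
  lv <- object@levels
  if (is.null(names(lv)) || any(!nzchar(names(lv))))
    msg <- c(msg, "'levels' must be named by CTV level")
  if (any(!is.finite(lv)) || any(lv <= 0))
    msg <- c(msg, "prescription levels must be strictly positive")
  ord <- c("CTV-High", "CTV-Mid", "CTV-Low")
  present <- ord[ord %in% names(lv)]
  if (length(present) > 1L && is.unsorted(rev(lv[present])))
    msg <- c(msg, "levels must satisfy CTV-High >= CTV-Mid >= CTV-Low")
  if (length(object@nFractions) != 1L || is.na(object@nFractions) ||
      object@nFractions < 1L)
    msg <- c(msg, "'nFractions' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a Prescription
#' @param levels named numeric vector of prescription doses (Gy-RBE).
#' @param nFractions fraction count.
#' @examples
#' Prescription(c("CTV-High" = 70, "CTV-Mid" = 63, "CTV-Low" = 56), 35)
#' @export
Prescription <- function(levels, nFractions) {
  new("Prescription", levels = levels, nFractions = as.integer(nFractions))
}

#' PiecewiseScoringFunction: continuous piecewise-linear metric-to-score map
#'
#' Scores a single dose-volume metric. The function is linear between knots,
#' flat at the cap (7 by default) beyond the "good" end, and continues the
#' terminal segment linearly (allowing arbitrarily negative scores) beyond the
#' "bad" end. The clinical-goal abscissa coincides with a knot.
#'
#' @slot metric metric identity, e.g. "V100", "Dmax", "Dmean".
#' @slot direction "higher" if larger metric values are better (coverage),
#'   "lower" if smaller values are better (dose metrics).
#' @slot knots two-column matrix (metric value, score), ascending in x.
#' @slot goal the clinical-goal abscissa; must equal one knot x.
#' @slot cap maximum attainable score.
#' @export
setClass("PiecewiseScoringFunction",
  representation(metric = "character", direction = "character",
                 knots = "matrix", goal = "numeric", cap = "numeric"),
  prototype(cap = 7)
)

setValidity("PiecewiseScoringFunction", function(object) {
  msg <- character()
  k <- object@knots
  if (!is.numeric(k) || ncol(k) != 2L || nrow(k) < 2L)
    msg <- c(msg, "'knots' must be a numeric matrix with >= 2 rows and 2 columns")
  else {
    if (is.unsorted(k[, 1], strictly = TRUE))
      msg <- c(msg, "knot abscissae must be strictly increasing")
    if (any(k[, 2] > object@cap + .eps))
      msg <- c(msg, "knot scores must not exceed the cap")
    dy <- diff(k[, 2])
    if (object@direction == "higher" && any(dy < -.eps))
      msg <- c(msg, "coverage-type function must be non-decreasing")
    if (object@direction == "lower" && any(dy > .eps))
      msg <- c(msg, "dose-type function must be non-increasing")
    if (!any(abs(k[, 1] - object@goal) < 1e-6))
      msg <- c(msg, "the clinical-goal abscissa must coincide with a knot")
  }
  if (!object@direction %in% c("higher", "lower"))
    msg <- c(msg, "'direction' must be \"higher\" or \"lower\"")
  if (length(msg)) msg else TRUE
})

#' Construct a piecewise-linear scoring function
#'
#' @param metric metric identity ("V100", "Dmax", "Dmean", ...).
#' @param direction "higher" (coverage-type) or "lower" (dose-type).
#' @param knots two-column matrix or data.frame of (metric value, score).
#' @param goal clinical-goal abscissa (must be a knot).
#' @param cap score cap, default 7.
#' @export
scoringFunction <- function(metric, direction, knots, goal, cap = 7) {
  knots <- as.matrix(knots)
  dimnames(knots) <- list(NULL, c("x", "score"))
  new("PiecewiseScoringFunction", metric = metric, direction = direction,
      knots = knots, goal = goal, cap = cap)
}

#' SerialOrganScoringFunction: step scoring for serial-organ near-maximum dose
#'
#' Full score while D0.03cc stays within tolerance, a large negative penalty
#' (clinical unacceptability) above it.
#'
#' @slot metric metric identity (always "D0.03cc").
#' @slot tolerance tolerance dose in Gy-RBE.
#' @slot fullScore score at or below tolerance (7).
#' @slot penalty score above tolerance (-150 by default).
#' @export
setClass("SerialOrganScoringFunction",
  representation(metric = "character", tolerance = "numeric",
                 fullScore = "numeric", penalty = "numeric"),
  prototype(metric = "D0.03cc", fullScore = 7, penalty = -150)
)

setValidity("SerialOrganScoringFunction", function(object) {
  if (!is.finite(object@tolerance) || object@tolerance <= 0)
    return("'tolerance' must be a positive dose (Gy-RBE)")
  TRUE
})

#' Construct a serial-organ scoring function
#' @param tolerance tolerance dose (Gy-RBE).
#' @param fullScore score within tolerance.
#' @param penalty score above tolerance.
#' @export
serialScoringFunction <- function(tolerance, fullScore = 7, penalty = -150) {
  new("SerialOrganScoringFunction", tolerance = tolerance,
      fullScore = fullScore, penalty = penalty)
}

#' ScoreCard: per-criterion plan-quality scores plus total
#'
#' @slot scores named numeric vector of criterion scores; NA marks a criterion
#'   whose structure is absent (dropped from the total).
#' @slot total sum of the present (non-NA) criterion scores.
#' @export
setClass("ScoreCard", representation(scores = "numeric", total = "numeric"))

setValidity("ScoreCard", function(object) {
  msg <- character()
  if (is.null(names(object@scores)))
    msg <- c(msg, "'scores' must be named by criterion")
  tot <- sum(object@scores, na.rm = TRUE)
  if (length(object@total) != 1L || abs(object@total - tot) > 1e-8)
    msg <- c(msg, "'total' must equal the sum of present criterion scores")
  if (length(msg)) msg else TRUE
})

ScoreCard <- function(scores) {
  new("ScoreCard", scores = scores, total = sum(scores, na.rm = TRUE))
}

#' MockPlan: analytic conformal dose surrogate
#'
#' A deterministic stand-in for an optimized treatment plan: each target level
#' receives its prescription inside the (margin-expanded) target with Gaussian
#' lateral falloff outside; the field is the maximum over levels and a floor
#' background dose.
#'
#' @slot targets list of target primitives (as in a phantom's `primitives`).
#' @slot rx [Prescription-class] for the target levels.
#' @slot margin margin (mm) added around each target.
#' @slot penumbra Gaussian falloff width sigma (mm).
#' @slot background background dose floor (Gy-RBE, full course).
#' @export
setClass("MockPlan",
  representation(targets = "list", rx = "Prescription", margin = "numeric",
                 penumbra = "numeric", background = "numeric")
)

setValidity("MockPlan", function(object) {
  msg <- character()
  if (object@margin < 0) msg <- c(msg, "'margin' must be >= 0")
  if (object@penumbra < 0) msg <- c(msg, "'penumbra' must be >= 0")
  if (object@background < 0) msg <- c(msg, "'background' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FractionRecord: one delivered fraction on the reference frame
#'
#' @slot index fraction index (1-based, contiguous).
#' @slot dose per-fraction [DoseGrid-class] mapped to the reference frame
#'   (may be an empty grid when grids are not retained).
#' @slot planId identifier of the in-use plan.
#' @slot evaluation list with the daily evaluation outcome (endpoints, goal
#'   pass/fail table, total score, trigger flag), or empty if not evaluated.
#' @export
setClass("FractionRecord",
  representation(index = "integer", dose = "DoseGrid", planId = "character",
                 evaluation = "list")
)

#' CourseSummary: one policy's accumulated treatment course
#'
#' @slot policy policy label ("nominal", "none", "offline", "online", ...).
#' @slot cumulativeDose accumulated course [DoseGrid-class] on the reference frame.
#' @slot endpoints cumulative endpoint table (one row per structure).
#' @slot scorecard [ScoreCard-class] of the cumulative dose.
#' @slot events data.frame of adaptation events (fraction, action, planId).
#' @slot fractions list of [FractionRecord-class] objects.
#' @export
setClass("CourseSummary",
  representation(policy = "character", cumulativeDose = "DoseGrid",
                 endpoints = "data.frame", scorecard = "ScoreCard",
                 events = "data.frame", fractions = "list")
)
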