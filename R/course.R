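#' @include AllClasses.R dvh-engine.R scoring.R synthetic.R
NULL

.congruent <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    max(abs(a@spacing - b@spacing)) < 1e-9 &&
    max(abs(a@origin - b@origin)) < 1e-9
}

#' Accumulate per-fraction doses on the reference frame
#'
#' Voxel-wise weighted sum of frame-aligned per-fraction dose grids (the
#' deformable mapping to the reference frame is assumed already applied;
#' see [simulateCourse()] for the synthetic surrogate). Linear in its inputs
#' and invariant under fraction reordering.
#'
#' @param fractions list of [DoseGrid-class] or [FractionRecord-class] objects.
#' @param weights per-fraction weights, default 1 (uniform fractionation).
#' @return the cumulative [DoseGrid-class].
#' @export
accumulateDose <- function(fractions, weights = rep(1, length(fractions))) {
  stopifnot(length(fractions) >= 1L, length(weights) == length(fractions))
  grids <- lapply(fractions, function(f)
    if (is(f, "FractionRecord")) f@dose else f)
  ref <- grids[[1]]
  vals <- array(0, dim = dim(ref@values))
  for (i in seq_along(grids)) {
    if (!.congruent(grids[[i]], ref))
      stop("fraction ", i, " is not congruent with the reference frame")
    vals <- vals + weights[i] * grids[[i]]@values
  }
  DoseGrid(vals, spacing = ref@spacing, origin = ref@origin)
}

#' Resample a dose grid onto a target frame with a rigid shift
#'
#' Trilinear interpolation of the source dose at the target voxel centers
#' offset by `shift` (mm); voxels outside the source support are zero.
#'
#' @param dose source [DoseGrid-class].
#' @param frame target geometry (a [DoseGrid-class]).
#' @param shift rigid offset in mm (sampling position = target center + shift).
#' @return a [DoseGrid-class] on the target frame.
#' @export
resampleToFrame <- function(dose, frame, shift = c(0, 0, 0)) {
  if (any(dose@spacing <= 0) || any(frame@spacing <= 0))
    stop("degenerate grid spacing")
  pts <- .gridPoints(frame)
  d <- dim(dose@values)
  # continuous 0-based voxel indices in the source grid
  ix <- (pts[, 1] + shift[1] - dose@origin[1]) / dose@spacing[1]
  iy <- (pts[, 2] + shift[2] - dose@origin[2]) / dose@spacing[2]
  iz <- (pts[, 3] + shift[3] - dose@origin[3]) / dose@spacing[3]
  i0 <- floor(ix); j0 <- floor(iy); k0 <- floor(iz)
  fx <- ix - i0; fy <- iy - j0; fz <- iz - k0
  inside <- i0 >= -1 & i0 <= d[1] - 1 & j0 >= -1 & j0 <= d[2] - 1 &
    k0 >= -1 & k0 <= d[3] - 1
  val <- numeric(nrow(pts))
  corner <- function(di, dj, dk) {
    i <- i0 + di; j <- j0 + dj; k <- k0 + dk
    ok <- inside & i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    v <- numeric(length(i))
    idx <- 1 + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
    v[ok] <- dose@values[idx]
    w <- (if (di == 1) fx else 1 - fx) * (if (dj == 1) fy else 1 - fy) *
      (if (dk == 1) fz else 1 - fz)
    v * w
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    val <- val + corner(di, dj, dk)
  DoseGrid(array(pmax(val, 0), dim = dim(frame@values)),
           spacing = frame@spacing, origin = frame@origin)
}

# Reference-frame delivered dose of one fraction under the synthetic course
# surrogate: each reference voxel is mapped to its fraction-day position by
# the owning structure's affine (centroid + isotropic scale) transform
# (background voxels move rigidly), shifted by the day's setup error, and the
# plan's analytic field is evaluated there. Returns the full-course-equivalent
# field; divide by nFractions for the per-fraction dose.
.mappedCourseDose <- function(plan, stream, t, shift = NULL) {
  pts <- stream$points
  own <- stream$owner
  mapped <- pts
  prims0 <- stream$phantom$primitives
  primsT <- if (t == 0) prims0 else stream$anatomy[[t]]
  for (i in seq_along(own$order)) {
    nm <- own$order[i]
    sel <- own$index == i
    if (!any(sel)) next
    s0 <- prims0[[nm]]; st <- primsT[[nm]]
    scale <- st$radii / s0$radii
    for (a in 1:3)
      mapped[sel, a] <- st$center[a] + (pts[sel, a] - s0$center[a]) * scale[a]
  }
  if (is.null(shift)) shift <- if (t == 0) c(0, 0, 0) else stream$shifts[[t]]
  for (a in 1:3) mapped[, a] <- mapped[, a] + shift[a]
  frame <- stream$phantom$frame
  DoseGrid(array(.planField(plan, mapped), dim = dim(frame@values)),
           spacing = frame@spacing, origin = frame@origin)
}

#' Daily plan-quality evaluation and replan trigger
#'
#' Computes the endpoints of a fraction's (course-equivalent) dose, checks the
#' clinical goals, scores the plan, and sets the trigger flag: adaptation is
#' triggered when any goal fails or when the total score drops more than
#' `dropThreshold` below the nominal plan's total.
#'
#' @param record a [FractionRecord-class] whose dose is the per-fraction dose
#'   on the reference frame.
#' @param structures reference [StructureSet-class].
#' @param rx [Prescription-class]; the fraction dose is scaled by the fraction
#'   count to evaluate against the course-level goals.
#' @param goals,fns as in [scoreEndpoints()].
#' @param nominalTotal total score of the nominal plan on the planning
#'   anatomy.
#' @param dropThreshold score drop quantifying "substantially worse than the
#'   nominal plan" (default 3).
#' @return the record with its evaluation slot filled (endpoints, goal table,
#'   total, trigger).
#' @export
evaluateFraction <- function(record, structures, rx,
                             goals = defaultClinicalGoals(),
                             fns = defaultScoringFunctions(), nominalTotal,
                             dropThreshold = 3) {
  course <- DoseGrid(record@dose@values * rx@nFractions,
                     spacing = record@dose@spacing, origin = record@dose@origin)
  ep <- extractEndpoints(course, structures, rx)
  gl <- checkGoals(ep, goals)
  card <- scoreEndpoints(ep, goals, fns)
  trig <- any(!gl$pass, na.rm = TRUE) ||
    totalScore(card) < nominalTotal - dropThreshold
  record@evaluation <- list(endpoints = ep, goals = gl,
                            total = totalScore(card), trigger = trig)
  record
}

#' Adaptation policies
#'
#' `policyNone()` never evaluates or adapts (the nominal plan is delivered
#' throughout). `policyOffline()` evaluates only at QACT fractions (every
#' `qactInterval` fractions, bi-weekly at 5 fractions/week by default) and,
#' when triggered, swaps to a plan designed on the QACT-day anatomy after
#' `replanLag` fractions (about a week by default). `policyOnline()` evaluates
#' every fraction before delivery and, when triggered, replans on the daily
#' anatomy for the same fraction with a reduced margin.
#'
#' @param qactInterval fractions between offline evaluations.
#' @param replanLag fractions between an offline trigger and the plan swap
#'   (0 = the new plan applies to the same fraction).
#' @param margin CTV margin (mm) used by that policy's replans.
#' @return a policy description list.
#' @export
policyNone <- function() list(type = "none")

#' @rdname policyNone
#' @export
policyOffline <- function(qactInterval = 10, replanLag = 5, margin = 3)
  list(type = "offline", qactInterval = qactInterval, replanLag = replanLag,
       margin = margin)

#' @rdname policyNone
#' @export
policyOnline <- function(margin = 1.5)
  list(type = "online", qactInterval = 1, replanLag = 0, margin = margin)

#' Run one adaptation policy over a course stream
#'
#' Replays the stream's per-fraction anatomy and setup errors, evaluating and
#' adapting the in-use plan according to the policy, accumulating the mapped
#' per-fraction dose on the reference frame, and scoring the cumulative dose.
#'
#' @param stream a [courseStream()].
#' @param policy a policy from [policyNone()], [policyOffline()],
#'   [policyOnline()].
#' @param goals,fns as in [scoreEndpoints()].
#' @param dropThreshold see [evaluateFraction()].
#' @param nominalMargin margin (mm) of the initial (nominal) plan.
#' @param penumbra,background mock-plan field parameters.
#' @param keepGrids retain every per-fraction grid in the records (memory).
#' @return a [CourseSummary-class].
#' @export
runPolicy <- function(stream, policy, goals = defaultClinicalGoals(),
                      fns = defaultScoringFunctions(), dropThreshold = 3,
                      nominalMargin = 3, penumbra = 5, background = 2,
                      keepGrids = FALSE) {
  if (!is.list(policy) || !policy$type %in% c("none", "offline", "online"))
    stop("unknown policy: ", if (is.list(policy)) policy$type else policy)
  rx <- stream$phantom$rx
  n <- stream$nFractions
  frame <- stream$phantom$frame
  structures <- stream$phantom$structures
  nominalPlan <- mockPlan(stream$phantom$primitives, rx, margin = nominalMargin,
                          penumbra = penumbra, background = background)
  planned <- .mappedCourseDose(nominalPlan, stream, 0)
  nominalTotal <- totalScore(scoreEndpoints(
    extractEndpoints(planned, structures, rx), goals, fns))
  emptyGrid <- DoseGrid(array(0, dim = c(1, 1, 1)))
  inUse <- nominalPlan; inUseId <- "nominal"
  # fraction at which the in-use plan was designed; a plan delivered the same
  # fraction it was designed on (online adaptation) was built on the
  # CBCT-captured in-position anatomy, so no setup misalignment applies
  inUseDesignedAt <- 0L
  pending <- NULL; pendingAt <- Inf; pendingId <- ""; pendingDesignedAt <- 0L
  cum <- array(0, dim = dim(frame@values))
  records <- vector("list", n)
  events <- list()
  evalAt <- switch(policy$type,
    none = integer(),
    offline = seq_len(n)[seq_len(n) %% policy$qactInterval == 0],
    online = seq_len(n))
  for (t in seq_len(n)) {
    if (!is.null(pending) && t >= pendingAt) {
      inUse <- pending; inUseId <- pendingId
      inUseDesignedAt <- pendingDesignedAt
      events[[length(events) + 1L]] <- data.frame(
        fraction = t, action = "plan swap", planId = pendingId)
      pending <- NULL; pendingAt <- Inf
    }
    evaluation <- list()
    if (t %in% evalAt) {
      courseEq <- .mappedCourseDose(inUse, stream, t)
      rec <- new("FractionRecord", index = t,
                 dose = DoseGrid(courseEq@values / n, spacing = courseEq@spacing,
                                 origin = courseEq@origin),
                 planId = inUseId, evaluation = list())
      rec <- evaluateFraction(rec, structures, rx, goals, fns, nominalTotal,
                              dropThreshold)
      evaluation <- rec@evaluation
      if (evaluation$trigger) {
        newId <- sprintf("%s-fx%02d", policy$type, t)
        newPlan <- mockPlan(stream$anatomy[[t]], rx, margin = policy$margin,
                            penumbra = penumbra, background = background)
        events[[length(events) + 1L]] <- data.frame(
          fraction = t, action = "replan", planId = newId)
        if (policy$replanLag == 0) {
          inUse <- newPlan; inUseId <- newId; inUseDesignedAt <- t
          events[[length(events) + 1L]] <- data.frame(
            fraction = t, action = "plan swap", planId = newId)
        } else {
          pending <- newPlan; pendingAt <- t + policy$replanLag
          pendingId <- newId; pendingDesignedAt <- t
        }
      }
    }
    delivered <- .mappedCourseDose(inUse, stream, t,
                                   shift = if (inUseDesignedAt == t)
                                     c(0, 0, 0) else NULL)
    gt <- delivered@values / n
    cum <- cum + gt
    records[[t]] <- new("FractionRecord", index = t,
                        dose = if (keepGrids)
                          DoseGrid(gt, spacing = frame@spacing,
                                   origin = frame@origin) else emptyGrid,
                        planId = inUseId, evaluation = evaluation)
  }
  cumGrid <- DoseGrid(cum, spacing = frame@spacing, origin = frame@origin)
  ep <- extractEndpoints(cumGrid, structures, rx)
  card <- scoreEndpoints(ep, goals, fns)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(fraction = integer(), action = character(), planId = character())
  new("CourseSummary", policy = policy$type, cumulativeDose = cumGrid,
      endpoints = ep, scorecard = card, events = ev, fractions = records)
}

#' Simulate an adaptive treatment course under several policies
#'
#' Generates one seeded anatomy/setup-error stream and replays it under each
#' policy (common random numbers), so score differences between the returned
#' course summaries are attributable to the adaptation policy alone.
#'
#' @param spec a [phantomSpec()].
#' @param model a [driftModel()].
#' @param policies named list of policies.
#' @param nFractions course length (default: the prescription's).
#' @param seed integer seed (mandatory).
#' @param ... passed to [runPolicy()].
#' @return named list of [CourseSummary-class], one per policy, with the
#'   stream attached as attribute "stream".
#' @export
simulateCourse <- function(spec = defaultPhantomSpec(),
                           model = defaultDriftModel(spec$rx@nFractions),
                           policies = list(none = policyNone(),
                                           offline = policyOffline(),
                                           online = policyOnline()),
                           nFractions = spec$rx@nFractions, seed, ...) {
  stream <- courseStream(spec, model, nFractions, seed)
  out <- lapply(policies, function(p) runPolicy(stream, p, ...))
  attr(out, "stream") <- stream
  out
}

#' Compare treatment courses (the score-comparison report)
#'
#' Builds per-patient course totals, pairwise score deltas (offline - nominal,
#' online - nominal, online - offline) and cohort averages from a scorecard
#' table.
#'
#' @param scores scorecard table with columns patient, course, total (as from
#'   [scoreEndpointTable()]), or a named list of [CourseSummary-class]
#'   objects for a single patient.
#' @param courses course labels to include, in order.
#' @return list with `totals` (patient x course data.frame), `deltas`
#'   (patient x pair), and `averages` (named vector over totals and deltas).
#' @export
compareCourses <- function(scores, courses = c("nominal", "offline", "online")) {
  if (!is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(names(scores), function(nm)
      data.frame(patient = 1L, course = nm,
                 total = totalScore(scores[[nm]]@scorecard))))
    courses <- intersect(c(courses, unique(scores$course)), scores$course)
  }
  patients <- sort(unique(scores$patient))
  totals <- data.frame(patient = patients)
  for (crs in courses) {
    totals[[crs]] <- vapply(patients, function(p) {
      v <- scores$total[scores$patient == p & scores$course == crs]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  }
  deltas <- data.frame(patient = patients)
  pairs <- list(c("offline", "nominal"), c("online", "nominal"),
                c("online", "offline"))
  for (pr in pairs) {
    if (!all(pr %in% courses)) next
    deltas[[paste(pr[1], pr[2], sep = "-")]] <- totals[[pr[1]]] - totals[[pr[2]]]
  }
  avg <- c(vapply(courses, function(c) mean(totals[[c]], na.rm = TRUE),
                  numeric(1)),
           vapply(setdiff(names(deltas), "patient"),
                  function(c) mean(deltas[[c]], na.rm = TRUE), numeric(1)))
  list(totals = totals, deltas = deltas, averages = avg)
}
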