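#' @include AllClasses.R dvh-engine.R
NULL

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Head-and-neck phantom specification
#'
#' An analytic phantom of ellipsoid primitives standing in for a planning CT
#' with contours: three nested CTV levels, two parotids, oral cavity,
#' brainstem and spinal cord on a 4 mm reference grid. Default target volumes
#' (about 33 / 85 / 250 cc for CTV-High/Mid/Low) and prescriptions
#' (70 / 63 / 56 Gy-RBE in 35 fractions) sit inside the ranges of the
#' published ten-patient cohort.
#'
#' @param shape voxel counts per axis.
#' @param spacing voxel size (mm).
#' @param origin position of the first voxel center (mm).
#' @param structures named list of primitives: each a list with name, role,
#'   center (mm), radii (mm).
#' @param rx a [Prescription-class].
#' @return a list of class "aptscore_phantom_spec".
#' @export
phantomSpec <- function(shape = c(44, 44, 36), spacing = c(4, 4, 4),
                        origin = c(2, 2, 2), structures = .defaultPrimitives(),
                        rx = Prescription(c("CTV-High" = 70, "CTV-Mid" = 63,
                                            "CTV-Low" = 56), 35)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  stopifnot(length(shape) == 3L, all(shape >= 2), all(spacing > 0))
  ext <- origin + (shape - 1) * spacing
  for (s in structures) {
    if (any(s$center - s$radii < origin - spacing) ||
        any(s$center + s$radii > ext + spacing))
      stop("structure '", s$name, "' does not fit inside the grid")
  }
  out <- list(shape = shape, spacing = spacing, origin = origin,
              structures = structures, rx = rx)
  class(out) <- "aptscore_phantom_spec"
  out
}

.defaultPrimitives <- function() {
  prim <- function(name, role, center, radii)
    list(name = name, role = role, center = center, radii = radii)
  list(
    `CTV-High` = prim("CTV-High", "target", c(88, 96, 76), c(22, 18, 20)),
    `CTV-Mid` = prim("CTV-Mid", "target", c(88, 96, 74), c(30, 25, 27)),
    `CTV-Low` = prim("CTV-Low", "target", c(88, 94, 70), c(44, 34, 40)),
    `Right Parotid` = prim("Right Parotid", "oar", c(32, 100, 80), c(13, 15, 17)),
    `Left Parotid` = prim("Left Parotid", "oar", c(144, 100, 80), c(13, 15, 17)),
    `Oral Cavity` = prim("Oral Cavity", "oar", c(88, 48, 70), c(24, 20, 18)),
    Brainstem = prim("Brainstem", "oar", c(88, 108, 124), c(9, 9, 20)),
    `Spinal Cord` = prim("Spinal Cord", "oar", c(88, 142, 60), c(5, 5, 40))
  )
}

#' @rdname phantomSpec
#' @export
defaultPhantomSpec <- function() phantomSpec()

.axisCoords <- function(spec) {
  lapply(1:3, function(a)
    spec$origin[a] + (seq_len(spec$shape[a]) - 1) * spec$spacing[a])
}

.rasterizeEllipsoid <- function(spec, center, radii) {
  co <- .axisCoords(spec)
  dx2 <- ((co[[1]] - center[1]) / radii[1])^2
  dy2 <- ((co[[2]] - center[2]) / radii[2])^2
  dz2 <- ((co[[3]] - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Rasterize a phantom specification
#'
#' Rasterizes every primitive onto the reference grid. Rasterized volumes
#' agree with the analytic ellipsoid volumes to within voxelization error.
#' Nested target levels may overlap; a warning is raised if an OAR overlaps a
#' target by more than `overlapWarn` of its volume.
#'
#' @param spec a [phantomSpec()].
#' @param seed accepted for interface symmetry; rasterization is
#'   deterministic, so the same spec always yields identical masks.
#' @param overlapWarn tolerated OAR/target overlap fraction before warning.
#' @return list with `frame` (zero [DoseGrid-class] defining the geometry),
#'   `structures` (a [StructureSet-class]), `primitives` and `rx`.
#' @export
makePhantom <- function(spec = defaultPhantomSpec(), seed = NULL,
                        overlapWarn = 0.5) {
  frame <- DoseGrid(array(0, dim = spec$shape), spacing = spec$spacing,
                    origin = spec$origin)
  masks <- lapply(spec$structures, function(s)
    StructureMask(s$name, s$role, .rasterizeEllipsoid(spec, s$center, s$radii)))
  sset <- StructureSet(masks)
  tgt <- Reduce(`|`, lapply(masks[vapply(masks, function(m) m@role, "") == "target"],
                            function(m) m@mask))
  for (m in masks) {
    if (m@role == "oar" && sum(m@mask & tgt) > overlapWarn * sum(m@mask))
      warning("OAR '", m@name, "' overlaps the target volumes by more than ",
              round(100 * overlapWarn), "% of its volume")
  }
  list(frame = frame, structures = sset, primitives = spec$structures,
       rx = spec$rx)
}

#' Anatomy drift model
#'
#' Gradual per-structure volumetric change and centroid drift plus random
#' per-fraction setup error, emulating resolving edema, tumor shrinkage and
#' daily setup variation over a 30-36 fraction course.
#'
#' @param volumeRate named numeric: per-fraction multiplicative volume change
#'   per structure (1 = static). Unnamed structures are static.
#' @param drift named list of 3-vectors: centroid velocity (mm/fraction).
#' @param setupSigma isotropic Gaussian setup-error sigma (mm).
#' @param setupCap truncation of setup error magnitude (mm).
#' @param nFractions course length used to bound cumulative shrinkage.
#' @return list of class "aptscore_drift_model".
#' @export
driftModel <- function(volumeRate = numeric(), drift = list(),
                       setupSigma = 1.5, setupCap = 5, nFractions = 35) {
  if (length(volumeRate)) {
    total <- volumeRate^nFractions
    if (any(total < 0.7 - 1e-9))
      stop("cumulative volume shrinkage exceeds 30% over the course")
  }
  out <- list(volumeRate = volumeRate, drift = drift, setupSigma = setupSigma,
              setupCap = setupCap, nFractions = nFractions)
  class(out) <- "aptscore_drift_model"
  out
}

#' @rdname driftModel
#' @details `defaultDriftModel()` shrinks the targets by about 15% over 35
#'   fractions (the magnitude seen in the published cohort), drifts targets
#'   and parotids by 0.35 mm/fraction, and draws setup errors from a 1.5 mm
#'   isotropic Gaussian truncated at 5 mm.
#' @export
defaultDriftModel <- function(nFractions = 35) {
  shrink <- 0.85^(1 / nFractions)
  v <- c(0.3, -0.15, 0.1); v <- 0.35 * v / sqrt(sum(v^2))
  driftModel(
    volumeRate = c("CTV-High" = shrink, "CTV-Mid" = shrink,
                   "CTV-Low" = shrink, "Right Parotid" = 0.90^(1 / nFractions),
                   "Left Parotid" = 0.90^(1 / nFractions)),
    drift = list(`CTV-High` = v, `CTV-Mid` = v, `CTV-Low` = v,
                 `Right Parotid` = c(0.15, 0, 0), `Left Parotid` = c(-0.15, 0, 0)),
    setupSigma = 1.5, setupCap = 5, nFractions = nFractions
  )
}

#' @rdname driftModel
#' @param seed integer seed.
#' @details `randomDriftModel()` draws a scenario: a random drift direction
#'   with magnitude 0.2-0.5 mm/fraction and total target shrinkage of 5-20%,
#'   for exercising the adaptation policies over varied seeded scenarios.
#' @export
randomDriftModel <- function(seed, nFractions = 35) {
  .withSeed(seed, {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    speed <- stats::runif(1, 0.2, 0.5)
    shrinkTotal <- stats::runif(1, 0.80, 0.95)
    v <- speed * dir
    driftModel(
      volumeRate = c("CTV-High" = shrinkTotal^(1 / nFractions),
                     "CTV-Mid" = shrinkTotal^(1 / nFractions),
                     "CTV-Low" = shrinkTotal^(1 / nFractions)),
      drift = list(`CTV-High` = v, `CTV-Mid` = v, `CTV-Low` = v),
      setupSigma = 1.5, setupCap = 5, nFractions = nFractions
    )
  })
}

#' Apply anatomy drift to primitives
#'
#' Scales and translates each primitive to its state at a given fraction:
#' centers move by `drift * fraction`, radii scale isotropically by the cube
#' root of the cumulative volume ratio, and the result is re-rasterized on
#' demand. Volume trajectories therefore follow the analytic drift curve
#' within voxelization error.
#'
#' @param primitives named list of primitives (see [phantomSpec()]).
#' @param fractionIndex fraction number (0 = planning anatomy).
#' @param model a [driftModel()].
#' @return drifted primitives list.
#' @export
driftAnatomy <- function(primitives, fractionIndex, model) {
  lapply(primitives, function(s) {
    rate <- model$volumeRate[s$name]
    if (!is.na(rate) && length(rate))
      s$radii <- s$radii * (rate^fractionIndex)^(1 / 3)
    v <- model$drift[[s$name]]
    if (!is.null(v)) s$center <- s$center + v * fractionIndex
    s
  })
}

#' Construct a mock conformal plan
#'
#' @param primitives anatomy primitives the plan is designed on (targets are
#'   selected by role).
#' @param rx a [Prescription-class].
#' @param margin CTV margin in mm (e.g. 3 for nominal/offline planning,
#'   1.5 for online adaptation).
#' @param penumbra Gaussian falloff sigma (mm).
#' @param background background dose floor (Gy-RBE over the full course).
#' @return a [MockPlan-class].
#' @export
mockPlan <- function(primitives, rx, margin = 3, penumbra = 5, background = 2) {
  targets <- Filter(function(s) s$role == "target", primitives)
  if (!length(targets)) stop("no target primitives to plan on")
  new("MockPlan", targets = targets, rx = rx, margin = margin,
      penumbra = penumbra, background = background)
}

# evaluate the plan's full-course dose field at arbitrary points (n x 3)
.planField <- function(plan, pts) {
  dose <- rep(plan@background, nrow(pts))
  for (s in plan@targets) {
    level <- plan@rx@levels[[s$name]]
    r <- s$radii + plan@margin
    rho <- sqrt(((pts[, 1] - s$center[1]) / r[1])^2 +
                ((pts[, 2] - s$center[2]) / r[2])^2 +
                ((pts[, 3] - s$center[3]) / r[3])^2)
    f <- numeric(length(rho))
    inside <- rho <= 1
    f[inside] <- 1
    if (plan@penumbra > 0) {
      d <- (rho[!inside] - 1) * min(r)
      f[!inside] <- exp(-d^2 / (2 * plan@penumbra^2))
    }
    dose <- pmax(dose, level * f)
  }
  dose
}

#' Analytic conformal dose of a mock plan on a grid
#'
#' The full-course dose field: each target level receives its prescription
#' inside the margin-expanded target with Gaussian falloff outside
#' (approximate surface distance in mm); the field is the maximum over levels
#' and the background floor. Deterministic.
#'
#' @param plan a [MockPlan-class].
#' @param frame a [DoseGrid-class] defining the output geometry.
#' @param shift rigid offset (mm) of the field relative to the frame (setup
#'   error), default none.
#' @return a [DoseGrid-class] with the full-course dose.
#' @export
mockPlanDose <- function(plan, frame, shift = c(0, 0, 0)) {
  pts <- .gridPoints(frame)
  pts <- cbind(pts[, 1] + shift[1], pts[, 2] + shift[2], pts[, 3] + shift[3])
  DoseGrid(array(.planField(plan, pts), dim = dim(frame@values)),
           spacing = frame@spacing, origin = frame@origin)
}

.gridPoints <- function(frame) {
  d <- dim(frame@values)
  co <- lapply(1:3, function(a)
    frame@origin[a] + (seq_len(d[a]) - 1) * frame@spacing[a])
  cbind(rep(co[[1]], times = d[2] * d[3]),
        rep(rep(co[[2]], each = d[1]), times = d[3]),
        rep(co[[3]], each = d[1] * d[2]))
}

.truncNorm3 <- function(sigma, cap) {
  repeat {
    v <- stats::rnorm(3, sd = sigma)
    if (sqrt(sum(v^2)) <= cap) return(v)
  }
}

#' Generate the per-fraction anatomy and setup-error stream for a course
#'
#' The stream is the common-random-numbers backbone of a policy comparison:
#' all policies replay the identical per-fraction anatomy and setup errors so
#' score differences are attributable to the policy alone.
#'
#' @param spec a [phantomSpec()].
#' @param model a [driftModel()].
#' @param nFractions number of fractions (default: the prescription's).
#' @param seed integer seed (mandatory) for the setup-error draws.
#' @return list with the phantom (reference anatomy/masks), per-fraction
#'   primitives, setup shifts, and cached voxel bookkeeping.
#' @export
courseStream <- function(spec = defaultPhantomSpec(),
                         model = defaultDriftModel(spec$rx@nFractions),
                         nFractions = spec$rx@nFractions, seed) {
  if (missing(seed)) stop("'seed' is required")
  phantom <- makePhantom(spec)
  # a shortened course keeps the full prescribed dose; the fraction count must
  # agree so per-fraction doses scale consistently in daily evaluation
  phantom$rx@nFractions <- as.integer(nFractions)
  shifts <- .withSeed(seed, lapply(seq_len(nFractions), function(t)
    .truncNorm3(model$setupSigma, model$setupCap)))
  anat <- lapply(seq_len(nFractions), function(t)
    driftAnatomy(phantom$primitives, t, model))
  list(spec = spec, model = model, nFractions = nFractions, seed = seed,
       phantom = phantom, anatomy = anat, shifts = shifts,
       points = .gridPoints(phantom$frame),
       owner = .ownershipMap(phantom$structures))
}

# voxel -> owning structure (targets take precedence, nested CTVs inner-first)
.ownershipMap <- function(structures) {
  nm <- structureNames(structures)
  prio <- c(intersect(c("CTV-High", "CTV-Mid", "CTV-Low"), nm),
            setdiff(nm, c("CTV-High", "CTV-Mid", "CTV-Low")))
  owner <- array(0L, dim = dim(structures[[1]]@mask))
  # write low-priority structures first so higher-priority ones overwrite
  for (i in rev(seq_along(prio))) owner[structures[[prio[i]]]@mask] <- i
  list(index = owner, order = prio)
}
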