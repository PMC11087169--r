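#' @include AllClasses.R scoring.R io.R
NULL

.fnDirection <- c(coverage = "higher", hotspot = "lower", parotid = "lower",
                  oral_cavity = "lower")
.fnGoal <- c(coverage = 98, hotspot = 107, parotid = 26, oral_cavity = 35)
.fnMetric <- c(coverage = "V100", hotspot = "Dmax", parotid = "Dmean",
               oral_cavity = "Dmean")

# cells where the printed table value conflicts with the value quoted in the
# running text; they are kept in the pair table but excluded from the fit
.inconsistentCells <- data.frame(
  patient = c(3, 3, 3, 3),
  course = c("offline", "offline", "online", "online"),
  structure = c("Right Parotid", "Oral Cavity", "Right Parotid", "Spinal Cord"),
  reason = c("table prints 29.7, text prints 29.5",
             "table prints 41.6, text prints 41.9",
             "table prints 22.0, text prints 22.2",
             "table prints 38.0, text prints 38.1"),
  stringsAsFactors = FALSE
)

#' Endpoint/score calibration pairs from the packaged tables
#'
#' Joins the packaged endpoint tables with the corresponding printed criterion
#' scores, one row per (patient, course, criterion) cell, tagged with the
#' scoring-function group it belongs to. Cells whose printed endpoint
#' conflicts with the value quoted in the source's running text are flagged
#' `excluded` (with the reason) so the fit can leave them out; serial-organ
#' cells are tagged `serial` and never fitted (the step function has no free
#' slopes).
#'
#' @param endpoints long endpoint table (default: the packaged ten-patient
#'   table plus the fine-tuned course of patient 5).
#' @param scores matching wide score table.
#' @return data.frame with columns fn, metric, x, y, patient, course,
#'   structure, serial, excluded, reason.
#' @export
calibrationPairs <- function(endpoints = NULL, scores = NULL) {
  if (is.null(endpoints)) {
    endpoints <- rbind(endpointTable3(),
                       subset(endpointTable6(), course == "online-f"))
    scores <- rbind(scoreTable4(), subset(scoreTable7(), course == "online-f"))
  }
  rows <- list()
  for (i in seq_len(nrow(scores))) {
    pat <- scores$patient[i]; crs <- scores$course[i]
    sub <- endpoints[endpoints$patient == pat & endpoints$course == crs, ]
    for (j in seq_len(nrow(.criteria))) {
      cr <- .criteria[j, ]
      x <- .lookupValue(sub, cr$structure, cr$metric)
      y <- scores[[cr$key]][i]
      if (is.na(x) || is.na(y)) next
      excl <- .inconsistentCells$patient == pat &
        .inconsistentCells$course == crs &
        .inconsistentCells$structure == cr$structure
      rows[[length(rows) + 1L]] <- data.frame(
        fn = cr$fn, metric = cr$metric, x = x, y = y, patient = pat,
        course = crs, structure = cr$structure,
        serial = cr$fn %in% c("brainstem", "spinal_cord"),
        excluded = any(excl),
        reason = if (any(excl)) .inconsistentCells$reason[excl][1] else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Calibrate piecewise-linear scoring functions from endpoint/score pairs
#'
#' Recovers each scoring function from printed (metric value, score) pairs by
#' least squares on a hinge basis with the knot pinned at the clinical-goal
#' abscissa: score = a + s_good * (distance inside goal) - s_bad * (distance
#' beyond goal), capped at `cap`. Pairs at the cap (score >= cap - satTol) are
#' excluded from the fit (they only constrain where the cap begins); the cap
#' onset is placed where the fitted good-side segment reaches the cap. One
#' shared coverage function is fitted for all CTV levels.
#'
#' @param pairs pair table as from [calibrationPairs()]; rows with
#'   `excluded = TRUE` or `serial = TRUE` are not fitted.
#' @param goals goals table supplying the serial-organ tolerances.
#' @param cap score cap (7).
#' @param satTol scores within `satTol` of the cap are treated as saturated.
#' @return list with elements `functions` (named list: coverage, hotspot,
#'   parotid, oral_cavity, brainstem, spinal_cord) and `residuals` (the pair
#'   table with fitted and residual columns for every pair, including
#'   saturated and excluded ones).
#' @export
calibrateScoringFunctions <- function(pairs = calibrationPairs(),
                                      goals = defaultClinicalGoals(),
                                      cap = 7, satTol = 0.05) {
  fns <- list()
  groups <- intersect(names(.fnDirection), unique(pairs$fn[!pairs$serial]))
  for (group in groups) {
    sub <- pairs[pairs$fn == group & !pairs$excluded & !pairs$serial, ]
    if (nrow(sub) < 3L)
      stop("under-determined scoring function '", group,
           "': fewer than 3 calibration pairs")
    dirn <- .fnDirection[[group]]
    cr <- .criteria[.criteria$fn == group, ][1, ]
    g <- goals$bound[goals$structure == cr$structure & goals$metric == cr$metric]
    if (length(g) != 1L) g <- .fnGoal[[group]]
    fit <- sub[sub$y < cap - satTol, ]
    sgn <- if (dirn == "higher") 1 else -1
    hGood <- pmax(sgn * (fit$x - g), 0)   # distance on the compliant side
    hBad <- pmax(sgn * (g - fit$x), 0)    # distance beyond the goal
    for (side in c("good", "bad")) {
      h <- if (side == "good") hGood else hBad
      if (sum(h > 0) < 1L)
        stop("under-determined scoring function '", group, "': no ",
             "non-saturated pairs on the ", side, " side of the goal at ", g)
    }
    co <- stats::coef(stats::lm(fit$y ~ hGood + hBad))
    a <- co[[1]]; sGood <- co[[2]]; sBad <- -co[[3]]
    if (!is.finite(sGood) || !is.finite(sBad) || sGood <= 0 || sBad <= 0)
      stop("calibration for '", group, "' produced a non-monotone fit")
    xCap <- g + sgn * (cap - a) / sGood
    # V100 lives on [0, 100]: full coverage must reach the cap
    if (group == "coverage") xCap <- min(xCap, 100)
    xFar <- if (dirn == "higher") min(sub$x) else max(sub$x)
    if (sgn * (g - xFar) <= 0) xFar <- g - sgn  # ensure a knot beyond the goal
    yFar <- a - sBad * abs(xFar - g)
    kn <- rbind(c(xFar, yFar), c(g, a), c(xCap, cap))
    kn <- kn[order(kn[, 1]), ]
    fns[[group]] <- scoringFunction(.fnMetric[[group]], dirn, kn, goal = g,
                                    cap = cap)
  }
  for (organ in c("Brainstem", "Spinal Cord")) {
    tol <- goals$bound[goals$structure == organ & goals$metric == "D0.03cc"]
    nm <- if (organ == "Brainstem") "brainstem" else "spinal_cord"
    fns[[nm]] <- serialScoringFunction(tol)
  }
  res <- pairs
  res$fitted <- vapply(seq_len(nrow(res)), function(i)
    evalScore(fns[[res$fn[i]]], res$x[i]), numeric(1))
  res$residual <- res$fitted - res$y
  list(functions = fns, residuals = res)
}

.cache <- new.env(parent = emptyenv())

#' Default (calibrated) scoring functions
#'
#' The package's shipped scoring system: the piecewise-linear functions
#' recovered by [calibrateScoringFunctions()] from the packaged table pairs,
#' plus the serial-organ step functions at the institutional tolerances. The
#' calibration is deterministic and cached for the session.
#'
#' @return named list of scoring-function objects (coverage, hotspot, parotid,
#'   oral_cavity, brainstem, spinal_cord).
#' @export
defaultScoringFunctions <- function() {
  if (is.null(.cache$fns))
    .cache$fns <- calibrateScoringFunctions()$functions
  .cache$fns
}
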