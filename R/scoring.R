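#' @include AllClasses.R AllGenerics.R
NULL

# canonical criterion order = the scorecard column order
.criteria <- data.frame(
  structure = c("CTV-High", "CTV-High", "CTV-Mid", "CTV-Low", "Right Parotid",
                "Left Parotid", "Oral Cavity", "Brainstem", "Spinal Cord"),
  metric = c("V100", "Dmax", "V100", "V100", "Dmean", "Dmean", "Dmean",
             "D0.03cc", "D0.03cc"),
  fn = c("coverage", "hotspot", "coverage", "coverage", "parotid", "parotid",
         "oral_cavity", "brainstem", "spinal_cord"),
  key = c("ctv_high_v100", "ctv_high_dmax", "ctv_mid_v100", "ctv_low_v100",
          "right_parotid_dmean", "left_parotid_dmean", "oral_cavity_dmean",
          "brainstem_d003cc", "spinal_cord_d003cc"),
  stringsAsFactors = FALSE
)

#' Institutional clinical planning goals
#'
#' The nine default planning goals: CTV coverage V100 >= 98% for each CTV
#' level, CTV-High Dmax <= 107% of prescription, parotid mean dose <= 26
#' Gy-RBE, oral cavity mean dose <= 35 Gy-RBE, brainstem D0.03cc <= 63 Gy-RBE
#' and spinal cord D0.03cc <= 54 Gy-RBE.
#'
#' @return data.frame with columns structure, metric, bound, direction
#'   ("ge" or "le").
#' @export
defaultClinicalGoals <- function() {
  data.frame(
    structure = .criteria$structure,
    metric = .criteria$metric,
    bound = c(98, 107, 98, 98, 26, 26, 35, 63, 54),
    direction = c("ge", "le", "ge", "ge", "le", "le", "le", "le", "le"),
    stringsAsFactors = FALSE
  )
}

#' @describeIn evalScore piecewise-linear evaluation: linear between knots,
#'   flat at the cap beyond the good end, linear continuation (unbounded
#'   negative) beyond the bad end.
#' @export
setMethod("evalScore", "PiecewiseScoringFunction", function(fn, x) {
  if (any(!is.finite(x))) stop("metric value must be finite")
  xs <- fn@knots[, 1]; ys <- fn@knots[, 2]; n <- length(xs)
  y <- stats::approx(xs, ys, xout = x, rule = 2, ties = "ordered")$y
  if (fn@direction == "higher") {
    idx <- x < xs[1]
    if (any(idx)) {
      s <- (ys[2] - ys[1]) / (xs[2] - xs[1])
      y[idx] <- ys[1] + (x[idx] - xs[1]) * s
    }
  } else {
    idx <- x > xs[n]
    if (any(idx)) {
      s <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
      y[idx] <- ys[n] + (x[idx] - xs[n]) * s
    }
  }
  pmin(y, fn@cap)
})

#' @describeIn evalScore serial-organ step: full score within tolerance,
#'   penalty above.
#' @export
setMethod("evalScore", "SerialOrganScoringFunction", function(fn, x) {
  serialOrganScore(x, fn@tolerance, fn@fullScore, fn@penalty)
})

#' Serial-organ sparing score
#'
#' Step scoring used for brainstem and spinal cord: the full score while the
#' near-maximum dose D0.03cc stays within tolerance, and a large negative
#' penalty above it (exceeding a serial-organ tolerance is clinically
#' unacceptable).
#'
#' @param d003 D0.03cc values in Gy-RBE (>= 0).
#' @param tolerance tolerance dose in Gy-RBE.
#' @param fullScore score at or below tolerance (default 7).
#' @param penalty score above tolerance (default -150).
#' @return numeric vector of scores.
#' @examples
#' serialOrganScore(62.9, 63)   # within tolerance -> 7
#' serialOrganScore(63.1, 63)   # above -> -150
#' @export
serialOrganScore <- function(d003, tolerance, fullScore = 7, penalty = -150) {
  if (any(!is.finite(d003)) || any(d003 < 0))
    stop("'d003' must be finite and >= 0")
  ifelse(d003 <= tolerance + .eps, fullScore, penalty)
}

.lookupValue <- function(endpoints, structure, metric) {
  i <- which(endpoints$structure == structure)
  if (length(i) == 0L) return(NA_real_)
  endpoints[[metric]][i[1]]
}

#' Evaluate clinical goals against an endpoint table
#'
#' @param endpoints endpoint table (one row per structure, as from
#'   [extractEndpoints()]).
#' @param goals goals table (see [defaultClinicalGoals()]).
#' @return the goals table with added columns `value` and `pass` (NA when the
#'   structure is absent; an absent structure does not fail its goal).
#' @export
checkGoals <- function(endpoints, goals = defaultClinicalGoals()) {
  goals$value <- mapply(.lookupValue, goals$structure, goals$metric,
                        MoreArgs = list(endpoints = endpoints))
  goals$pass <- ifelse(is.na(goals$value), NA,
                       ifelse(goals$direction == "ge",
                              goals$value >= goals$bound - .eps,
                              goals$value <= goals$bound + .eps))
  goals
}

#' Score one endpoint row set into a ScoreCard
#'
#' Applies the scoring functions to a single plan's endpoint table: one score
#' per criterion whose structure is present, NA (dropped from the total) for
#' absent structures. D98 values are carried in endpoint tables but never
#' scored. The total is the equally-weighted sum of the present criterion
#' scores, computed unrounded.
#'
#' @param endpoints endpoint table for one plan (one row per structure).
#' @param goals goals table; defaults to [defaultClinicalGoals()].
#' @param fns named list of scoring functions as from
#'   [defaultScoringFunctions()]; must contain an entry for every scored
#'   criterion present in `endpoints`.
#' @return a [ScoreCard-class].
#' @export
scoreEndpoints <- function(endpoints, goals = defaultClinicalGoals(),
                           fns = defaultScoringFunctions()) {
  crit <- .criteria[paste(.criteria$structure, .criteria$metric) %in%
                    paste(goals$structure, goals$metric), , drop = FALSE]
  scores <- vapply(seq_len(nrow(crit)), function(i) {
    x <- .lookupValue(endpoints, crit$structure[i], crit$metric[i])
    if (is.na(x)) return(NA_real_)
    fname <- crit$fn[i]
    if (is.null(fns[[fname]]))
      stop("endpoint present but no fitted scoring function for '", fname, "'")
    evalScore(fns[[fname]], x)
  }, numeric(1))
  names(scores) <- crit$key
  ScoreCard(scores)
}

#' Score a long endpoint table into a Table-4-shaped scorecard table
#'
#' @param tab long endpoint table with columns patient, course, structure and
#'   the metric columns (as read by [readEndpointTable()]).
#' @param goals,fns as in [scoreEndpoints()].
#' @param digits round the reported scores to this many decimals (default 1,
#'   the printing convention); totals are computed from unrounded criterion
#'   scores and rounded once. Use NA to disable rounding.
#' @return data.frame with patient, course, one column per criterion and a
#'   `total` column.
#' @export
scoreEndpointTable <- function(tab, goals = defaultClinicalGoals(),
                               fns = defaultScoringFunctions(), digits = 1) {
  keys <- unique(tab[, c("patient", "course")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$patient == keys$patient[i] & tab$course == keys$course[i], ]
    card <- scoreEndpoints(sub, goals, fns)
    out <- c(as.list(criterionScores(card)), total = totalScore(card))
    if (!is.na(digits)) out <- lapply(out, round, digits = digits)
    cbind(keys[i, , drop = FALSE], as.data.frame(out), row.names = NULL)
  })
  do.call(rbind, rows)
}
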