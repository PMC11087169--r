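fns <- defaultScoringFunctions()

test_that("calibrated functions reproduce published per-criterion scores", {
  # full coverage earns the cap
  expect_equal(evalScore(fns$coverage, 100), 7)
  # published endpoint -> score pairs (patient 1 nominal CTV-High coverage,
  # patient 3 offline hot-spot, patient 7 nominal left parotid)
  expect_equal(evalScore(fns$coverage, 90.4), -7.7, tolerance = 0.015)
  expect_equal(evalScore(fns$hotspot, 109.2), 1.3, tolerance = 0.05)
  expect_equal(evalScore(fns$parotid, 32.0), -2.5, tolerance = 0.02)
  expect_error(evalScore(fns$coverage, NaN), "finite")
})

test_that("fitted functions are continuous, capped, monotone and goal-knotted", {
  goals <- defaultClinicalGoals()
  for (nm in c("coverage", "hotspot", "parotid", "oral_cavity")) {
    fn <- fns[[nm]]
    xs <- seq(fn@knots[1, 1] - 10, fn@knots[nrow(fn@knots), 1] + 10,
              length.out = 400)
    ys <- evalScore(fn, xs)
    expect_true(all(ys <= 7 + 1e-9))
    d <- diff(ys)
    if (fn@direction == "higher") expect_true(all(d >= -1e-9))
    else expect_true(all(d <= 1e-9))
    # continuity: no jump larger than the local slope allows
    expect_lt(max(abs(d)), 2 * max(abs(diff(fn@knots[, 2]) /
                                        diff(fn@knots[, 1]))) * (xs[2] - xs[1]))
    expect_true(any(abs(fn@knots[, 1] - fn@goal) < 1e-6))
  }
  expect_equal(fns$brainstem@tolerance, 63)
  expect_equal(fns$spinal_cord@tolerance, 54)
})

test_that("calibration recovers a known piecewise function from noiseless pairs", {
  truth <- scoringFunction("Dmean", "lower",
                           rbind(c(20, 7), c(26, 5), c(40, -12.5)), goal = 26)
  xs <- c(21, 23, 24.5, 25.5, 26, 27, 30, 33, 38, 40)
  pairs <- data.frame(fn = "parotid", metric = "Dmean", x = xs,
                      y = evalScore(truth, xs), patient = 0, course = "nominal",
                      structure = "Right Parotid", serial = FALSE,
                      excluded = FALSE, reason = "")
  cal <- calibrateScoringFunctions(pairs[pairs$fn == "parotid", ])
  probe <- seq(20, 40, by = 0.25)
  expect_equal(evalScore(cal$functions$parotid, probe), evalScore(truth, probe),
               tolerance = 1e-9)
})

test_that("calibration flags under-determined segments instead of guessing", {
  oneSided <- data.frame(fn = "parotid", metric = "Dmean",
                         x = c(27, 30, 35), y = c(3.8, 0, -6.1),
                         patient = 0, course = "nominal",
                         structure = "Right Parotid", serial = FALSE,
                         excluded = FALSE, reason = "")
  expect_error(calibrateScoringFunctions(oneSided), "under-determined")
  expect_error(calibrateScoringFunctions(oneSided[1:2, ]), "under-determined")
})

test_that("one shared coverage function fits all three CTV levels", {
  cal <- calibrateScoringFunctions()
  res <- cal$residuals
  cov <- res[res$fn == "coverage" & !res$excluded, ]
  for (lvl in c("CTV-High", "CTV-Mid", "CTV-Low"))
    expect_lt(max(abs(cov$residual[cov$structure == lvl])), 0.15)
})

test_that("serial-organ scoring is a step at the tolerance", {
  expect_equal(serialOrganScore(62.9, 63), 7)    # within tolerance
  expect_equal(serialOrganScore(38.0, 54), 7)
  expect_equal(serialOrganScore(63.1, 63), -150) # tolerance + 0.1
  expect_equal(serialOrganScore(c(10, 54, 54.1), 54), c(7, 7, -150))
  expect_equal(serialOrganScore(60, 54, penalty = -99), -99)
  expect_error(serialOrganScore(-1, 63), "finite")
})

test_that("scoreEndpoints reproduces the published patient 1 nominal scorecard", {
  t3 <- endpointTable3()
  row <- t3[t3$patient == 1 & t3$course == "nominal", ]
  card <- scoreEndpoints(row)
  expect_equal(unname(criterionScores(card)),
               c(-7.7, 5.2, 2.2, 6.1, 7.0, 7.0, 7.0, 7.0, 7.0),
               tolerance = 0.02)
  expect_equal(totalScore(card), 40.8, tolerance = 0.15)
})

test_that("missing structures are dropped from the scorecard total", {
  t3 <- endpointTable3()
  row <- t3[t3$patient == 5 & t3$course == "nominal", ]
  card <- scoreEndpoints(row)
  s <- criterionScores(card)
  expect_true(is.na(s["ctv_mid_v100"]))
  expect_equal(sum(!is.na(s)), 8)
  expect_equal(totalScore(card), sum(s, na.rm = TRUE))
  expect_equal(totalScore(card), 38.4, tolerance = 0.2)
})

test_that("endpoints exactly at the goals earn the goal-knot scores", {
  goals <- defaultClinicalGoals()
  ep <- data.frame(
    structure = c("CTV-High", "CTV-Mid", "CTV-Low", "Right Parotid",
                  "Left Parotid", "Oral Cavity", "Brainstem", "Spinal Cord"),
    V100 = c(98, 98, 98, NA, NA, NA, NA, NA),
    D98 = NA_real_,
    Dmax = c(107, NA, NA, NA, NA, NA, NA, NA),
    Dmean = c(NA, NA, NA, 26, 26, 35, NA, NA),
    "D0.03cc" = c(NA, NA, NA, NA, NA, NA, 63, 54),
    check.names = FALSE)
  card <- scoreEndpoints(ep, goals)
  want <- c(evalScore(fns$coverage, 98), evalScore(fns$hotspot, 107),
            evalScore(fns$coverage, 98), evalScore(fns$coverage, 98),
            evalScore(fns$parotid, 26), evalScore(fns$parotid, 26),
            evalScore(fns$oral_cavity, 35), 7, 7)
  expect_equal(unname(criterionScores(card)), want)
  expect_equal(totalScore(card), sum(want))
  # the goal-knot scores of the dose-type criteria sit near the published
  # goal level of 5
  expect_equal(want[c(2, 5, 7)], rep(5, 3), tolerance = 0.05)
})

test_that("scoring is invariant to row order and extra absent structures", {
  t3 <- endpointTable3()
  row <- t3[t3$patient == 2 & t3$course == "online", ]
  card <- scoreEndpoints(row)
  shuffled <- row[rev(seq_len(nrow(row))), ]
  expect_identical(criterionScores(scoreEndpoints(shuffled)),
                   criterionScores(card))
  extra <- rbind(row, data.frame(patient = 2, course = "online",
                                 structure = "CTV-Mid2", V100 = NA, D98 = NA,
                                 Dmax = NA, Dmean = NA, "D0.03cc" = NA,
                                 check.names = FALSE))
  expect_identical(criterionScores(scoreEndpoints(extra)),
                   criterionScores(card))
})

test_that("a present endpoint without a fitted function is a configuration error", {
  t3 <- endpointTable3()
  row <- t3[t3$patient == 1 & t3$course == "nominal", ]
  broken <- defaultScoringFunctions()
  broken$parotid <- NULL
  expect_error(scoreEndpoints(row, fns = broken), "no fitted scoring function")
})

test_that("scorecard totals conserve the sum of present criteria exactly", {
  sc <- scoreEndpointTable(endpointTable3(), digits = NA)
  crit <- setdiff(names(sc), c("patient", "course", "total"))
  expect_equal(rowSums(sc[, crit], na.rm = TRUE), sc$total)
})
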