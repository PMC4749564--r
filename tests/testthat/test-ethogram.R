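# Ethogram validation, interval statistics, initiation rates, cumulative
# first-lift histograms, progression histograms, and session IO.

test_that("canonical trials validate; ordering violations are reported", {
  tr <- makeTrial(canonicalRows())
  expect_length(validateTrial(tr), 0)
  bad <- makeTrial(list(list("Grab", 200, 240), list("Lift", 250, 290)))
  expect_match(paste(validateTrial(bad), collapse = "; "), "ordering")
  none <- makeTrial(NULL, outcome = "no_initiation")
  expect_length(validateTrial(none), 0)
  rev <- makeTrial(canonicalRows(), laserOn = 500, laserOff = 400)
  expect_match(paste(validateTrial(rev), collapse = "; "), "laser")
})

test_that("interval statistics follow the annotation definitions", {
  tr <- makeTrial(list(list("Lift", 1250, 1280), list("HandOpen", 1284, 1300),
                       list("Grab", 1311, 1340), list("Supinate", 1340, 1375),
                       list("AtMouth", 1375, 1450)), cue = 1000)
  iv <- intervalStats(tr, "cue")
  expect_equal(iv$first_lift, 500)            # (1250 - 1000) / 500 fps
  expect_equal(iv$lift_to_handopen, 68)       # 34 frames
  expect_equal(iv$lift_to_grab, 122)
  expect_equal(iv$handopen_to_grab, 54)
  expect_equal(iv$grab_to_supinate, 58)
  expect_equal(iv$supinate_to_atmouth, 70)
  expect_equal(iv$grab_to_atmouth, 128)
  expect_error(intervalStats(tr, "laser_off"), "no laser_off")
})

test_that("final-sequence intervals use the last maximal canonical run", {
  # an interrupted reach followed by a complete rebound sequence
  rows <- c(list(list("Lift", 300, 330), list("HandOpen", 330, 350)),
            canonicalRows(liftStart = 800, step = 30))
  tr <- makeTrial(rows)
  iv <- intervalStats(tr, "cue")
  expect_equal(iv$grab_to_supinate, 60)   # from the rebound run (30-frame steps)
  expect_equal(iv$first_lift, 400)        # still the first Lift after cue
})

test_that("initiation rates are exact counts over the bracketed window", {
  mk <- function(liftStart) makeTrial(canonicalRows(liftStart), cue = 100)
  # fixture session: one Lift per trial inside the window, 124 trials
  ses <- lapply(rep(300, 124), mk)
  expect_identical(initiationRate(ses, c(0, 1000)), c(initiated = 124L, total = 124L))
  # no Lift in window
  expect_identical(initiationRate(ses, c(1000, 2000)), c(initiated = 0L, total = 124L))
  none <- lapply(1:5, function(i) makeTrial(NULL, outcome = "no_initiation"))
  expect_identical(initiationRate(none, c(0, 1000)), c(initiated = 0L, total = 5L))
  expect_identical(initiationRate(list(), c(0, 1000)), c(initiated = 0L, total = 0L))
  # half-open boundary: a Lift exactly at the window end does not count
  edge <- list(makeTrial(canonicalRows(1100), cue = 100))
  expect_identical(initiationRate(edge, c(0, 1000))[["initiated"]], 0L)
  expect_identical(initiationRate(edge, c(0, 1001))[["initiated"]], 1L)
})

test_that("cumulative first-lift histogram is a monotone step function", {
  none <- lapply(1:4, function(i) makeTrial(NULL, outcome = "no_initiation"))
  h0 <- cumulativeFirstLift(none)
  expect_identical(nrow(h0), 0L)
  expect_equal(attr(h0, "fun")(c(0, 500)), c(0, 0))
  same <- lapply(1:7, function(i) makeTrial(canonicalRows(350), cue = 100))
  h1 <- cumulativeFirstLift(same)
  expect_identical(nrow(h1), 1L)
  expect_equal(h1$cum_count, 7)
  expect_equal(attr(h1, "fun")(c(499, 500, 501)), c(0, 7, 7))
  # terminal value equals the initiation count on a covering window
  mixed <- lapply(c(200, 250, 400, 800), function(s) makeTrial(canonicalRows(s), cue = 100))
  h2 <- cumulativeFirstLift(mixed)
  expect_true(all(diff(h2$cum_count) >= 0))
  expect_equal(tail(h2$cum_count, 1),
               unname(initiationRate(mixed, c(0, 1e6))["initiated"]))
})

test_that("progression histogram matches controls and scores transitions", {
  ctrl <- lapply(1:20, function(i) makeTrial(canonicalRows(250 + i), id = paste0("c", i)))
  # laser during Lift, frozen: only Lift annotated, nothing after
  laser <- lapply(1:6, function(i)
    makeTrial(list(list("Lift", 250, 280)), laserOn = 260, laserOff = 1260,
              outcome = "failure", id = paste0("l", i)))
  ph <- progressionHistogram(laser, ctrl, seed = 5)
  laserRows <- ph[ph$condition == "laser", ]
  ctrlRows <- ph[ph$condition == "control", ]
  expect_true(all(ctrlRows$pct == 100))        # complete controls: 100% everywhere
  expect_true(all(laserRows$pct == 0))         # frozen: 0% beyond the freeze point
  expect_true(all(ctrlRows$n == 6))            # matched control count per animal
  expect_true(all(ph$group == "Lift"))
  # reproducible and order-invariant
  ph2 <- progressionHistogram(rev(laser), ctrl, seed = 5)
  expect_identical(ph, ph2)
  expect_error(progressionHistogram(laser, list(), seed = 1), "no eligible control")
})

test_that("epoch at laser onset picks the last started component", {
  tr <- makeTrial(canonicalRows(250, step = 40), laserOn = 345, laserOff = 800)
  expect_identical(epochAtLaserOnset(tr), "Grab")  # Grab starts at 330 <= 345
  pre <- makeTrial(canonicalRows(500), laserOn = 100, laserOff = 300)
  expect_identical(epochAtLaserOnset(pre), "none")
})

test_that("sessions round-trip through JSON and epochs through CSV", {
  kin <- reachKinematicsParams()
  trials <- simulateSession(6, kin, laserFraction = 0.4, seed = 61,
                            nFrames = 1600, cueFrame = 200)
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p), add = TRUE)
  writeSession(trials, p)
  back <- readSession(p)
  expect_length(back, 6)
  for (i in seq_along(trials)) {
    expect_identical(back[[i]]@trialId, trials[[i]]@trialId)
    expect_equal(back[[i]]@epochs, trials[[i]]@epochs)
    expect_equal(back[[i]]@laserOnFrame, trials[[i]]@laserOnFrame)
    expect_identical(back[[i]]@outcome, trials[[i]]@outcome)
  }
  pc <- tempfile(fileext = ".csv")
  on.exit(unlink(pc), add = TRUE)
  trialsToEpochCSV(trials, pc)
  flat <- epochCSVToFrame(pc)
  expect_identical(nrow(flat), sum(vapply(trials, function(t) nrow(t@epochs), 0L)))
})

test_that("session laser fraction stays near the configured 20%", {
  kin <- reachKinematicsParams()
  trials <- simulateSession(60, kin, laserFraction = 0.2, seed = 62,
                            nFrames = 1600, cueFrame = 200)
  nl <- sum(vapply(trials, function(t) !is.na(t@laserOnFrame), TRUE))
  expect_gt(nl, 2); expect_lt(nl, 25)
})
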