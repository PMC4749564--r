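# Synthetic trial, video and spike-train generators.

test_that("unperturbed trials have canonical epochs and grab at the pellet", {
  kin <- reachKinematicsParams()
  for (seed in c(3, 17, 91)) {
    tr <- simulateTrial(kin, seed = seed)
    expect_identical(epochs(tr)$label, canonicalEpochs())
    expect_true(all(diff(epochs(tr)$start) > 0))
    expect_length(validateTrial(tr), 0)
    grabStart <- epochs(tr)$start[epochs(tr)$label == "Grab"]
    grabPos <- trajectory3d(tr)[grabStart + 1, ]
    expect_lt(sqrt(sum((grabPos - kin@pelletPos)^2)), 3 * kin@positionNoiseSD * sqrt(3))
  }
})

test_that("laser covering the cue blocks initiation until after laser offset", {
  kin <- reachKinematicsParams()
  pert <- perturbationParams(laserOnFrame = 500, laserDurationMs = 4000,
                             reboundProbVsDuration = c("4000" = 1))
  for (seed in 1:5) {
    tr <- simulateTrial(kin, pert, seed = seed, nFrames = 4500)
    ep <- epochs(tr)
    lifts <- ep$start[ep$label == "Lift"]
    expect_true(all(lifts >= tr@laserOffFrame))
    expect_identical(tr@meta$rebounded, TRUE)
    expect_length(validateTrial(tr), 0)
  }
})

test_that("no-rebound suppression at cue yields a valid non-initiation trial", {
  kin <- reachKinematicsParams()
  pert <- perturbationParams(laserOnFrame = 500, laserDurationMs = 2000,
                             reboundProbVsDuration = c("2000" = 0))
  tr <- simulateTrial(kin, pert, seed = 4)
  expect_identical(outcome(tr), "no_initiation")
  expect_identical(nrow(epochs(tr)), 0L)
  expect_length(validateTrial(tr), 0)
  # the hand never leaves the perch (beyond noise)
  expect_lt(max(abs(sweep(trajectory3d(tr), 2, kin@perchPos))),
            6 * kin@positionNoiseSD)
})

test_that("laser window outside the trial duration is a parameter error", {
  kin <- reachKinematicsParams()
  pert <- perturbationParams(laserOnFrame = 3000, laserDurationMs = 4000)
  expect_error(simulateTrial(kin, pert, seed = 1, nFrames = 3500),
               "outside the trial")
})

test_that("rebound fraction matches the configured probability (binomial CI)", {
  kin <- reachKinematicsParams()
  pert <- perturbationParams(laserOnFrame = 400, laserDurationMs = 2000,
                             reboundProbVsDuration = c("2000" = 0.9))
  set.seed(501)
  seeds <- sample.int(2^31 - 1, 1000)
  reb <- vapply(seeds, function(s)
    isTRUE(simulateTrial(kin, pert, seed = s, nFrames = 2200,
                         cueFrame = 400)@meta$rebounded), TRUE)
  ci <- 0.9 + c(-1, 1) * 1.96 * sqrt(0.9 * 0.1 / 1000)
  expect_gte(mean(reb), ci[1])
  expect_lte(mean(reb), ci[2])
})

test_that("rebound first-lift latencies are less variable than control", {
  kin <- reachKinematicsParams()  # control latency sd 80 ms > rebound sd 40 ms
  set.seed(502)
  seeds <- sample.int(2^31 - 1, 400)
  ctrl <- vapply(seeds[1:200], function(s)
    intervalStats(simulateTrial(kin, seed = s, nFrames = 1400, cueFrame = 200),
                  "cue")$first_lift, 0)
  pert <- perturbationParams(laserOnFrame = 200, laserDurationMs = 1500,
                             reboundProbVsDuration = c("1500" = 1))
  reb <- vapply(seeds[201:400], function(s)
    intervalStats(simulateTrial(kin, pert, seed = s, nFrames = 1700,
                                cueFrame = 200), "laser_off")$first_lift, 0)
  expect_lt(sd(reb), sd(ctrl))
})

test_that("generators reproduce bit-identically under a fixed seed", {
  kin <- reachKinematicsParams()
  expect_identical(simulateTrial(kin, seed = 11), simulateTrial(kin, seed = 11))
  scene <- sceneParams()
  tr <- simulateTrial(kin, seed = 11, nFrames = 900, cueFrame = 100)
  v1 <- renderStereoVideo(tr, scene, seed = 2, frameRange = c(300, 304))
  v2 <- renderStereoVideo(tr, scene, seed = 2, frameRange = c(300, 304))
  expect_identical(v1, v2)
  p <- spikeSimParams(nTrials = 5)
  expect_identical(simulateSpikeTrains(p, seed = 3), simulateSpikeTrains(p, seed = 3))
})

test_that("rendered frames have the acquisition geometry and blob at the projection", {
  kin <- reachKinematicsParams()
  scene0 <- sceneParams(backgroundNoiseSD = 0)
  tr <- simulateTrial(kin, seed = 21, nFrames = 900, cueFrame = 100)
  lift <- epochs(tr)$start[1]
  vid <- renderStereoVideo(tr, scene0, seed = 1, frameRange = c(lift, lift + 19))
  for (v in c("front", "side")) {
    expect_identical(dim(vid$frames[[v]][[1]]), c(260L, 352L))
    for (i in c(1, 10, 20)) {
      img <- vid$frames[[v]][[i]]
      am <- which(img == max(img), arr.ind = TRUE)[1, ]
      gt <- vid$tracks[[v]][i, ]
      expect_lt(abs((am["col"] - 1) - gt[1]), 1 + 1e-9)
      expect_lt(abs((am["row"] - 1) - gt[2]), 1 + 1e-9)
    }
  }
})

test_that("ground-truth stereo tracks triangulate back to the 3D trajectory", {
  kin <- reachKinematicsParams(positionNoiseSD = 0)
  scene <- sceneParams()
  tr <- simulateTrial(kin, seed = 22, nFrames = 900, cueFrame = 100)
  lift <- epochs(tr)$start[1]
  vid <- renderStereoVideo(tr, scene, seed = 1, frameRange = c(lift, lift + 49))
  tk3 <- triangulateTrack(vid$tracks$front, vid$tracks$side, scene@cameras)
  gt <- trajectory3d(tr)[vid$frameIndex + 1, ]
  err <- sqrt(rowSums((as.matrix(tk3[, c("x_mm", "y_mm", "z_mm")]) - gt)^2))
  expect_lt(max(err), 1e-3)
})

test_that("out-of-frame projections are rendered with a warning record", {
  kin <- reachKinematicsParams(pelletPos = c(80, 15, -5))  # projects far off-frame
  scene <- sceneParams()
  tr <- simulateTrial(kin, seed = 23, nFrames = 900, cueFrame = 100)
  grab <- epochs(tr)$start[epochs(tr)$label == "Grab"]
  expect_warning(
    vid <- renderStereoVideo(tr, scene, seed = 1, frameRange = c(grab, grab + 4)),
    "outside the image bounds")
  expect_gt(nrow(vid$outOfBounds), 0)
  expect_length(vid$frames$front, 5)  # frames still rendered
})

test_that("frame stacks round-trip through PNG with the manifest", {
  kin <- reachKinematicsParams()
  scene <- sceneParams()
  tr <- simulateTrial(kin, seed = 24, nFrames = 900, cueFrame = 100)
  vid <- renderStereoVideo(tr, scene, seed = 1, frameRange = c(400, 403))
  d <- tempfile("stacks")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  writeFrameStacks(vid, d, seed = 1)
  expect_true(file.exists(file.path(d, "front", "frame_000400.png")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  img <- png::readPNG(file.path(d, "front", "frame_000400.png"))
  expect_identical(dim(img), c(260L, 352L))
  tk <- read.csv(file.path(d, "track_front.csv"))
  expect_equal(tk$x_px, vid$tracks$front[, 1], tolerance = 1e-9)
})

test_that("spike trains follow the piecewise Poisson rate profile", {
  # zero baseline -> empty trains
  p0 <- spikeSimParams(baselineRate = 0, nTrials = 10)
  expect_true(all(lengths(simulateSpikeTrains(p0, seed = 1)) == 0))
  # baseline 10 Hz, no laser, 100 trials of 4 s -> mean count within 2 SEM of 40
  p1 <- spikeSimParams(baselineRate = 10, laserWindow = c(NA, NA),
                       trialDuration = 4, nTrials = 100)
  counts <- lengths(simulateSpikeTrains(p1, seed = 2))
  expect_lt(abs(mean(counts) - 40), 2 * sqrt(40 / 100))
  # suppression 0.9 -> laser-window rate within 2 SEM of 1 Hz
  p2 <- spikeSimParams(baselineRate = 10, suppressionFraction = 0.9,
                       laserWindow = c(1, 3), trialDuration = 4, nTrials = 200)
  trains <- simulateSpikeTrains(p2, seed = 3)
  nLaser <- sum(vapply(trains, function(s) sum(s >= 1 & s < 3), 0))
  rate <- nLaser / (200 * 2)
  expect_lt(abs(rate - 1), 2 * sqrt(1 / (200 * 2)))
})
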