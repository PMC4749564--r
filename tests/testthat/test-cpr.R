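# Cascaded pose regression: features, training, tracking, smoothing,
# corrections.

test_that("pose-indexed features are intensity differences with clamping", {
  img <- matrix(0.5, 40, 60)
  defs <- rbind(c(3, 0, -3, 0), c(0, 5, 0, -5))
  expect_equal(poseIndexedFeatures(img, c(30, 20), defs), c(0, 0))
  img2 <- img
  img2[21, 34] <- 10  # pose (30, 20) + offsetA (3, 0) -> pixel (33, 20)
  img2[21, 28] <- 3   # pose + offsetB (-3, 0) -> pixel (27, 20)
  expect_equal(poseIndexedFeatures(img2, c(30, 20), defs)[1], 7)
  expect_error(poseIndexedFeatures(img, c(30, 20), matrix(numeric(0), 0, 4)),
               "at least one offset pair")
  # out-of-bounds samples clamp to the nearest pixel instead of erroring
  expect_equal(poseIndexedFeatures(img, c(0, 0), rbind(c(-10, -10, 10, 10))), 0)
})

test_that("features are equivariant under joint image/pose translation", {
  set.seed(31)
  for (rep in 1:5) {
    big <- matrix(runif(120 * 120), 120, 120)
    defs <- cbind(runif(8, -6, 6), runif(8, -6, 6),
                  runif(8, -6, 6), runif(8, -6, 6))
    pose <- c(40, 50)
    shift <- c(5, 5)
    f1 <- poseIndexedFeatures(big[1:80, 1:80], pose, defs)
    shifted <- big[1:80 + shift[2], 1:80 + shift[1]]
    f2 <- poseIndexedFeatures(shifted, pose - shift, defs)
    expect_equal(f1, f2)
  }
})

test_that("training rejects bad input and warns on degenerate labels", {
  img <- matrix(0, 20, 20)
  expect_error(trainCascade(list(), matrix(numeric(0), 0, 2)), "empty")
  expect_error(trainCascade(rep(list(img), 5), cbind(1:5, 1:5)), "at least 10")
  expect_error(trainCascade(rep(list(img), 12), cbind(rep(50, 12), rep(5, 12))),
               "inside the image")
  expect_warning(
    m <- trainCascade(rep(list(img), 12), cbind(rep(5, 12), rep(5, 12)),
                      nStages = 2, nFerns = 5, poolSize = 20, augPerFrame = 2),
    "degenerate")
  expect_s4_class(m, "CascadeModel")
})

test_that("training error decreases over stages and tracking finds the blob", {
  tk <- smallTracker()
  errs <- tk$model@trainingMeta$stageMedianErrors
  expect_true(all(diff(errs) <= 0.5))
  expect_lt(tail(errs, 1), 2)
  # held-out frames: top mode within 3 px of ground truth (a mid-scale fixture
  # needs more initializations than the full-scale default for a stable top
  # mode; the full-scale configuration is exercised in the acceptance tests)
  heldOut <- makeTrainingFrames(10, tk$scene, seed = 404)
  cfg <- trackConfig(nInits = 150)
  hits <- 0
  for (i in 1:10) {
    modes <- trackFrame(heldOut$frames[[i]], tk$model, cfg, seed = i)
    d <- sqrt(sum((c(modes$x[1], modes$y[1]) - heldOut$labels[i, ])^2))
    hits <- hits + (d < 3)
  }
  expect_gte(hits, 9)
})

test_that("a pure-noise frame yields only diffuse, low-confidence modes", {
  tk <- smallTracker()
  set.seed(405)
  noise <- matrix(runif(260 * 352), 260, 352)
  cfg <- trackConfig()
  modes <- trackFrame(noise, tk$model, cfg, seed = 9)
  expect_lt(modes$weight[1] / cfg@nInits, cfg@errorSpreadThreshold)
})

test_that("cascade models serialize to JSON and back unchanged", {
  tk <- smallTracker()
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  writeCascadeModel(tk$model, p)
  m2 <- readCascadeModel(p)
  expect_equal(m2@offsets, tk$model@offsets)
  expect_equal(m2@thresholds, tk$model@thresholds)
  expect_equal(m2@outputs, tk$model@outputs)
  img <- matrix(runif(100), 10, 10)
  set.seed(1); a <- trackFrame(img, tk$model, seed = 2)
  set.seed(1); b <- trackFrame(img, m2, seed = 2)
  expect_equal(a, b)
})

test_that("the 100-stage default configuration trains and serializes", {
  # tiny training set; this checks the full-depth cascade plumbing only
  ts <- makeTrainingFrames(12, seed = 406)
  m <- trainCascade(ts$frames, ts$labels, nStages = 100, nFerns = 4,
                    fernDepth = 3, poolSize = 30, augPerFrame = 2, seed = 407)
  expect_identical(m@nStages, 100)
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  writeCascadeModel(m, p)
  expect_identical(readCascadeModel(p)@nStages, 100)
})

test_that("smoothing with lambda = 0 reduces to per-frame top modes", {
  set.seed(32)
  modes <- randomModes(8, 4)
  cfg <- trackConfig(smoothnessWeight = 0)
  sm <- smoothTrack(modes, cfg)
  top <- vapply(modes, function(m) which.max(m$weight), 0L)
  expect_identical(sm$selected, top)
})

test_that("constant-position candidates give a constant, unflagged track", {
  modes <- rep(list(data.frame(x = 55, y = 70, weight = 50)), 10)
  sm <- smoothTrack(modes, trackConfig())
  expect_true(all(sm$track$x_px == 55 & sm$track$y_px == 70))
  expect_false(any(sm$track$flagged))
})

test_that("a displaced middle frame is overridden or flagged", {
  cfg <- trackConfig()
  agree <- data.frame(x = c(50), y = c(50), weight = c(45))
  middle <- data.frame(x = c(100, 51), y = c(50, 50), weight = c(30, 15))
  sm <- smoothTrack(list(agree, middle, agree), cfg)
  picked <- sm$track[2, ]
  expect_true(picked$x_px == 51 || picked$flagged)
  # and the DP solution matches exhaustive enumeration
  bf <- bruteForceSmooth(list(agree, middle, agree), cfg)
  expect_identical(sm$selected, bf$selected)
})

test_that("DP mode selection equals brute force on random small instances", {
  set.seed(33)
  for (rep in 1:60) {
    modes <- randomModes(sample(2:6, 1), sample(2:4, 1))
    cfg <- trackConfig(smoothnessWeight = 10^runif(1, -4, -1))
    sm <- smoothTrack(modes, cfg)
    bf <- bruteForceSmooth(modes, cfg)
    expect_identical(sm$selected, bf$selected)
  }
})

test_that("smoothTrack validates its input", {
  expect_error(smoothTrack(list(), trackConfig()), "empty")
  expect_error(smoothTrack(list(data.frame(x = 1, y = 1, weight = 1),
                                data.frame(x = numeric(0), y = numeric(0),
                                           weight = numeric(0))),
                           trackConfig()), "at least one candidate")
})

test_that("corrections pin frames, clear flags, and match an exhaustive re-solve", {
  set.seed(34)
  modes <- randomModes(6, 3)
  cfg <- trackConfig(smoothnessWeight = 0.01)
  base <- smoothTrack(modes, cfg)
  # empty corrections: identity
  same <- applyCorrections(modes, data.frame(frame = numeric(0), x_px = numeric(0),
                                             y_px = numeric(0)), cfg)
  expect_identical(same$track, base$track)
  # pin frame 2 (0-based) and compare with enumeration over the pinned problem
  corr <- data.frame(frame = 2, x_px = 40, y_px = 60)
  fixed <- applyCorrections(modes, corr, cfg)
  expect_equal(fixed$track$x_px[3], 40)
  expect_equal(fixed$track$confidence[3], 1)
  expect_false(fixed$track$flagged[3])
  pinnedModes <- modes
  pinnedModes[[3]] <- data.frame(x = 40, y = 60, weight = cfg@nInits)
  bf <- bruteForceSmooth(pinnedModes, cfg)
  expect_identical(fixed$selected, bf$selected)
  # out-of-range and out-of-bounds corrections error
  expect_error(applyCorrections(modes, data.frame(frame = 99, x_px = 1, y_px = 1), cfg),
               "outside the tracked range")
  expect_error(applyCorrections(modes, data.frame(frame = 1, x_px = 1e4, y_px = 1), cfg),
               "outside the image")
})

test_that("multi-pass tracking is deterministic under a fixed seed", {
  tk <- smallTracker()
  frames <- tk$train$frames[1:6]
  r1 <- trackFrames(frames, tk$model, trackConfig(), seed = 77)
  r2 <- trackFrames(frames, tk$model, trackConfig(), seed = 77)
  expect_identical(r1$track, r2$track)
})
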