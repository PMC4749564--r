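# Trajectory statistics: targets, matched controls, deviation/divergence,
# arc-length alignment, NN balanced accuracy, grab error, test contracts.

trialWithTraj <- function(pos, epochRows, ...) {
  makeTrial(epochRows, traj = pos, ...)
}

constantTraj <- function(n, p) matrix(rep(p, each = n), n, 3)

test_that("target inference recovers shared epoch-start positions", {
  p <- c(10, 15, -5); m <- c(2, 5, 8)
  rows <- canonicalRows(250, step = 40)
  trials <- lapply(1:5, function(i) {
    traj <- constantTraj(600, c(0, 0, 0))
    traj[331:600, ] <- constantTraj(270, p)   # Grab starts at frame 330
    traj[411:600, ] <- constantTraj(190, m)   # AtMouth starts at frame 410
    trialWithTraj(traj, rows, id = paste0("t", i))
  })
  for (est in c("mean", "median")) {
    tg <- inferTargets(trials, est)
    expect_equal(unname(tg$grabTarget), p)
    expect_equal(unname(tg$mouthTarget), m)
  }
  expect_error(inferTargets(list(makeTrial(NULL, outcome = "no_initiation"))),
               "no control trials")
})

test_that("median target estimation resists a gross outlier; mean is displaced", {
  kin <- reachKinematicsParams()
  set.seed(71)
  seeds <- sample.int(2^31 - 1, 20)
  trials <- lapply(seeds, function(s)
    simulateTrial(kin, seed = s, nFrames = 1400, cueFrame = 200))
  # corrupt one trial's Grab-start position by 60 mm
  bad <- trials[[1]]
  g <- epochs(bad)$start[epochs(bad)$label == "Grab"]
  bad@trajectory3d[g + 1, ] <- bad@trajectory3d[g + 1, ] + c(60, 0, 0)
  trials[[1]] <- bad
  tgMed <- inferTargets(trials, "median")
  tgMean <- inferTargets(trials, "mean")
  expect_lt(abs(tgMed$grabTarget[1] - kin@pelletPos[1]), 0.5)
  expect_gt(abs(tgMean$grabTarget[1] - kin@pelletPos[1]), 2)
})

test_that("grab target recovery scales with noise over control sessions", {
  kin <- reachKinematicsParams()
  set.seed(72)
  seeds <- sample.int(2^31 - 1, 40)
  trials <- lapply(seeds, function(s)
    simulateTrial(kin, seed = s, nFrames = 1400, cueFrame = 200))
  tg <- inferTargets(trials, "mean")
  tol <- 3 * kin@positionNoiseSD / sqrt(length(trials)) * sqrt(3) + 0.05
  expect_lt(sqrt(sum((tg$grabTarget - kin@pelletPos)^2)), tol + 0.2)
})

test_that("matched control intervals transplant the laser offsets", {
  rows <- canonicalRows(250, step = 40)
  # t = 0: laser exactly at the Lift start
  laser0 <- lapply(1:4, function(i)
    makeTrial(list(list("Lift", 250, 290)), laserOn = 250, laserOff = 1250,
              outcome = "failure", id = paste0("l", i)))
  ctrl <- lapply(1:6, function(i) makeTrial(rows, id = paste0("c", i)))
  mci <- matchedControlIntervals(ctrl, laser0, "Lift", seed = 3)
  expect_true(all(mci$t_frames == 0))
  expect_true(all(mci$start_frame == 250))
  # determinism
  expect_identical(mci, matchedControlIntervals(ctrl, laser0, "Lift", seed = 3))
  # controls lacking the epoch are skipped with a warning
  ctrl2 <- c(ctrl, list(makeTrial(NULL, outcome = "no_initiation", id = "c9")))
  expect_warning(mci2 <- matchedControlIntervals(ctrl2, laser0, "Lift", seed = 3),
                 "skipped")
  expect_identical(nrow(mci2), 6L)
})

test_that("assigned offsets reproduce the laser-trial t distribution", {
  # laser trials with t in {5, 10, 20}; many controls; chi-squared on counts
  mkLaser <- function(t, i) makeTrial(list(list("Lift", 300, 340)),
                                      laserOn = 300 + t, laserOff = 1300,
                                      outcome = "failure", id = paste0("l", t, i))
  laser <- c(lapply(1:2, function(i) mkLaser(5, i)),
             lapply(1:2, function(i) mkLaser(10, i)),
             lapply(1:2, function(i) mkLaser(20, i)))
  ctrl <- lapply(1:1000, function(i) makeTrial(canonicalRows(250), id = paste0("c", i)))
  mci <- matchedControlIntervals(ctrl, laser, "Lift", seed = 9)
  obs <- table(factor(mci$t_frames, levels = c(5, 10, 20)))
  chi <- suppressWarnings(chisq.test(obs, p = c(1, 1, 1) / 3))
  expect_gt(chi$p.value, 0.001)
})

test_that("deviation time course handles fixed and frozen hands", {
  target <- c(1, 2, 3)
  rows <- list(list("Lift", 100, 140))
  atT <- lapply(1:5, function(i)
    trialWithTraj(constantTraj(400, target), rows, id = paste0("a", i)))
  tc0 <- deviationTimecourse(atT, rep(100, 5), target, horizonMs = 200, preMs = 0)
  expect_true(all(tc0$median == 0))
  expect_true(all(tc0$q25 <= tc0$median & tc0$median <= tc0$q75))
  d <- sqrt(sum((target - c(1, 2, 10))^2))
  frozen <- lapply(1:5, function(i)
    trialWithTraj(constantTraj(400, c(1, 2, 10)), rows, id = paste0("f", i)))
  tc1 <- deviationTimecourse(frozen, rep(100, 5), target, horizonMs = 200, preMs = 0)
  expect_true(all(abs(tc1$median - d) < 1e-9))
  expect_warning(
    deviationTimecourse(frozen, rep(100, 5), target, horizonMs = 2000),
    "truncated")
})

test_that("divergence time is absent for identical courses, 0 for disjoint ones", {
  tc <- data.frame(time_ms = seq(-20, 100, 2), q25 = 1, median = 2, q75 = 3)
  expect_true(is.na(divergenceTime(tc, tc)))
  far <- transform(tc, q25 = 10, median = 11, q75 = 12)
  expect_equal(divergenceTime(tc, far), 0)
  off <- data.frame(time_ms = seq(0, 100, 2), q25 = 1, median = 2, q75 = 3)
  expect_error(divergenceTime(tc, off), "grids")
  # bands that touch do not count as disjoint; separation must be sustained
  blip <- far
  blip$q25[blip$time_ms == 50] <- 2       # momentary overlap at 50 ms
  expect_equal(divergenceTime(tc, blip), 52)
})

test_that("arc-length alignment is invariant to time reparameterization", {
  line <- cbind(seq(0, 9, length.out = 10), 0, 0)
  al <- alignByArclength(line, c(0, 1 / 3, 2 / 3, 1))
  expect_equal(al$positions[, 1], c(0, 3, 6, 9))
  fast <- line[c(1, 3, 5, 7, 9, 10), ]   # same path, varying speed
  al2 <- alignByArclength(fast, c(0, 1 / 3, 2 / 3, 1))
  expect_equal(al2$positions, al$positions, tolerance = 1e-9)
  expect_error(alignByArclength(constantTraj(5, c(1, 1, 1))), "zero total path")
  expect_error(alignByArclength(line[1, , drop = FALSE]), "at least 2")
  expect_error(alignByArclength(line, c(0, 0.8, 0.5, 1)), "strictly increasing")
})

test_that("alignment fractions are recovered on a dense random smooth path", {
  set.seed(73)
  t <- seq(0, 1, length.out = 2000)
  path <- cbind(sin(2 * t), cos(3 * t), t^2)
  al <- alignByArclength(path, c(0, 0.25, 0.5, 0.75, 1))
  # recompute the arc-length fraction of each returned checkpoint position
  steps <- sqrt(rowSums(diff(path)^2))
  arc <- c(0, cumsum(steps)); s <- arc / max(arc)
  for (j in 2:4) {
    i <- which.min(colSums((t(path) - al$positions[j, ])^2))
    expect_lt(abs(s[i] - al$fractions[j]), 1 / (2 * length(t)) + 1e-3)
  }
})

test_that("NN balanced accuracy separates offset groups and is symmetric", {
  set.seed(74)
  mkGroup <- function(n, center, spread) lapply(1:n, function(i)
    list(fractions = c(0, 0.5, 1),
         positions = matrix(rep(center, each = 3), 3, 3) +
           matrix(rnorm(9, 0, spread), 3, 3)))
  a <- mkGroup(10, c(0, 0, 0), 0.1)
  b <- mkGroup(10, c(10, 0, 0), 0.1)   # separated by 10x spread
  expect_equal(nnBalancedAccuracy(a, b, 2), 1)
  c1 <- mkGroup(15, c(0, 0, 0), 1)
  c2 <- mkGroup(8, c(0, 0, 0), 1)
  expect_equal(nnBalancedAccuracy(c1, c2, 2), nnBalancedAccuracy(c2, c1, 2))
  perm <- sample(15)
  expect_equal(nnBalancedAccuracy(c1[perm], c2, 2), nnBalancedAccuracy(c1, c2, 2))
  expect_error(nnBalancedAccuracy(a[1], b, 2), "at least 2")
})

test_that("grab error measures distance to the reference median grab position", {
  rows <- canonicalRows(250, step = 40)   # Grab starts at frame 330
  mk <- function(p, id) {
    traj <- constantTraj(600, p)
    trialWithTraj(traj, rows, id = id)
  }
  refs <- lapply(1:5, function(i) mk(c(10, 15, -5), paste0("r", i)))
  expect_equal(grabError(refs[1], refs)$distances_mm, 0)
  off <- mk(c(11, 15, -5), "o1")
  expect_equal(grabError(list(off), refs)$distances_mm, 1)
  expect_error(grabError(list(off), list(makeTrial(NULL, outcome = "no_initiation"))),
               "empty reference")
})

test_that("rank-sum matches full enumeration and handles degenerate input", {
  # oracle: all C(6,3) = 20 assignments of ranks to group A
  rankSumExact <- function(a, b) {
    ranks <- rank(c(a, b))
    w <- sum(ranks[seq_along(a)])
    combs <- combn(length(a) + length(b), length(a))
    ws <- apply(combs, 2, function(ix) sum(ranks[ix]))
    lo <- mean(ws <= w); hi <- mean(ws >= w)
    min(1, 2 * min(lo, hi))
  }
  expect_equal(rankSumExact(1:3, 4:6), 0.1)  # one-sided 1/20, two-sided 2/20
  r <- compareDistributions(1:3, 4:6, "rank_sum")
  expect_equal(r$p.value, 0.1)
  set.seed(75)
  for (i in 1:10) {
    a <- runif(sample(2:5, 1)); b <- runif(sample(2:5, 1))
    expect_equal(compareDistributions(a, b, "rank_sum")$p.value,
                 rankSumExact(a, b), tolerance = 1e-12)
  }
  expect_warning(r0 <- compareDistributions(rep(1, 5), rep(1, 4)), "degenerate")
  expect_equal(r0$p.value, 1)
  expect_error(compareDistributions(1, 1:5), "at least 2")
})

test_that("Welch test attains its nominal type-I rate under unequal variances", {
  set.seed(76)
  rej <- vapply(1:1000, function(i) {
    a <- rnorm(10, 0, 1); b <- rnorm(40, 0, 4)
    compareDistributions(a, b, "welch_t")$p.value < 0.05
  }, TRUE)
  ci <- 0.05 + c(-1, 1) * 2.6 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("chew during the laser window excludes pre-Grab laser trials", {
  frozen <- makeTrial(list(list("Lift", 250, 280)), laserOn = 260,
                      laserOff = 1260, outcome = "failure", id = "l1")
  notImpeded <- makeTrial(c(list(list("Lift", 250, 280), list("HandOpen", 280, 300),
                                 list("Grab", 300, 330), list("Supinate", 330, 360),
                                 list("AtMouth", 360, 420), list("Chew", 420, 900))),
                          laserOn = 260, laserOff = 1260, id = "l2")
  atMouth <- makeTrial(c(canonicalRows(250, step = 40)),
                       laserOn = 420, laserOff = 1000, id = "l3")
  kept <- filterImpededLaserTrials(list(frozen, notImpeded, atMouth))
  expect_identical(vapply(kept, function(t) t@trialId, ""), c("l1", "l3"))
})
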