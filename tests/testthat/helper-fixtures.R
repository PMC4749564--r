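# Shared fixtures, built in code. Heavy objects are cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# a trained small cascade + its scene, shared by the tracker unit tests
smallTracker <- function() {
  cached("smallTracker", function() {
    scene <- sceneParams()
    ts <- makeTrainingFrames(100, scene, seed = 401)
    model <- trainCascade(ts$frames, ts$labels, nStages = 60, nFerns = 50,
                          poolSize = 300, augPerFrame = 8, seed = 402)
    list(scene = scene, model = model, train = ts)
  })
}

# hand-built trial with an explicit ethogram (frames); slots are assigned
# directly so that deliberately invalid annotations can be constructed for
# validateTrial tests (the constructor itself enforces validity)
makeTrial <- function(epochRows, cue = 100, laserOn = NA, laserOff = NA,
                      outcome = "success", fps = 500, id = "t1",
                      animal = "animal1", traj = matrix(numeric(0), 0, 3)) {
  ep <- if (is.null(epochRows)) emptyEpochs() else
    do.call(rbind, lapply(epochRows, function(r)
      data.frame(label = r[[1]], start = as.numeric(r[[2]]),
                 end = as.numeric(r[[3]]))))
  tr <- trial(id, animal, fps = fps, cueFrame = cue,
              outcome = "no_initiation", trajectory3d = traj)
  tr@epochs <- ep
  tr@laserOnFrame <- as.numeric(laserOn)
  tr@laserOffFrame <- as.numeric(laserOff)
  tr@outcome <- outcome
  tr
}

# canonical full reach annotation starting at a given frame
canonicalRows <- function(liftStart = 250, step = 40) {
  labs <- canonicalEpochs()
  starts <- liftStart + step * (seq_along(labs) - 1)
  lapply(seq_along(labs), function(i) list(labs[i], starts[i], starts[i] + step))
}

# brute-force oracle for smoothTrack: enumerate all mode assignments
# (vectorized over the assignment grid so 1000 randomized instances are cheap)
bruteForceSmooth <- function(modesList, cfg) {
  nT <- length(modesList)
  counts <- vapply(modesList, nrow, 0L)
  grid <- as.matrix(do.call(expand.grid, lapply(counts, seq_len)))
  cost <- numeric(nrow(grid))
  for (t in seq_len(nT)) {
    m <- modesList[[t]]
    cost <- cost - log(pmax(m$weight[grid[, t]] / cfg@nInits, 1e-9))
    if (t > 1) {
      p <- modesList[[t - 1]]
      cost <- cost + cfg@smoothnessWeight *
        ((m$x[grid[, t]] - p$x[grid[, t - 1]])^2 +
         (m$y[grid[, t]] - p$y[grid[, t - 1]])^2)
    }
  }
  best <- which.min(cost)
  list(selected = as.integer(grid[best, ]), cost = cost[best])
}

# random candidate-mode lists for DP-vs-enumeration checks
randomModes <- function(nFrames, maxModes, nInits = 50) {
  lapply(seq_len(nFrames), function(t) {
    k <- sample.int(maxModes, 1)
    w <- sample.int(nInits, k, replace = TRUE)
    data.frame(x = runif(k, 0, 100), y = runif(k, 0, 100), weight = w)
  })
}
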