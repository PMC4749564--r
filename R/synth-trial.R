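## Synthetic trial generator: minimum-jerk multi-epoch reaches, optogenetic
## freezing with short latency, and rebound reaches after laser offset.

msToFrames <- function(ms, fps) ms * fps / 1000

framesToMs <- function(frames, fps) frames * 1000 / fps

#' Minimum-jerk position profile
#'
#' The standard smooth-reach model: normalized position along a straight
#' segment as a function of normalized time, with zero velocity and
#' acceleration at both ends.
#'
#' @param s Normalized time in `[0, 1]` (values outside are clamped).
#' @return Normalized displacement in `[0, 1]`.
#' @export
minimumJerk <- function(s) {
  s <- pmin(1, pmax(0, s))
  10 * s^3 - 15 * s^4 + 6 * s^5
}

#' Draw log-normal epoch durations with a given mean and CV
#' @noRd
.drawDurations <- function(means, cv) {
  if (cv <= 0) return(means)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(means) - sdlog^2 / 2
  setNames(rlnorm(length(means), meanlog, sdlog), names(means))
}

#' Piecewise minimum-jerk path through timed segments
#'
#' @param nFrames Total frames.
#' @param segments List of `list(start, end, from, to)` (frames, mm); segments
#'   must be ordered and non-overlapping. Outside segments the hand holds its
#'   last position (initial position = first segment's `from`).
#' @noRd
.buildPath <- function(nFrames, segments) {
  pos <- matrix(rep(segments[[1]]$from, each = nFrames), nFrames, 3)
  tIdx <- seq_len(nFrames) - 1
  for (sg in segments) {
    dur <- max(sg$end - sg$start, 1)
    inSeg <- tIdx >= sg$start & tIdx < sg$end
    s <- minimumJerk((tIdx[inSeg] - sg$start) / dur)
    pos[inSeg, ] <- outer(1 - s, sg$from) + outer(s, sg$to)
    after <- tIdx >= sg$end
    pos[after, ] <- matrix(rep(sg$to, each = sum(after)), ncol = 3)
  }
  pos
}

#' Contiguous canonical epoch schedule starting at a given time
#'
#' @return data.frame(label, start, end) in frames (absolute), durations drawn
#'   log-normal.
#' @noRd
.epochSchedule <- function(kin, startFrame, labels = canonicalEpochs()) {
  dMs <- .drawDurations(kin@epochDurationMeans[labels], kin@epochDurationCV)
  dFr <- pmax(1, round(msToFrames(dMs, kin@fps)))
  starts <- startFrame + c(0, cumsum(dFr))[seq_along(labels)]
  data.frame(label = labels, start = starts, end = starts + dFr,
             stringsAsFactors = FALSE)
}

#' Reach segments (straight minimum-jerk legs) implied by an epoch schedule
#' @noRd
.reachSegments <- function(sched, from, pellet, mouth) {
  segs <- list()
  firstLabel <- sched$label[1]
  pre <- intersect(c("Lift", "HandOpen"), sched$label)
  if (length(pre)) {
    grabStart <- sched$start[sched$label == "Grab"]
    segs <- c(segs, list(list(start = sched$start[1], end = grabStart,
                              from = from, to = pellet)))
    from <- pellet
  }
  if ("Supinate" %in% sched$label) {
    supStart <- sched$start[sched$label == "Supinate"]
    amStart <- sched$start[sched$label == "AtMouth"]
    segs <- c(segs, list(list(start = supStart, end = amStart,
                              from = from, to = mouth)))
  }
  segs
}

#' Simulate one prehension trial
#'
#' Generates the ethogram and 3D hand trajectory of a single cued trial. An
#' unperturbed trial lifts off the perch after a normally distributed reaction
#' time, reaches the pellet with a minimum-jerk profile over the
#' Lift/HandOpen phase, grabs, carries the pellet to the mouth over the
#' Supinate phase, and chews; per-axis Gaussian noise is added throughout.
#'
#' With a perturbation: if the laser window covers the would-be movement
#' onset, initiation is blocked for the duration of the laser; if the laser
#' starts during the reach (Lift through Supinate), the hand freezes after a
#' latency drawn uniformly from the configured range, its velocity decaying
#' exponentially (time constant 10 ms). In either case a rebound reach is
#' launched after laser offset with the duration-dependent probability, at a
#' latency drawn from the rebound latency distribution. Laser during AtMouth
#' or Chew has no kinematic effect.
#'
#' @param kin A [reachKinematicsParams()].
#' @param pert A [perturbationParams()], or `NULL` for a control trial.
#' @param seed Integer seed (all randomness in the trial derives from it).
#' @param nFrames Trial length, frames.
#' @param cueFrame Cue onset, frame (0-based).
#' @param trialId,animalId Identifiers.
#' @param pelletPresent Whether a pellet is presented (rebound trials in the
#'   dark-pellet condition use `FALSE`; chewing without a pellet is labeled
#'   `ChewNoPellet`).
#' @return A [trial()] with `trajectory3d` filled and generator ground truth
#'   in `meta` (`condition`, `firstLiftLatencyMs`, `freezeFrame`,
#'   `interruptedEpoch`, `rebounded`, `reboundLiftFrame`).
#' @export
simulateTrial <- function(kin, pert = NULL, seed = NULL, nFrames = 3500,
                          cueFrame = 500, trialId = "t1", animalId = "animal1",
                          pelletPresent = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  validObject(kin)
  fps <- kin@fps
  if (!is.null(pert)) {
    validObject(pert)
    laserOn <- pert@laserOnFrame
    laserOff <- laserOn + round(msToFrames(pert@laserDurationMs, fps))
    if (laserOn < 0 || laserOff > nFrames)
      stop("laser window lies outside the trial duration")
  } else {
    laserOn <- laserOff <- NA_real_
  }

  ## kinematic draws first (so a trial's latent schedule is identical with and
  ## without a perturbation under the same seed)
  latencyMs <- max(50, rnorm(1, kin@firstLiftLatencyMean, kin@firstLiftLatencySD))
  liftStart <- cueFrame + round(msToFrames(latencyMs, fps))
  sched <- .epochSchedule(kin, liftStart)

  meta <- list(condition = if (is.null(pert)) "control" else "laser",
               firstLiftLatencyMs = latencyMs, freezeFrame = NA_real_,
               interruptedEpoch = NA_character_, rebounded = NA,
               reboundLiftFrame = NA_real_)
  chewLabel <- if (pelletPresent) "Chew" else "ChewNoPellet"
  finalize <- function(sched, segs, outcome) {
    sched <- sched[sched$start < nFrames, , drop = FALSE]
    sched$end <- pmin(sched$end, nFrames)
    sched$label[sched$label == "Chew"] <- chewLabel
    pos <- .buildPath(nFrames, segs)
    pos <- pos + matrix(rnorm(3 * nFrames, 0, kin@positionNoiseSD), nFrames, 3)
    trial(trialId, animalId, fps = fps, cueFrame = cueFrame,
          laserOnFrame = laserOn, laserOffFrame = laserOff,
          pelletPresent = pelletPresent, epochs = sched, outcome = outcome,
          trajectory3d = pos, meta = meta)
  }

  if (is.null(pert) || liftStart >= laserOff) {
    ## control, or laser over before movement would begin: full reach
    segs <- .reachSegments(sched, kin@perchPos, kin@pelletPos, kin@mouthPos)
    return(finalize(sched, segs, "success"))
  }

  reboundDraw <- function() {
    rb <- runif(1) < reboundProbability(pert)
    lat <- if (rb) max(20, rnorm(1, pert@reboundLatencyMean, pert@reboundLatencySD)) else NA
    list(rebound = rb, latencyMs = lat)
  }

  if (liftStart >= laserOn) {
    ## suppression covers movement onset: initiation blocked
    meta$interruptedEpoch <- "none"
    rd <- reboundDraw()
    meta$rebounded <- rd$rebound
    if (!rd$rebound)
      return(finalize(emptyEpochs(), list(list(start = 0, end = 1,
             from = kin@perchPos, to = kin@perchPos)), "no_initiation"))
    rbLift <- laserOff + round(msToFrames(rd$latencyMs, fps))
    meta$reboundLiftFrame <- rbLift
    target <- kin@pelletPos + pert@reboundOffset
    sched2 <- .epochSchedule(kin, rbLift)
    segs <- .reachSegments(sched2, kin@perchPos, target, kin@mouthPos)
    outcome <- if (max(sched2$start[sched2$label == "AtMouth"]) < nFrames)
      "success" else "failure"
    return(finalize(sched2, segs, outcome))
  }

  ## laser starts mid-trial: find the epoch ongoing at laser onset
  started <- sched$label[sched$start <= laserOn]
  interrupted <- if (length(started)) tail(started, 1) else "none"
  meta$interruptedEpoch <- interrupted

  segsClean <- .reachSegments(sched, kin@perchPos, kin@pelletPos, kin@mouthPos)
  if (interrupted %in% c("AtMouth", "Chew")) {
    ## chewing and mouth-holding are unaffected by cortical suppression
    return(finalize(sched, segsClean, "success"))
  }

  ## freeze after a short latency; velocity decays exponentially
  freezeLatMs <- runif(1, pert@freezeLatencyRange[1], pert@freezeLatencyRange[2])
  freezeFrame <- laserOn + round(msToFrames(freezeLatMs, fps))
  meta$freezeFrame <- freezeFrame
  clean <- .buildPath(nFrames, segsClean)
  amStart <- sched$start[sched$label == "AtMouth"]
  if (freezeFrame >= amStart) {
    ## movement complete before the freeze takes hold
    return(finalize(sched, segsClean, "success"))
  }
  tauFr <- msToFrames(10, fps)  # 10 ms velocity decay time constant
  i0 <- freezeFrame + 1         # 1-based row of the freeze frame
  v <- clean[min(i0 + 1, nFrames), ] - clean[i0, ]
  pos <- clean
  tAfter <- seq_len(nFrames) - i0
  sel <- tAfter > 0
  decay <- 1 - exp(-tAfter[sel] / tauFr)
  pos[sel, ] <- matrix(rep(clean[i0, ], each = sum(sel)), ncol = 3) +
    outer(decay, v * tauFr)
  pFrozen <- clean[i0, ] + v * tauFr

  schedCut <- sched[sched$start < freezeFrame, , drop = FALSE]
  schedCut$end <- pmin(schedCut$end, freezeFrame)

  rd <- reboundDraw()
  meta$rebounded <- rd$rebound
  retracted <- runif(1) < pert@retractionProbability
  if (retracted && laserOff - freezeFrame > msToFrames(500, fps)) {
    ## prolonged suppression: limb drifts to a characteristic mid-air point
    rStart <- freezeFrame + round(msToFrames(250, fps))
    rEnd <- rStart + round(msToFrames(300, fps))
    midair <- (kin@perchPos + kin@pelletPos) / 2 + c(0, 0, 3)
    pos <- .overlayPath(pos, list(list(start = rStart, end = rEnd,
                                       from = pFrozen, to = midair)))
    pFrozen <- midair
  }

  if (!rd$rebound) {
    return(.finalizeWithPath(schedCut, pos, "failure", kin, meta,
                             trialId, animalId, fps, cueFrame, laserOn, laserOff,
                             pelletPresent, chewLabel, nFrames))
  }

  ## rebound: resume the remaining sequence from the frozen position
  rbLift <- laserOff + round(msToFrames(rd$latencyMs, fps))
  meta$reboundLiftFrame <- rbLift
  remaining <- canonicalEpochs()[seq(match(interrupted, canonicalEpochs()),
                                     length(canonicalEpochs()))]
  sched2 <- .epochSchedule(kin, rbLift, labels = remaining)
  target <- kin@pelletPos + pert@reboundOffset
  segs2 <- if (any(c("Lift", "HandOpen") %in% remaining)) {
    .reachSegments(sched2, pFrozen, target, kin@mouthPos)
  } else if ("Grab" %in% remaining) {
    grabEnd <- sched2$end[sched2$label == "Grab"]
    c(list(list(start = sched2$start[1], end = grabEnd, from = pFrozen, to = target)),
      .reachSegments(sched2[sched2$label != "Grab", , drop = FALSE],
                     target, target, kin@mouthPos))
  } else {
    amStart2 <- sched2$start[sched2$label == "AtMouth"]
    list(list(start = sched2$start[1], end = amStart2,
              from = pFrozen, to = kin@mouthPos))
  }
  pos <- .overlayPath(pos, segs2)
  schedAll <- rbind(schedCut, sched2)
  outcome <- if (any(schedAll$label == "AtMouth") &&
                 min(schedAll$start[schedAll$label == "AtMouth"]) < nFrames)
    "success" else "failure"
  .finalizeWithPath(schedAll, pos, outcome, kin, meta, trialId,
                    animalId, fps, cueFrame, laserOn, laserOff, pelletPresent,
                    chewLabel, nFrames)
}

#' Overlay minimum-jerk segments on an existing path (holds after last segment)
#' @noRd
.overlayPath <- function(pos, segments) {
  nFrames <- nrow(pos)
  tIdx <- seq_len(nFrames) - 1
  for (sg in segments) {
    dur <- max(sg$end - sg$start, 1)
    inSeg <- tIdx >= sg$start & tIdx < sg$end
    s <- minimumJerk((tIdx[inSeg] - sg$start) / dur)
    pos[inSeg, ] <- outer(1 - s, sg$from) + outer(s, sg$to)
    after <- tIdx >= sg$end
    pos[after, ] <- matrix(rep(sg$to, each = sum(after)), ncol = 3)
  }
  pos
}

#' Build a Trial from an explicit (already perturbed) path
#' @noRd
.finalizeWithPath <- function(sched, pos, outcome, kin, meta, trialId,
                              animalId, fps, cueFrame, laserOn, laserOff,
                              pelletPresent, chewLabel, nFrames) {
  sched <- sched[sched$start < nFrames, , drop = FALSE]
  sched$end <- pmin(sched$end, nFrames)
  sched$label[sched$label == "Chew"] <- chewLabel
  pos <- pos + matrix(rnorm(3 * nFrames, 0, kin@positionNoiseSD), nFrames, 3)
  meta$trajectoryOverride <- NULL
  trial(trialId, animalId, fps = fps, cueFrame = cueFrame,
        laserOnFrame = laserOn, laserOffFrame = laserOff,
        pelletPresent = pelletPresent, epochs = sched, outcome = outcome,
        trajectory3d = pos, meta = meta)
}

#' Simulate a behavioral session
#'
#' Generates a sequence of trials with laser trials randomly interspersed at
#' the configured fraction (default 20%, matching the experimental sessions).
#' Laser onset is placed either at the cue (blocking initiation) or at a fixed
#' offset after the trial's own first Lift (interrupting the reach); the
#' latter uses the fact that a trial's latent kinematic schedule is a
#' deterministic function of its seed, so the laser can be timed against the
#' schedule the trial would have produced.
#'
#' @param nTrials Number of trials.
#' @param kin A [reachKinematicsParams()].
#' @param laserFraction Fraction of laser trials (0 for a pure control
#'   session).
#' @param laserDurationMs Laser duration, ms.
#' @param laserAlign `"cue"` (laser from the cue) or `"afterLift"` (laser
#'   `laserOffsetMs` after the first Lift).
#' @param laserOffsetMs Laser onset relative to first Lift for
#'   `laserAlign = "afterLift"`, ms.
#' @param pertArgs Extra arguments passed to [perturbationParams()].
#' @param seed Integer seed.
#' @param nFrames,cueFrame,animalId,pelletPresent Passed to [simulateTrial()].
#' @return List of [trial()] objects.
#' @export
simulateSession <- function(nTrials, kin, laserFraction = 0.2,
                            laserDurationMs = 2000,
                            laserAlign = c("cue", "afterLift"),
                            laserOffsetMs = 40, pertArgs = list(),
                            seed = 1, nFrames = 3500, cueFrame = 500,
                            animalId = "animal1", pelletPresent = TRUE) {
  laserAlign <- match.arg(laserAlign)
  set.seed(seed)
  isLaser <- runif(nTrials) < laserFraction
  trialSeeds <- sample.int(.Machine$integer.max, nTrials)
  lapply(seq_len(nTrials), function(i) {
    id <- sprintf("t%03d", i)
    if (!isLaser[i]) {
      return(simulateTrial(kin, NULL, seed = trialSeeds[i], nFrames = nFrames,
                           cueFrame = cueFrame, trialId = id,
                           animalId = animalId, pelletPresent = pelletPresent))
    }
    laserOn <- if (laserAlign == "cue") {
      cueFrame
    } else {
      latent <- simulateTrial(kin, NULL, seed = trialSeeds[i], nFrames = nFrames,
                              cueFrame = cueFrame, trialId = id,
                              animalId = animalId, pelletPresent = pelletPresent)
      lift <- latent@epochs$start[latent@epochs$label == "Lift"][1]
      lift + round(msToFrames(laserOffsetMs, kin@fps))
    }
    pert <- do.call(perturbationParams,
                    c(list(laserOnFrame = laserOn,
                           laserDurationMs = laserDurationMs), pertArgs))
    simulateTrial(kin, pert, seed = trialSeeds[i], nFrames = nFrames,
                  cueFrame = cueFrame, trialId = id, animalId = animalId,
                  pelletPresent = pelletPresent)
  })
}
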