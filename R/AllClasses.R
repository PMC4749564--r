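#' @import methods
#' @importFrom stats approx median quantile rnorm runif rpois rlnorm sd setNames
#'   optim wilcox.test t.test ansari.test pnorm complete.cases dist
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib prehensr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Canonical prehension epoch order
#'
#' The six sequential components of the head-fixed prehension behavior, in the
#' order they occur in a complete reach: lift hand from perch, open hand while
#' reaching, grab pellet, supinate hand, bring hand to mouth, chew.
#'
#' @return Character vector of the six canonical epoch labels.
#' @export
canonicalEpochs <- function() {
  c("Lift", "HandOpen", "Grab", "Supinate", "AtMouth", "Chew")
}

.epochLabels <- function() {
  c(canonicalEpochs(), "ChewNoPellet", "Lick", "Groom")
}

## ---------------------------------------------------------------------------
## Camera geometry
## ---------------------------------------------------------------------------

#' @rdname cameraModel
#' @export
setClass("CameraModel",
  representation(
    fx = "numeric", fy = "numeric", cx = "numeric", cy = "numeric",
    distortion = "numeric",   # radial (k1, k2)
    rotation = "matrix",      # world -> camera, 3x3 orthonormal
    translation = "numeric"   # mm, X_cam = R X_world + t
  )
)

setValidity("CameraModel", function(object) {
  msg <- character(0)
  if (length(object@fx) != 1 || object@fx <= 0) msg <- c(msg, "fx must be a single positive number")
  if (length(object@fy) != 1 || object@fy <= 0) msg <- c(msg, "fy must be a single positive number")
  if (length(object@distortion) != 2) msg <- c(msg, "distortion must be (k1, k2)")
  if (!all(dim(object@rotation) == c(3, 3))) msg <- c(msg, "rotation must be 3x3")
  else if (max(abs(crossprod(object@rotation) - diag(3))) > 1e-8)
    msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-8)")
  if (length(object@translation) != 3) msg <- c(msg, "translation must be a 3-vector")
  if (length(msg)) msg else TRUE
})

#' Pinhole camera model
#'
#' A calibrated pinhole camera with two-term radial distortion. World
#' coordinates are millimeters; pixel coordinates are 0-based with origin at
#' the top-left corner, x rightward and y downward. A world point `X` maps to
#' the camera frame as `R X + t` (depth along camera z), is distorted radially
#' in normalized coordinates, then scaled by the focal lengths and shifted by
#' the principal point.
#'
#' @param fx,fy Focal lengths in pixels (positive).
#' @param cx,cy Principal point in pixels.
#' @param distortion Radial distortion coefficients `c(k1, k2)`.
#' @param rotation 3x3 orthonormal world-to-camera rotation.
#' @param translation Camera translation (mm), `X_cam = R X_world + t`.
#' @return A `CameraModel` object.
#' @seealso [projectPoint()], [triangulate()], [defaultStereoRig()]
#' @export
cameraModel <- function(fx, fy, cx, cy, distortion = c(0, 0),
                        rotation = diag(3), translation = c(0, 0, 0)) {
  new("CameraModel", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy),
      distortion = as.numeric(distortion), rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname stereoRig
#' @export
setClass("StereoRig", representation(front = "CameraModel", side = "CameraModel"))

#' Optical axis of a camera in world coordinates
#' @noRd
.opticalAxis <- function(cam) as.numeric(t(cam@rotation) %*% c(0, 0, 1))

setValidity("StereoRig", function(object) {
  a <- .opticalAxis(object@front)
  b <- .opticalAxis(object@side)
  ang <- acos(min(1, max(-1, sum(a * b)))) * 180 / pi
  if (ang <= 1) "camera optical axes are near-parallel (angle must exceed 1 degree)" else TRUE
})

#' Two-camera stereo rig
#'
#' Pair of calibrated cameras viewing the behavior arena from (near)
#' perpendicular angles, one in front of the animal and one to its side.
#'
#' @param front,side `CameraModel` objects for the two views.
#' @return A `StereoRig` object.
#' @export
stereoRig <- function(front, side) new("StereoRig", front = front, side = side)

#' Default stereo rig for the synthetic arena
#'
#' Two perpendicular cameras at a 200 mm working distance, focal length
#' 1400 px, principal point at the image center of a 352 x 260 frame, no
#' distortion. The world frame is right-handed in millimeters with its origin
#' at the perch: x to the animal's right, y forward (toward the front camera),
#' z up. The front camera looks along -y, the side camera along -x.
#'
#' @param workingDistance Camera distance from the perch origin, mm.
#' @param f Focal length, px.
#' @return A `StereoRig`.
#' @export
defaultStereoRig <- function(workingDistance = 200, f = 1400) {
  Rf <- rbind(c(-1, 0, 0), c(0, 0, -1), c(0, -1, 0))  # front: z_cam = -y world
  Rs <- rbind(c(0, 1, 0), c(0, 0, -1), c(-1, 0, 0))   # side:  z_cam = -x world
  front <- cameraModel(f, f, 176, 130, rotation = Rf,
                       translation = as.numeric(-Rf %*% c(0, workingDistance, 0)))
  side <- cameraModel(f, f, 176, 130, rotation = Rs,
                      translation = as.numeric(-Rs %*% c(workingDistance, 0, 0)))
  stereoRig(front, side)
}

## ---------------------------------------------------------------------------
## Synthetic-generator parameter bundles
## ---------------------------------------------------------------------------

#' @rdname reachKinematicsParams
#' @export
setClass("ReachKinematicsParams",
  representation(
    perchPos = "numeric", pelletPos = "numeric", mouthPos = "numeric",
    epochDurationMeans = "numeric", epochDurationCV = "numeric",
    positionNoiseSD = "numeric", fps = "numeric",
    firstLiftLatencyMean = "numeric", firstLiftLatencySD = "numeric"
  )
)

setValidity("ReachKinematicsParams", function(object) {
  msg <- character(0)
  for (s in c("perchPos", "pelletPos", "mouthPos"))
    if (length(slot(object, s)) != 3 || any(!is.finite(slot(object, s))))
      msg <- c(msg, paste(s, "must be a finite 3-vector (mm)"))
  pts <- rbind(object@perchPos, object@pelletPos, object@mouthPos)
  if (nrow(unique(pts)) < 3) msg <- c(msg, "perch, pellet and mouth positions must be pairwise distinct")
  if (any(object@epochDurationMeans <= 0)) msg <- c(msg, "epoch duration means must be positive")
  if (!all(canonicalEpochs() %in% names(object@epochDurationMeans)))
    msg <- c(msg, "epochDurationMeans must name all six canonical epochs")
  if (object@epochDurationCV < 0) msg <- c(msg, "epochDurationCV must be non-negative")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (object@firstLiftLatencyMean <= 0 || object@firstLiftLatencySD < 0)
    msg <- c(msg, "first-lift latency mean must be positive and SD non-negative")
  if (length(msg)) msg else TRUE
})

#' Reach kinematics parameters for the trial generator
#'
#' Describes the geometry and timing of an unperturbed cued reach: the three
#' waypoints (perch, pellet, mouth) in world millimeters, mean durations of
#' the six canonical epochs, the coefficient of variation of those durations
#' (epoch durations are drawn log-normal), additive Gaussian position noise,
#' the video frame rate, and the cue-to-first-lift reaction-time distribution.
#'
#' Defaults emulate a well-trained head-fixed mouse: a ~19 mm perch-to-pellet
#' reach completed in roughly 200 ms, retrieval to the mouth in a further
#' ~230 ms, tightly stereotyped timing (CV 0.12), and a cued reaction time of
#' 300 +/- 80 ms.
#'
#' @param perchPos,pelletPos,mouthPos Waypoints, mm (3-vectors).
#' @param epochDurationMeans Named vector of mean epoch durations, ms; must
#'   name all of `canonicalEpochs()`.
#' @param epochDurationCV Coefficient of variation of epoch durations.
#' @param positionNoiseSD Per-axis Gaussian position noise, mm.
#' @param fps Video frame rate, frames/s.
#' @param firstLiftLatencyMean,firstLiftLatencySD Cue-to-first-lift latency
#'   distribution (normal), ms.
#' @return A `ReachKinematicsParams` object.
#' @export
reachKinematicsParams <- function(perchPos = c(0, 0, 0),
                                  pelletPos = c(10, 15, -5),
                                  mouthPos = c(2, 5, 8),
                                  epochDurationMeans = c(Lift = 80, HandOpen = 60,
                                                         Grab = 70, Supinate = 80,
                                                         AtMouth = 150, Chew = 800),
                                  epochDurationCV = 0.12,
                                  positionNoiseSD = 0.15,
                                  fps = 500,
                                  firstLiftLatencyMean = 300,
                                  firstLiftLatencySD = 80) {
  new("ReachKinematicsParams", perchPos = as.numeric(perchPos),
      pelletPos = as.numeric(pelletPos), mouthPos = as.numeric(mouthPos),
      epochDurationMeans = epochDurationMeans, epochDurationCV = epochDurationCV,
      positionNoiseSD = positionNoiseSD, fps = fps,
      firstLiftLatencyMean = firstLiftLatencyMean,
      firstLiftLatencySD = firstLiftLatencySD)
}

#' @rdname perturbationParams
#' @export
setClass("PerturbationParams",
  representation(
    laserOnFrame = "numeric", laserDurationMs = "numeric",
    freezeLatencyRange = "numeric", retractionProbability = "numeric",
    reboundProbVsDuration = "numeric",
    reboundLatencyMean = "numeric", reboundLatencySD = "numeric",
    reboundOffset = "numeric"
  )
)

setValidity("PerturbationParams", function(object) {
  msg <- character(0)
  if (length(object@freezeLatencyRange) != 2 ||
      object@freezeLatencyRange[1] > object@freezeLatencyRange[2])
    msg <- c(msg, "freezeLatencyRange must be an ordered (low, high) pair in ms")
  probs <- c(object@retractionProbability, object@reboundProbVsDuration)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@laserDurationMs <= 0) msg <- c(msg, "laserDurationMs must be positive")
  if (length(object@reboundOffset) != 3) msg <- c(msg, "reboundOffset must be a 3-vector (mm)")
  if (is.null(names(object@reboundProbVsDuration)) &&
      length(object@reboundProbVsDuration) > 1)
    msg <- c(msg, "reboundProbVsDuration must be named by laser duration (ms)")
  if (length(msg)) msg else TRUE
})

#' Optogenetic perturbation parameters for the trial generator
#'
#' Describes a laser epoch and its behavioral consequences: if cortical
#' suppression starts while a reach is in progress the hand freezes after a
#' latency drawn uniformly from `freezeLatencyRange` (default 72-170 ms, the
#' observed range for a representative animal); if suppression covers the
#' would-be movement onset, initiation is blocked. At laser offset a rebound
#' reach is launched with a probability that grows with laser duration, after
#' a latency drawn from a normal distribution that is shorter and less
#' variable than the cued reaction time.
#'
#' @param laserOnFrame Laser onset, frame index (0-based).
#' @param laserDurationMs Laser duration, ms.
#' @param freezeLatencyRange Uniform range for the laser-to-freeze latency, ms.
#' @param retractionProbability Probability that prolonged suppression drives
#'   the frozen limb back to a mid-air rest point (disabled by default).
#' @param reboundProbVsDuration Named vector mapping laser duration (ms) to
#'   rebound probability; probabilities are interpolated between named
#'   durations and clamped outside the named range.
#' @param reboundLatencyMean,reboundLatencySD Laser-offset-to-rebound-lift
#'   latency distribution (normal), ms.
#' @param reboundOffset Systematic offset added to the rebound grab target, mm.
#' @return A `PerturbationParams` object.
#' @export
perturbationParams <- function(laserOnFrame,
                               laserDurationMs = 2000,
                               freezeLatencyRange = c(72, 170),
                               retractionProbability = 0,
                               reboundProbVsDuration = c("100" = 0.05, "500" = 0.3,
                                                         "1000" = 0.6, "2000" = 0.85,
                                                         "4000" = 0.95),
                               reboundLatencyMean = 150,
                               reboundLatencySD = 40,
                               reboundOffset = c(0, 0, 0)) {
  new("PerturbationParams", laserOnFrame = as.numeric(laserOnFrame),
      laserDurationMs = as.numeric(laserDurationMs),
      freezeLatencyRange = as.numeric(freezeLatencyRange),
      retractionProbability = retractionProbability,
      reboundProbVsDuration = reboundProbVsDuration,
      reboundLatencyMean = reboundLatencyMean, reboundLatencySD = reboundLatencySD,
      reboundOffset = as.numeric(reboundOffset))
}

#' Rebound probability for a given laser duration
#'
#' Linear interpolation of the configured duration-to-probability map, clamped
#' at the ends of the named duration range.
#'
#' @param pert A `PerturbationParams` object.
#' @param durationMs Laser duration, ms.
#' @return Probability in `[0, 1]`.
#' @export
reboundProbability <- function(pert, durationMs = pert@laserDurationMs) {
  p <- pert@reboundProbVsDuration
  if (length(p) == 0) return(0)
  if (length(p) == 1) return(unname(p))
  d <- as.numeric(names(p))
  o <- order(d)
  approx(d[o], p[o], xout = durationMs, rule = 2)$y
}

#' @rdname sceneParams
#' @export
setClass("SceneParams",
  representation(
    imageSize = "numeric", blobSigma = "numeric", blobAmplitude = "numeric",
    backgroundNoiseSD = "numeric", cameras = "StereoRig"
  )
)

setValidity("SceneParams", function(object) {
  msg <- character(0)
  if (length(object@imageSize) != 2 || any(object@imageSize < 1))
    msg <- c(msg, "imageSize must be positive (width, height) in px")
  if (object@blobSigma <= 0) msg <- c(msg, "blobSigma must be positive")
  if (object@backgroundNoiseSD < 0) msg <- c(msg, "backgroundNoiseSD must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Rendering parameters for synthetic stereo video
#'
#' The synthetic scene renders the hand as an isotropic Gaussian intensity
#' blob at its projected position in each view, over a flat background with
#' i.i.d. Gaussian noise. Frame geometry defaults to the acquisition format of
#' the behavioral videos: 352 x 260 px single-channel frames.
#'
#' @param imageSize Frame size `c(width, height)`, px.
#' @param blobSigma Hand blob standard deviation, px.
#' @param blobAmplitude Peak blob intensity.
#' @param backgroundNoiseSD Background noise SD (intensity units).
#' @param cameras A `StereoRig` used for projection.
#' @return A `SceneParams` object.
#' @export
sceneParams <- function(imageSize = c(352, 260), blobSigma = 6,
                        blobAmplitude = 1, backgroundNoiseSD = 0.02,
                        cameras = defaultStereoRig()) {
  new("SceneParams", imageSize = as.numeric(imageSize), blobSigma = blobSigma,
      blobAmplitude = blobAmplitude, backgroundNoiseSD = backgroundNoiseSD,
      cameras = cameras)
}

#' @rdname spikeSimParams
#' @export
setClass("SpikeSimParams",
  representation(
    baselineRate = "numeric", suppressionFraction = "numeric",
    reboundGain = "numeric", reboundDurationMs = "numeric",
    laserWindow = "numeric", trialDuration = "numeric", nTrials = "numeric"
  )
)

setValidity("SpikeSimParams", function(object) {
  msg <- character(0)
  if (object@baselineRate < 0) msg <- c(msg, "baselineRate must be non-negative")
  if (object@suppressionFraction < 0 || object@suppressionFraction > 1)
    msg <- c(msg, "suppressionFraction must lie in [0, 1]")
  if (object@reboundGain < 0) msg <- c(msg, "reboundGain must be non-negative")
  if (length(object@laserWindow) == 2 && !any(is.na(object@laserWindow)) &&
      object@laserWindow[1] >= object@laserWindow[2])
    msg <- c(msg, "laserWindow must be ordered (on, off) in seconds")
  if (object@trialDuration <= 0) msg <- c(msg, "trialDuration must be positive")
  if (object@nTrials < 1) msg <- c(msg, "nTrials must be at least 1")
  if (length(msg)) msg else TRUE
})

#' Spike-train simulation parameters
#'
#' Inhomogeneous-Poisson model of a cortical unit during photostimulation of
#' inhibitory interneurons: firing at `baselineRate` outside the laser window,
#' suppressed to `baselineRate * (1 - suppressionFraction)` during the laser,
#' and elevated to `baselineRate * reboundGain` for `reboundDurationMs` after
#' laser offset (rebound spiking).
#'
#' @param baselineRate Baseline firing rate, Hz.
#' @param suppressionFraction Fractional rate suppression during the laser.
#' @param reboundGain Multiplicative rate gain during the rebound window.
#' @param reboundDurationMs Rebound window duration after laser offset, ms.
#' @param laserWindow Laser `c(on, off)` times, s; `c(NA, NA)` for no laser.
#' @param trialDuration Trial duration, s.
#' @param nTrials Number of trials to simulate.
#' @return A `SpikeSimParams` object.
#' @export
spikeSimParams <- function(baselineRate = 10, suppressionFraction = 0.9,
                           reboundGain = 3, reboundDurationMs = 300,
                           laserWindow = c(1, 3), trialDuration = 6,
                           nTrials = 100) {
  new("SpikeSimParams", baselineRate = baselineRate,
      suppressionFraction = suppressionFraction, reboundGain = reboundGain,
      reboundDurationMs = reboundDurationMs, laserWindow = as.numeric(laserWindow),
      trialDuration = trialDuration, nTrials = as.numeric(nTrials))
}

## ---------------------------------------------------------------------------
## Trials
## ---------------------------------------------------------------------------

#' @rdname trial
#' @export
setClass("Trial",
  representation(
    trialId = "character", animalId = "character", fps = "numeric",
    cueFrame = "numeric", laserOnFrame = "numeric", laserOffFrame = "numeric",
    pelletPresent = "logical", epochs = "data.frame", outcome = "character",
    trajectory3d = "matrix", meta = "list"
  )
)

setValidity("Trial", function(object) {
  v <- validateTrial(object)
  if (length(v)) paste(v, collapse = "; ") else TRUE
})

#' A single behavioral trial
#'
#' One trial of the cued prehension task: event frames (cue, laser on/off),
#' pellet availability, the annotated ethogram (a data frame of epoch
#' intervals), the trial outcome, and optionally the 3D hand trajectory.
#' Frames are 0-based; epoch intervals are half-open `[start, end)`.
#'
#' @param trialId,animalId Identifiers.
#' @param fps Video frame rate, frames/s.
#' @param cueFrame Auditory cue frame, or `NA` if uncued.
#' @param laserOnFrame,laserOffFrame Laser window frames, or `NA` for control
#'   trials.
#' @param pelletPresent Whether a pellet was presented.
#' @param epochs Data frame with columns `label`, `start`, `end` (frames).
#' @param outcome One of `"success"`, `"failure"`, `"no_initiation"`.
#' @param trajectory3d Optional `nFrames x 3` matrix of hand positions, mm.
#' @param meta Free-form list of provenance metadata (e.g. generator ground
#'   truth).
#' @return A `Trial` object.
#' @seealso [validateTrial()], [intervalStats()], [simulateTrial()]
#' @export
trial <- function(trialId, animalId = "animal1", fps = 500, cueFrame = NA_real_,
                  laserOnFrame = NA_real_, laserOffFrame = NA_real_,
                  pelletPresent = TRUE, epochs = emptyEpochs(),
                  outcome = c("success", "failure", "no_initiation"),
                  trajectory3d = matrix(numeric(0), 0, 3), meta = list()) {
  outcome <- match.arg(outcome)
  epochs$label <- as.character(epochs$label)
  new("Trial", trialId = as.character(trialId), animalId = as.character(animalId),
      fps = fps, cueFrame = as.numeric(cueFrame),
      laserOnFrame = as.numeric(laserOnFrame), laserOffFrame = as.numeric(laserOffFrame),
      pelletPresent = pelletPresent, epochs = epochs, outcome = outcome,
      trajectory3d = trajectory3d, meta = meta)
}

#' Empty epoch table
#' @return Zero-row data frame with columns `label`, `start`, `end`.
#' @export
emptyEpochs <- function() {
  data.frame(label = character(0), start = numeric(0), end = numeric(0),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Tracker
## ---------------------------------------------------------------------------

#' @rdname trackConfig
#' @export
setClass("TrackConfig",
  representation(
    nInits = "numeric", smoothnessWeight = "numeric", modeBandwidth = "numeric",
    errorSpreadThreshold = "numeric", jumpLimit = "numeric", nPasses = "numeric"
  )
)

setValidity("TrackConfig", function(object) {
  msg <- character(0)
  if (object@nInits < 1) msg <- c(msg, "nInits must be at least 1")
  if (object@smoothnessWeight < 0) msg <- c(msg, "smoothnessWeight must be non-negative")
  if (object@modeBandwidth <= 0) msg <- c(msg, "modeBandwidth must be positive")
  if (object@errorSpreadThreshold < 0 || object@errorSpreadThreshold > 1)
    msg <- c(msg, "errorSpreadThreshold must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Tracking configuration
#'
#' Controls test-time application of the cascade: the number of random
#' initializations per frame (default 50, the configuration used for the
#' behavioral videos), the smoothness weight of the dynamic-programming
#' trajectory selection, the mean-shift bandwidth used to cluster the final
#' pose estimates into candidate modes, and the error-flagging rules (a frame
#' is flagged when the fraction of initializations supporting the selected
#' mode falls below `errorSpreadThreshold`, or the frame-to-frame jump exceeds
#' `jumpLimit`).
#'
#' @param nInits Number of random initializations per frame.
#' @param smoothnessWeight Weight of the squared frame-to-frame displacement in
#'   the smoothing cost, px^-2 scale.
#' @param modeBandwidth Mean-shift kernel bandwidth, px.
#' @param errorSpreadThreshold Minimum weight fraction for an unflagged frame.
#' @param jumpLimit Maximum unflagged frame-to-frame jump, px.
#' @param nPasses Number of tracking passes (pass 2+ re-tracks flagged frames
#'   initialized from their smoothed neighbors).
#' @return A `TrackConfig` object.
#' @export
trackConfig <- function(nInits = 50, smoothnessWeight = 0.01, modeBandwidth = 5,
                        errorSpreadThreshold = 0.4, jumpLimit = 20, nPasses = 2) {
  new("TrackConfig", nInits = as.numeric(nInits), smoothnessWeight = smoothnessWeight,
      modeBandwidth = modeBandwidth, errorSpreadThreshold = errorSpreadThreshold,
      jumpLimit = jumpLimit, nPasses = as.numeric(nPasses))
}

#' @rdname trainCascade
#' @export
setClass("CascadeModel",
  representation(
    nStages = "numeric", nFerns = "numeric", fernDepth = "numeric",
    featureRadius = "numeric",
    offsets = "array",     # [4, depth, nFerns, nStages]: ax, ay, bx, by (px)
    thresholds = "array",  # [depth, nFerns, nStages]
    outputs = "array",     # [2, 2^depth, nFerns, nStages]: dx, dy (px)
    trainingMeta = "list"
  )
)

setValidity("CascadeModel", function(object) {
  msg <- character(0)
  if (object@nStages < 1) msg <- c(msg, "nStages must be at least 1")
  if (!all(is.finite(object@outputs))) msg <- c(msg, "all bin outputs must be finite")
  if (any(abs(object@offsets) > object@featureRadius + 1e-9))
    msg <- c(msg, "feature offsets must lie within featureRadius")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Ephys
## ---------------------------------------------------------------------------

#' @rdname psth
#' @export
setClass("Psth",
  representation(binEdges = "numeric", rates = "numeric", nTrials = "numeric")
)

setValidity("Psth", function(object) {
  msg <- character(0)
  if (any(diff(object@binEdges) <= 0)) msg <- c(msg, "bin edges must be strictly increasing")
  if (length(object@rates) != length(object@binEdges) - 1)
    msg <- c(msg, "rates must have one entry per bin")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname unitRecord
#' @export
setClass("UnitRecord",
  representation(unitId = "character", spikeTimes = "list",
                 meanWaveform = "numeric", sampleRate = "numeric")
)

setValidity("UnitRecord", function(object) {
  for (st in object@spikeTimes) {
    if (any(st < 0)) return("spike times must be non-negative")
    if (is.unsorted(st)) return("spike times must be sorted within trial")
  }
  TRUE
})

#' A recorded single unit
#'
#' Sorted spike times (one numeric vector per trial, seconds) together with
#' the unit's mean extracellular waveform, from which the trough-to-peak spike
#' width is computed for cell-type classification.
#'
#' @param unitId Identifier.
#' @param spikeTimes List of per-trial spike-time vectors, s, sorted.
#' @param meanWaveform Mean spike waveform samples (voltage).
#' @param sampleRate Waveform sampling rate, Hz.
#' @return A `UnitRecord` object.
#' @seealso [spikeWidth()], [classifyUnit()], [psth()]
#' @export
unitRecord <- function(unitId, spikeTimes, meanWaveform = numeric(0),
                       sampleRate = 19531.25) {
  new("UnitRecord", unitId = as.character(unitId), spikeTimes = spikeTimes,
      meanWaveform = as.numeric(meanWaveform), sampleRate = sampleRate)
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CameraModel", function(object) {
  cat("CameraModel: f = (", object@fx, ",", object@fy, ") px, c = (",
      object@cx, ",", object@cy, ") px, k = (",
      paste(object@distortion, collapse = ", "), ")\n")
})

setMethod("show", "StereoRig", function(object) {
  a <- .opticalAxis(object@front); b <- .opticalAxis(object@side)
  ang <- acos(min(1, max(-1, sum(a * b)))) * 180 / pi
  cat("StereoRig: front + side cameras, optical-axis angle",
      sprintf("%.1f", ang), "deg\n")
})

setMethod("show", "Trial", function(object) {
  cat("Trial", object@trialId, "(", object@animalId, "):", object@outcome,
      "|", nrow(object@epochs), "epochs",
      if (!is.na(object@laserOnFrame)) sprintf("| laser [%d, %d)",
        as.integer(object@laserOnFrame), as.integer(object@laserOffFrame)) else "",
      "\n")
})

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel:", object@nStages, "stages x", object@nFerns,
      "ferns (depth", object@fernDepth, "), feature radius",
      object@featureRadius, "px\n")
})

setMethod("show", "Psth", function(object) {
  cat("Psth:", length(object@rates), "bins over [",
      min(object@binEdges), ",", max(object@binEdges), "] s,",
      object@nTrials, "trials\n")
})

## ---------------------------------------------------------------------------
## Simple accessors
## ---------------------------------------------------------------------------

#' Accessors for trial components
#'
#' @param x A `Trial`.
#' @return `epochs()` the epoch interval table; `trajectory3d()` the 3D hand
#'   trajectory matrix (mm); `outcome()` the trial outcome; `trialFps()` the
#'   frame rate.
#' @name trial-accessors
NULL

#' @rdname trial-accessors
#' @export
epochs <- function(x) x@epochs

#' @rdname trial-accessors
#' @export
trajectory3d <- function(x) x@trajectory3d

#' @rdname trial-accessors
#' @export
outcome <- function(x) x@outcome

#' @rdname trial-accessors
#' @export
trialFps <- function(x) x@fps

#' PSTH accessors
#' @param x A `Psth`.
#' @return `psthRates()` the per-bin rates (Hz); `psthBinEdges()` the bin
#'   edges (s).
#' @name psth-accessors
NULL

#' @rdname psth-accessors
#' @export
psthRates <- function(x) x@rates

#' @rdname psth-accessors
#' @export
psthBinEdges <- function(x) x@binEdges
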