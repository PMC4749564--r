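## Synthetic stereo video: Gaussian hand blob over a noisy background,
## rendered through the calibrated cameras.

#' Render one synthetic frame
#'
#' A single grayscale frame containing a Gaussian blob centered at `center`
#' plus i.i.d. Gaussian background noise. Frames are `height x width` matrices
#' indexed `[y + 1, x + 1]` with 0-based pixel coordinates, origin top-left.
#'
#' @param center Blob center `c(x, y)`, px (may lie outside the frame).
#' @param scene A [sceneParams()].
#' @return Numeric `height x width` matrix.
#' @export
renderFrame <- function(center, scene) {
  w <- scene@imageSize[1]; h <- scene@imageSize[2]
  s2 <- 2 * scene@blobSigma^2
  gy <- exp(-((seq_len(h) - 1) - center[2])^2 / s2)
  gx <- exp(-((seq_len(w) - 1) - center[1])^2 / s2)
  img <- scene@blobAmplitude * (gy %o% gx)
  if (scene@backgroundNoiseSD > 0)
    img <- img + matrix(rnorm(h * w, 0, scene@backgroundNoiseSD), h, w)
  img
}

#' Render a trial as a stereo frame stack with ground-truth tracks
#'
#' Projects the trial's 3D hand trajectory through both cameras of the scene
#' and renders each frame as a Gaussian blob over background noise. Frames
#' where the hand projects outside the image bounds are still rendered (the
#' blob is simply clipped) and recorded as warnings.
#'
#' @param tr A [trial()] with `trajectory3d` filled.
#' @param scene A [sceneParams()].
#' @param seed Integer seed for the background noise.
#' @param frameRange Optional `c(first, last)` 0-based frame window to render
#'   (defaults to the whole trial; long trials are large, ~0.7 MB/frame/view).
#' @return List with `frames` (list `front`/`side` of frame-matrix lists),
#'   `tracks` (list `front`/`side` of `n x 2` ground-truth pixel tracks),
#'   `frameIndex` (0-based original frame numbers) and `outOfBounds`
#'   (data.frame view/frame of clipped projections).
#' @export
renderStereoVideo <- function(tr, scene, seed = NULL, frameRange = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traj <- tr@trajectory3d
  if (nrow(traj) == 0) stop("trial has no 3D trajectory")
  if (is.null(frameRange)) frameRange <- c(0, nrow(traj) - 1)
  idx <- seq(frameRange[1], frameRange[2]) + 1
  if (any(idx < 1 | idx > nrow(traj)))
    stop("frameRange outside trial trajectory")
  traj <- traj[idx, , drop = FALSE]
  rig <- scene@cameras
  tracks <- list(front = projectPoint(traj, rig@front),
                 side = projectPoint(traj, rig@side))
  w <- scene@imageSize[1]; h <- scene@imageSize[2]
  oob <- do.call(rbind, lapply(names(tracks), function(v) {
    tk <- tracks[[v]]
    bad <- which(tk[, 1] < 0 | tk[, 1] > w - 1 | tk[, 2] < 0 | tk[, 2] > h - 1)
    if (length(bad)) data.frame(view = v, frame = idx[bad] - 1) else NULL
  }))
  if (is.null(oob)) oob <- data.frame(view = character(0), frame = numeric(0))
  if (nrow(oob) > 0)
    warning(sprintf("%d frame projections fall outside the image bounds", nrow(oob)))
  frames <- lapply(tracks, function(tk)
    lapply(seq_len(nrow(tk)), function(i) renderFrame(tk[i, ], scene)))
  list(frames = frames, tracks = tracks, frameIndex = idx - 1, outOfBounds = oob)
}

#' Write a rendered stereo video to per-view PNG stacks
#'
#' Frames are written as zero-padded grayscale PNGs (`frame_000123.png`) in
#' `front/` and `side/` subdirectories; ground-truth tracks as per-view CSVs
#' (`frame, x_px, y_px`); seeds and geometry in a JSON sidecar manifest.
#'
#' @param video Output of [renderStereoVideo()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
writeFrameStacks <- function(video, dir, seed = NA) {
  for (v in names(video$frames)) {
    vd <- file.path(dir, v)
    dir.create(vd, recursive = TRUE, showWarnings = FALSE)
    fr <- video$frames[[v]]
    for (i in seq_along(fr)) {
      img <- pmin(pmax(fr[[i]], 0), 1)
      png::writePNG(img, file.path(vd, sprintf("frame_%06d.png", video$frameIndex[i])))
    }
    tk <- video$tracks[[v]]
    write.csv(data.frame(frame = video$frameIndex, x_px = tk[, 1], y_px = tk[, 2]),
              file.path(dir, paste0("track_", v, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(list(seed = seed, n_frames = length(video$frameIndex),
                            views = names(video$frames)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Build a labeled training set of synthetic frames
#'
#' Simulates control reaches, samples frames (biased toward movement so hand
#' positions cover the reach workspace in both views), renders each sampled
#' frame, and returns frames with their ground-truth hand labels -- the
#' synthetic stand-in for manually labeled video frames.
#'
#' @param nFrames Number of labeled frames to generate.
#' @param scene A [sceneParams()].
#' @param kin A [reachKinematicsParams()].
#' @param seed Integer seed.
#' @return List with `frames` (list of matrices) and `labels` (`n x 2` px).
#' @export
makeTrainingFrames <- function(nFrames, scene = sceneParams(),
                               kin = reachKinematicsParams(), seed = 1) {
  set.seed(seed)
  frames <- vector("list", nFrames)
  labels <- matrix(NA_real_, nFrames, 2)
  rig <- scene@cameras
  nTrials <- max(2, ceiling(nFrames / 40))
  trialSeeds <- sample.int(.Machine$integer.max, nTrials)
  pool <- NULL
  for (s in trialSeeds) {
    tr <- simulateTrial(kin, NULL, seed = s, nFrames = 1500, cueFrame = 100)
    ep <- tr@epochs
    moveFrames <- seq(max(0, ep$start[1] - 50),
                      min(nrow(tr@trajectory3d) - 1, ep$start[ep$label == "AtMouth"] + 100))
    pts <- tr@trajectory3d[moveFrames + 1, , drop = FALSE]
    pool <- rbind(pool, rbind(projectPoint(pts, rig@front),
                              projectPoint(pts, rig@side)))
  }
  pick <- sample.int(nrow(pool), nFrames, replace = nFrames > nrow(pool))
  for (i in seq_len(nFrames)) {
    labels[i, ] <- pool[pick[i], ]
    frames[[i]] <- renderFrame(labels[i, ], scene)
  }
  list(frames = frames, labels = labels)
}
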