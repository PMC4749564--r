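## Cascaded pose regression: test-time tracking. Many random initializations
## per frame, mean-shift mode finding on the final estimates, dynamic
## programming selection of a smooth trajectory, error-frame flagging and
## re-tracking, and manual corrections as hard constraints.

#' Mean-shift modes of a 2D point set
#'
#' @param pts `n x 2` matrix.
#' @param bandwidth Gaussian kernel bandwidth, px.
#' @return Data frame `x, y, weight` (weight = number of points converging to
#'   the mode), sorted by decreasing weight, ties broken by lowest `(y, x)`.
#' @export
meanShiftModes <- function(pts, bandwidth) {
  pts <- as.matrix(pts)
  cur <- pts
  for (it in 1:100) {
    d2 <- outer(cur[, 1], pts[, 1], "-")^2 + outer(cur[, 2], pts[, 2], "-")^2
    W <- exp(-d2 / (2 * bandwidth^2))
    nxt <- (W %*% pts) / rowSums(W)
    if (max(abs(nxt - cur)) < 1e-3) { cur <- nxt; break }
    cur <- nxt
  }
  modes <- matrix(numeric(0), 0, 2)
  assign <- integer(nrow(cur))
  for (i in seq_len(nrow(cur))) {
    if (nrow(modes) > 0) {
      d <- sqrt((modes[, 1] - cur[i, 1])^2 + (modes[, 2] - cur[i, 2])^2)
      j <- which.min(d)
    }
    if (nrow(modes) > 0 && d[j] < bandwidth / 2) {
      assign[i] <- j
    } else {
      modes <- rbind(modes, cur[i, ])
      assign[i] <- nrow(modes)
    }
  }
  out <- data.frame(
    x = vapply(seq_len(nrow(modes)), function(j) mean(cur[assign == j, 1]), 0),
    y = vapply(seq_len(nrow(modes)), function(j) mean(cur[assign == j, 2]), 0),
    weight = as.numeric(tabulate(assign, nrow(modes))))
  out[order(-out$weight, out$y, out$x), , drop = FALSE]
}

#' Track one frame: candidate hand-position modes
#'
#' Runs the cascade from `nInits` random initial poses drawn uniformly over
#' the frame, clusters the final estimates by mean shift, and returns the
#' resulting candidate modes sorted by weight. The weight fraction of the top
#' mode (`weight / nInits`) serves as the frame's confidence.
#'
#' @param image Grayscale `height x width` matrix.
#' @param model A trained `CascadeModel`.
#' @param cfg A [trackConfig()].
#' @param seed Integer seed for the initializations.
#' @param inits Optional `n x 2` matrix of initial poses overriding the
#'   uniform draw (used when re-tracking flagged frames from neighbors).
#' @return Data frame `x, y, weight`.
#' @export
trackFrame <- function(image, model, cfg = trackConfig(), seed = NULL,
                       inits = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- ncol(image); h <- nrow(image)
  if (is.null(inits)) {
    inits <- cbind(runif(cfg@nInits, 0, w - 1), runif(cfg@nInits, 0, h - 1))
  }
  finals <- .cprApplyCascade(image, inits, as.numeric(model@offsets),
                             as.numeric(model@thresholds),
                             as.numeric(model@outputs),
                             model@nStages, model@nFerns, model@fernDepth)
  meanShiftModes(finals, cfg@modeBandwidth)
}

#' Select a smooth trajectory through per-frame candidate modes
#'
#' Dynamic programming over one mode per frame, minimizing the summed cost
#' `-log(weight fraction) + lambda * ||p_t - p_(t-1)||^2`. Frames are flagged
#' as potential tracking errors when the selected mode's weight fraction falls
#' below `errorSpreadThreshold` or the frame-to-frame jump exceeds
#' `jumpLimit`. With `lambda = 0` the selection reduces to the independent
#' per-frame top mode.
#'
#' @param modesList List (one element per frame) of `x, y, weight` data frames
#'   from [trackFrame()].
#' @param cfg A [trackConfig()].
#' @param pinned Optional integer vector of 1-based frame indices treated as
#'   hard constraints (never flagged; their single candidate is kept).
#' @return List with `track` (data frame `frame, x_px, y_px, confidence,
#'   flagged`; frames 0-based) and `selected` (chosen mode index per frame).
#' @export
smoothTrack <- function(modesList, cfg = trackConfig(), pinned = integer(0)) {
  nT <- length(modesList)
  if (nT == 0) stop("empty mode list")
  if (any(vapply(modesList, nrow, 0L) == 0))
    stop("every frame needs at least one candidate mode")
  lam <- cfg@smoothnessWeight
  unary <- lapply(modesList, function(m)
    -log(pmax(m$weight / cfg@nInits, 1e-9)))
  cost <- unary[[1]]
  back <- vector("list", nT)
  for (t in seq_len(nT)[-1]) {
    a <- modesList[[t - 1]]; b <- modesList[[t]]
    d2 <- outer(b$x, a$x, "-")^2 + outer(b$y, a$y, "-")^2   # nb x na
    tot <- sweep(lam * d2, 2, cost, "+")
    back[[t]] <- max.col(-tot, ties.method = "first")
    cost <- unary[[t]] + tot[cbind(seq_len(nrow(b)), back[[t]])]
  }
  sel <- integer(nT)
  sel[nT] <- which.min(cost)
  if (nT > 1) for (t in seq(nT, 2)) sel[t - 1] <- back[[t]][sel[t]]
  xs <- vapply(seq_len(nT), function(t) modesList[[t]]$x[sel[t]], 0)
  ys <- vapply(seq_len(nT), function(t) modesList[[t]]$y[sel[t]], 0)
  conf <- vapply(seq_len(nT), function(t)
    min(1, modesList[[t]]$weight[sel[t]] / cfg@nInits), 0)
  jump <- c(0, sqrt(diff(xs)^2 + diff(ys)^2))
  flagged <- conf < cfg@errorSpreadThreshold | jump > cfg@jumpLimit
  flagged[pinned] <- FALSE
  list(track = data.frame(frame = seq_len(nT) - 1, x_px = xs, y_px = ys,
                          confidence = conf, flagged = flagged),
       selected = sel)
}

#' Track a whole video with multi-pass smoothing
#'
#' Pass 1 tracks every frame from uniform random initializations and selects
#' a smooth trajectory. Subsequent passes re-track flagged frames with
#' initializations concentrated around the position interpolated from their
#' unflagged neighbors, then re-run the smoothing.
#'
#' @param frames List of grayscale frame matrices.
#' @param model A trained `CascadeModel`.
#' @param cfg A [trackConfig()].
#' @param seed Integer seed.
#' @return List with `track` (as in [smoothTrack()]), `modes` (per-frame
#'   candidate lists), and `flaggedFrames` (0-based indices flagged in the
#'   final pass).
#' @export
trackFrames <- function(frames, model, cfg = trackConfig(), seed = 1) {
  set.seed(seed)
  frameSeeds <- sample.int(.Machine$integer.max, length(frames) * cfg@nPasses)
  modes <- lapply(seq_along(frames), function(i)
    trackFrame(frames[[i]], model, cfg, seed = frameSeeds[i]))
  sm <- smoothTrack(modes, cfg)
  pass <- 1
  while (pass < cfg@nPasses && any(sm$track$flagged)) {
    bad <- which(sm$track$flagged)
    good <- which(!sm$track$flagged)
    for (i in bad) {
      init <- if (length(good)) {
        c(approx(good, sm$track$x_px[good], xout = i, rule = 2)$y,
          approx(good, sm$track$y_px[good], xout = i, rule = 2)$y)
      } else c(sm$track$x_px[i], sm$track$y_px[i])
      set.seed(frameSeeds[pass * length(frames) + i])
      inits <- cbind(rnorm(cfg@nInits, init[1], 2 * cfg@modeBandwidth),
                     rnorm(cfg@nInits, init[2], 2 * cfg@modeBandwidth))
      modes[[i]] <- trackFrame(frames[[i]], model, cfg, inits = inits)
    }
    sm <- smoothTrack(modes, cfg)
    pass <- pass + 1
  }
  list(track = sm$track, modes = modes,
       flaggedFrames = sm$track$frame[sm$track$flagged])
}

#' Apply manual corrections to a tracked trajectory
#'
#' Corrected frames are pinned: their candidate set is replaced by the
#' user-supplied position with confidence 1, the smoothing is re-run with the
#' pins as hard constraints, and pinned frames are never flagged.
#'
#' @param modesList Per-frame candidate modes (from [trackFrames()]`$modes`).
#' @param corrections Data frame `frame, x_px, y_px` (frames 0-based).
#' @param cfg A [trackConfig()].
#' @param imageSize `c(width, height)` used to validate corrections, px.
#' @return As [smoothTrack()].
#' @export
applyCorrections <- function(modesList, corrections, cfg = trackConfig(),
                             imageSize = c(352, 260)) {
  if (NROW(corrections) == 0) return(smoothTrack(modesList, cfg))
  if (any(corrections$frame < 0 | corrections$frame >= length(modesList)))
    stop("correction frame outside the tracked range")
  if (any(corrections$x_px < 0 | corrections$x_px > imageSize[1] - 1 |
          corrections$y_px < 0 | corrections$y_px > imageSize[2] - 1))
    stop("correction outside the image bounds")
  pinned <- corrections$frame + 1L
  for (i in seq_len(nrow(corrections))) {
    modesList[[pinned[i]]] <- data.frame(x = corrections$x_px[i],
                                         y = corrections$y_px[i],
                                         weight = cfg@nInits)
  }
  smoothTrack(modesList, cfg, pinned = pinned)
}

#' Write/read tracked trajectories
#'
#' Trajectory CSV columns: `frame, x_px, y_px, confidence, flagged`; the
#' flagged-frame review list is written as JSON.
#'
#' @param track Track data frame (from [smoothTrack()] or [trackFrames()]).
#' @param path CSV path.
#' @param reviewPath Optional JSON path for the flagged-frame list.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path, reviewPath = NULL) {
  write.csv(track, path, row.names = FALSE)
  if (!is.null(reviewPath))
    jsonlite::write_json(list(flagged_frames = track$frame[track$flagged]),
                         reviewPath, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTrack
#' @export
readTrack <- function(path) read.csv(path)
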