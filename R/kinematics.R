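## Trajectory-level statistics comparing cued, laser-perturbed and rebound
## reaches: target inference, matched-control deviation time courses,
## IQR divergence time, arc-length alignment, nearest-neighbor balanced
## accuracy, grab end-point error, and the distribution-comparison contracts.

#' Hand position at the first frame of an epoch
#' @noRd
.positionAtEpochStart <- function(tr, label, finalSeq = TRUE) {
  ep <- if (finalSeq) finalSequence(tr) else tr@epochs
  s <- .firstStart(ep, label)
  if (is.na(s) || nrow(tr@trajectory3d) <= s) return(NULL)
  tr@trajectory3d[s + 1, ]
}

#' Infer grab and mouth targets from control trials
#'
#' The location of the pellet (grab target) and the mouth are estimated as the
#' per-axis mean (or median) of the hand position at the first frame of the
#' Grab and AtMouth epochs across cued control trials.
#'
#' @param controlTrials List of [trial()] objects with 3D trajectories.
#' @param estimator `"mean"` or `"median"`.
#' @return List with `grabTarget`, `mouthTarget` (3-vectors, mm), `estimator`
#'   and `nTrials`.
#' @export
inferTargets <- function(controlTrials, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  grabs <- do.call(rbind, lapply(controlTrials, .positionAtEpochStart, label = "Grab"))
  mouths <- do.call(rbind, lapply(controlTrials, .positionAtEpochStart, label = "AtMouth"))
  if (is.null(grabs) || is.null(mouths))
    stop("no control trials containing both Grab and AtMouth with trajectories")
  est <- if (estimator == "mean") colMeans else function(m) apply(m, 2, median)
  list(grabTarget = est(grabs), mouthTarget = est(mouths),
       estimator = estimator, nTrials = nrow(grabs))
}

#' Laser trials eligible for the distance-to-target analysis
#'
#' Implements the exclusion rule: for trials interrupted during Lift through
#' Supinate, the occurrence of a Chew epoch during the laser-on period shows
#' the behavior was not impeded, and the trial is dropped; for AtMouth and
#' Chew interruptions a lack of effect is not detectable and all trials are
#' kept.
#'
#' @param laserTrials List of laser [trial()] objects.
#' @return Filtered list.
#' @export
filterImpededLaserTrials <- function(laserTrials) {
  keep <- vapply(laserTrials, function(tr) {
    g <- epochAtLaserOnset(tr)
    if (!g %in% c("Lift", "HandOpen", "Grab", "Supinate")) return(TRUE)
    ep <- tr@epochs
    chew <- .labelMatches(ep$label, "Chew")
    !any(chew & ep$start < tr@laserOffFrame & ep$end > tr@laserOnFrame)
  }, TRUE)
  laserTrials[keep]
}

#' Matched control intervals for a laser-trial group
#'
#' Builds the control comparison set for a group of laser trials interrupted
#' during a given epoch. For each control trial, one laser trial is drawn
#' uniformly (seeded) and its offset `t` -- the time between the last
#' occurrence of the grouping epoch preceding laser onset and laser onset --
#' is transplanted onto a uniformly drawn instance of that epoch in the
#' control trial; the matched interval starts `t` frames after that epoch
#' instance's first frame.
#'
#' @param controlTrials,laserTrials Lists of [trial()] objects; the laser
#'   trials should already be grouped by interrupted epoch (and filtered with
#'   [filterImpededLaserTrials()]).
#' @param epoch Grouping epoch label.
#' @param seed Integer seed.
#' @return Data frame `control_index, start_frame, t_frames, laser_index`;
#'   control trials lacking the epoch are skipped with a warning.
#' @export
matchedControlIntervals <- function(controlTrials, laserTrials, epoch = "Lift",
                                    seed = 1) {
  if (length(laserTrials) == 0) stop("laser group is empty")
  set.seed(seed)
  tVals <- vapply(laserTrials, function(tr) {
    starts <- tr@epochs$start[.labelMatches(tr@epochs$label, epoch) &
                              tr@epochs$start <= tr@laserOnFrame]
    if (!length(starts)) return(NA_real_)
    tr@laserOnFrame - max(starts)
  }, 0)
  if (all(is.na(tVals))) stop("no laser trial contains the grouping epoch before laser onset")
  out <- NULL
  skipped <- 0
  for (ci in seq_along(controlTrials)) {
    tr <- controlTrials[[ci]]
    inst <- which(.labelMatches(tr@epochs$label, epoch))
    if (!length(inst)) { skipped <- skipped + 1; next }
    li <- sample(which(!is.na(tVals)), 1)
    ei <- inst[sample.int(length(inst), 1)]
    out <- rbind(out, data.frame(control_index = ci,
                                 start_frame = tr@epochs$start[ei] + tVals[li],
                                 t_frames = tVals[li], laser_index = li))
  }
  if (skipped > 0)
    warning(sprintf("%d control trials lack epoch %s and were skipped", skipped, epoch))
  out
}

#' Distance-to-target time course
#'
#' Per time point (relative to laser onset for laser trials, or to the
#' matched interval start for controls), the Euclidean distance between the
#' hand and the chosen target, summarized across trials by the median and
#' quartiles.
#'
#' @param trials List of [trial()] objects with trajectories.
#' @param startFrames Interval start frame per trial (laser onset or matched
#'   start).
#' @param target Target position (3-vector, mm), e.g. from [inferTargets()]
#'   (the grab target for pre-Grab interruptions, the mouth target
#'   afterwards).
#' @param horizonMs Time course duration, ms.
#' @param preMs Lead-in before the interval start, ms.
#' @return Data frame `time_ms, q25, median, q75, n` (class
#'   `"deviationTimecourse"`); truncated with a warning when the horizon
#'   exceeds the trajectories.
#' @export
deviationTimecourse <- function(trials, startFrames, target, horizonMs = 400,
                                preMs = 100) {
  stopifnot(length(trials) == length(startFrames))
  fps <- trials[[1]]@fps
  pre <- round(msToFrames(preMs, fps))
  hor <- round(msToFrames(horizonMs, fps))
  offsets <- seq(-pre, hor)
  D <- matrix(NA_real_, length(trials), length(offsets))
  for (i in seq_along(trials)) {
    traj <- trials[[i]]@trajectory3d
    fr <- startFrames[i] + offsets
    ok <- fr >= 0 & fr < nrow(traj)
    if (!all(ok)) D[i, !ok] <- NA
    d <- sweep(traj[fr[ok] + 1, , drop = FALSE], 2, target)
    D[i, ok] <- sqrt(rowSums(d^2))
  }
  if (any(is.na(D))) warning("horizon exceeds some trajectories; truncated")
  qs <- apply(D, 2, quantile, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  out <- data.frame(time_ms = framesToMs(offsets, fps), q25 = qs[1, ],
                    median = qs[2, ], q75 = qs[3, ], n = colSums(!is.na(D)))
  class(out) <- c("deviationTimecourse", "data.frame")
  out
}

#' Interquartile divergence time of two deviation time courses
#'
#' The first time point at or after zero (laser onset) from which the
#' interquartile bands `[q25, q75]` of the two conditions are disjoint at
#' every subsequent point of the common grid; `NA` if the bands never
#' permanently separate.
#'
#' @param a,b Deviation time courses (from [deviationTimecourse()]) on a
#'   common time grid.
#' @return Divergence time, ms, or `NA`.
#' @export
divergenceTime <- function(a, b) {
  if (length(a$time_ms) != length(b$time_ms) ||
      max(abs(a$time_ms - b$time_ms)) > 1e-9)
    stop("time grids do not match")
  disjoint <- a$q75 < b$q25 | b$q75 < a$q25
  disjoint[is.na(disjoint)] <- FALSE
  post <- which(a$time_ms >= 0)
  sustained <- rev(cumprod(rev(disjoint[post]))) > 0
  if (!any(sustained)) return(NA_real_)
  a$time_ms[post[which(sustained)[1]]]
}

#' Align a trajectory segment by relative distance traveled
#'
#' Normalizes cumulative arc length to `[0, 1]` and linearly interpolates the
#' position at the requested arc-length fractions, removing time
#' parameterization: the same path traversed at any speed yields the same
#' aligned trajectory.
#'
#' @param segment `n x 3` matrix of positions, mm (at least 2 distinct).
#' @param fractions Strictly increasing checkpoint fractions spanning
#'   `[0, 1]`, or a single integer count of evenly spaced checkpoints.
#' @return List with `fractions` and `positions` (one row per checkpoint).
#' @export
alignByArclength <- function(segment, fractions = c(0, 1 / 3, 2 / 3, 1)) {
  segment <- as.matrix(segment)
  if (length(fractions) == 1 && fractions >= 2)
    fractions <- seq(0, 1, length.out = fractions)
  if (any(diff(fractions) <= 0) || fractions[1] != 0 || tail(fractions, 1) != 1)
    stop("fractions must be strictly increasing and span [0, 1]")
  if (nrow(segment) < 2) stop("segment needs at least 2 positions")
  steps <- sqrt(rowSums(diff(segment)^2))
  arc <- c(0, cumsum(steps))
  if (tail(arc, 1) <= 0) stop("zero total path length")
  s <- arc / tail(arc, 1)
  keep <- c(TRUE, diff(s) > 0)
  pos <- vapply(1:3, function(j)
    approx(s[keep], segment[keep, j], xout = fractions)$y, numeric(length(fractions)))
  list(fractions = fractions, positions = matrix(pos, ncol = 3))
}

#' Reach segment of a trial (first Lift to Grab start)
#'
#' Convenience extractor for the transport phase used by the
#' nearest-neighbor comparison: hand positions from the first frame of the
#' first Lift (after laser offset for rebound trials) to the first frame of
#' Grab in the final sequence.
#'
#' @param tr A [trial()] with a trajectory.
#' @return `n x 3` matrix, or `NULL` if the trial lacks the epochs.
#' @export
reachSegment <- function(tr) {
  lift <- .firstStart(tr@epochs, "Lift")
  grab <- .firstStart(finalSequence(tr), "Grab")
  if (is.na(lift) || is.na(grab) || grab <= lift) return(NULL)
  if (nrow(tr@trajectory3d) <= grab) return(NULL)
  tr@trajectory3d[seq(lift, grab) + 1, , drop = FALSE]
}

#' Nearest-neighbor balanced accuracy between two trajectory groups
#'
#' How well a leave-one-out 1-nearest-neighbor classifier on the hand
#' position at a given arc-length checkpoint can tell the two groups apart,
#' reported as balanced accuracy -- the average of the true-positive and
#' true-negative rates, so that 0.5 is chance regardless of group sizes.
#'
#' @param groupA,groupB Lists of aligned trajectories (from
#'   [alignByArclength()]) computed at a common set of fractions, each with
#'   at least 2 members.
#' @param checkpoint Index into the checkpoint fractions.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
nnBalancedAccuracy <- function(groupA, groupB, checkpoint = 3) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 trials")
  pa <- t(vapply(groupA, function(a) a$positions[checkpoint, ], numeric(3)))
  pb <- t(vapply(groupB, function(b) b$positions[checkpoint, ], numeric(3)))
  X <- rbind(pa, pb)
  y <- c(rep(TRUE, nrow(pa)), rep(FALSE, nrow(pb)))
  d2 <- as.matrix(dist(X))^2
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  pred <- y[nn]
  tpr <- mean(pred[y])
  tnr <- mean(!pred[!y])
  (tpr + tnr) / 2
}

#' Grab end-point error
#'
#' Distance between each trial's Grab-start hand position and the per-axis
#' median Grab position of the reference trials (control successes).
#'
#' @param trials Trials to score.
#' @param referenceTrials Control success trials defining the reference Grab
#'   position.
#' @return List with `distances_mm` (one per scorable trial), `median_mm` and
#'   `mad_mm` (median absolute deviation).
#' @export
grabError <- function(trials, referenceTrials) {
  refs <- do.call(rbind, lapply(referenceTrials, .positionAtEpochStart, label = "Grab"))
  if (is.null(refs)) stop("empty reference set: no Grab positions")
  ref <- apply(refs, 2, median)
  pts <- do.call(rbind, lapply(trials, .positionAtEpochStart, label = "Grab"))
  if (is.null(pts)) stop("no scorable trials with Grab positions")
  d <- sqrt(rowSums(sweep(pts, 2, ref)^2))
  list(distances_mm = d, median_mm = median(d),
       mad_mm = median(abs(d - median(d))))
}

#' Two-sample distribution comparison
#'
#' The two tests used throughout the perturbation analyses, as a uniform
#' contract: the Wilcoxon-Mann-Whitney rank-sum test (exact null when the
#' pooled sample size is at most 20 and there are no ties, normal
#' approximation with tie correction otherwise) and Welch's t-test assuming
#' unequal variances. Two-sided throughout. Degenerate input (all pooled
#' values identical) returns p = 1 with a warning.
#'
#' @param a,b Numeric samples (at least 2 observations each).
#' @param method `"rank_sum"` or `"welch_t"`.
#' @return List with `statistic` and `p.value`.
#' @export
compareDistributions <- function(a, b, method = c("rank_sum", "welch_t")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2)
    stop("at least 2 observations per sample are required")
  pooled <- c(a, b)
  if (max(pooled) - min(pooled) < .Machine$double.eps) {
    warning("degenerate samples: all pooled values identical; p = 1")
    return(list(statistic = NA_real_, p.value = 1))
  }
  if (method == "rank_sum") {
    exact <- length(pooled) <= 20 && !anyDuplicated(pooled)
    ht <- wilcox.test(a, b, exact = exact, correct = !exact)
  } else {
    ht <- t.test(a, b, var.equal = FALSE)
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Rank-based dispersion comparison
#'
#' Ansari-Bradley test on median-centered samples: a rank-based test of equal
#' scale used to compare the variability of control and rebound first-lift
#' latencies without assuming normality.
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` and `p.value`.
#' @export
compareDispersion <- function(a, b) {
  ht <- ansari.test(a - median(a), b - median(b), exact = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
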