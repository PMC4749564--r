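## Ethogram statistics: epoch validation, latency/interval measures,
## initiation rates, cumulative first-lift histograms, and epoch-progression
## histograms with matched-control subsampling.

.canonicalIndex <- function(label) {
  label[label == "ChewNoPellet"] <- "Chew"
  match(label, canonicalEpochs())
}

#' First frame of the first epoch with a given label
#' @noRd
.firstStart <- function(ep, label, after = -Inf) {
  s <- ep$start[.labelMatches(ep$label, label) & ep$start >= after]
  if (length(s)) min(s) else NA_real_
}

.labelMatches <- function(labels, label) {
  if (label == "Chew") labels %in% c("Chew", "ChewNoPellet") else labels == label
}

#' The final prehension sequence of a trial
#'
#' The last maximal run of canonical epochs (sorted by first frame) whose
#' canonical indices are non-decreasing; interval statistics that the
#' annotation scheme defines "during the final prehension sequence"
#' (Grab-Supinate, Supinate-At mouth, Grab-At mouth) are computed on this run.
#'
#' @param tr A [trial()].
#' @return Epoch data frame (possibly zero rows).
#' @export
finalSequence <- function(tr) {
  ep <- tr@epochs
  ep <- ep[!is.na(.canonicalIndex(ep$label)), , drop = FALSE]
  if (nrow(ep) == 0) return(ep)
  ep <- ep[order(ep$start), , drop = FALSE]
  ci <- .canonicalIndex(ep$label)
  runStart <- 1
  for (i in seq_len(nrow(ep))[-1]) if (ci[i] < ci[i - 1]) runStart <- i
  ep[seq(runStart, nrow(ep)), , drop = FALSE]
}

#' Validate a trial against the annotation invariants
#'
#' Checks the structural rules of the ethogram: ordered laser window, valid
#' epoch labels, positive-length intervals, and canonical ordering of the
#' final prehension sequence on first frames (Lift before HandOpen before
#' Grab before Supinate before AtMouth before Chew). A trial with no epochs
#' and outcome `no_initiation` is valid.
#'
#' @param tr A [trial()].
#' @return Character vector of violations; empty iff the trial is valid.
#' @export
validateTrial <- function(tr) {
  v <- character(0)
  ep <- tr@epochs
  if (!is.na(tr@laserOnFrame) && !is.na(tr@laserOffFrame) &&
      tr@laserOnFrame >= tr@laserOffFrame)
    v <- c(v, "laser window: laser_on must precede laser_off")
  if (nrow(ep)) {
    bad <- !ep$label %in% .epochLabels()
    if (any(bad))
      v <- c(v, paste("unknown epoch label:", paste(unique(ep$label[bad]), collapse = ", ")))
    if (any(ep$start >= ep$end))
      v <- c(v, "epoch interval: start must precede end")
    fin <- tryCatch(finalSequence(tr), error = function(e) NULL)
    if (!is.null(fin) && nrow(fin)) {
      firsts <- vapply(canonicalEpochs(), function(l) .firstStart(fin, l), 0)
      firsts <- firsts[!is.na(firsts)]
      if (length(firsts) > 1 && any(diff(firsts) <= 0))
        v <- c(v, paste("canonical ordering violated in final sequence:",
                        paste(names(firsts), collapse = " -> ")))
    }
    ## a Grab anywhere before the trial's first Lift breaks the sequence logic
    lifts <- ep$start[ep$label == "Lift"]
    grabs <- ep$start[ep$label == "Grab"]
    if (length(lifts) && length(grabs) && min(grabs) < min(lifts))
      v <- c(v, "canonical ordering violated: Grab precedes first Lift")
  } else if (tr@outcome != "no_initiation" && tr@outcome != "failure") {
    v <- c(v, "successful trial must contain epochs")
  }
  v
}

#' Reference frame of a trial (cue or laser offset)
#' @noRd
.referenceFrame <- function(tr, reference) {
  ref <- switch(reference, cue = tr@cueFrame, laser_off = tr@laserOffFrame,
                stop("reference must be 'cue' or 'laser_off'"))
  if (is.na(ref)) stop(sprintf("trial %s has no %s event", tr@trialId, reference))
  ref
}

#' Latency and interval statistics of a trial
#'
#' First Lift is the first frame of the first Lift after the reference event
#' (the cue for control trials, laser offset for rebound trials). The
#' between-component intervals are differences of first frames: Lift-HandOpen,
#' Lift-Grab and HandOpen-Grab over the whole trial; Grab-Supinate,
#' Supinate-AtMouth and Grab-AtMouth within the final prehension sequence.
#' All values in ms at the trial's frame rate; undefined intervals are `NA`.
#'
#' @param tr A [trial()].
#' @param reference `"cue"` or `"laser_off"`.
#' @return One-row data frame with columns `first_lift`, `lift_to_handopen`,
#'   `lift_to_grab`, `handopen_to_grab`, `grab_to_supinate`,
#'   `supinate_to_atmouth`, `grab_to_atmouth` (ms).
#' @export
intervalStats <- function(tr, reference = c("cue", "laser_off")) {
  reference <- match.arg(reference)
  ref <- .referenceFrame(tr, reference)
  ep <- tr@epochs
  fin <- finalSequence(tr)
  ms <- function(frames) framesToMs(frames, tr@fps)
  lift <- .firstStart(ep, "Lift", after = ref)
  ho <- .firstStart(ep, "HandOpen")
  grab <- .firstStart(ep, "Grab")
  gFin <- .firstStart(fin, "Grab")
  sFin <- .firstStart(fin, "Supinate")
  aFin <- .firstStart(fin, "AtMouth")
  liftAny <- .firstStart(ep, "Lift")
  data.frame(
    first_lift = ms(lift - ref),
    lift_to_handopen = ms(ho - liftAny),
    lift_to_grab = ms(grab - liftAny),
    handopen_to_grab = ms(grab - ho),
    grab_to_supinate = ms(sFin - gFin),
    supinate_to_atmouth = ms(aFin - sFin),
    grab_to_atmouth = ms(aFin - gFin))
}

#' Initiation rate over a bracketed window
#'
#' A trial counts as initiated iff a Lift starts within `[reference + window[1],
#' reference + window[2])`. Counts are exact integers.
#'
#' @param trials List of [trial()] objects.
#' @param window `c(lo, hi)` frames relative to the reference event.
#' @param reference `"cue"` or `"laser_off"`.
#' @return Named integer vector `c(initiated, total)`.
#' @export
initiationRate <- function(trials, window, reference = c("cue", "laser_off")) {
  reference <- match.arg(reference)
  if (window[1] > window[2]) stop("window must be ordered")
  if (length(trials) == 0) return(c(initiated = 0L, total = 0L))
  hits <- vapply(trials, function(tr) {
    ref <- .referenceFrame(tr, reference)
    lifts <- tr@epochs$start[tr@epochs$label == "Lift"]
    any(lifts >= ref + window[1] & lifts < ref + window[2])
  }, logical(1))
  c(initiated = sum(hits), total = length(trials))
}

#' Cumulative first-lift histogram
#'
#' The running total, over trials, of the occurrence of the first Lift after
#' the reference event: a non-decreasing step function of time whose terminal
#' value is the number of initiating trials.
#'
#' @param trials List of [trial()] objects.
#' @param reference `"cue"` or `"laser_off"`.
#' @return Data frame `time_ms, cum_count` (sorted, unique times), with the
#'   evaluable step function in `attr(, "fun")`.
#' @export
cumulativeFirstLift <- function(trials, reference = c("cue", "laser_off")) {
  reference <- match.arg(reference)
  lat <- vapply(trials, function(tr) {
    ref <- .referenceFrame(tr, reference)
    framesToMs(.firstStart(tr@epochs, "Lift", after = ref) - ref, tr@fps)
  }, 0)
  lat <- sort(lat[!is.na(lat)])
  if (length(lat) == 0) {
    out <- data.frame(time_ms = numeric(0), cum_count = numeric(0))
    attr(out, "fun") <- function(t) rep(0, length(t))
    return(out)
  }
  ut <- unique(lat)
  cc <- vapply(ut, function(t) sum(lat <= t), 0)
  out <- data.frame(time_ms = ut, cum_count = cc)
  f <- stats::stepfun(ut, c(0, cc))
  attr(out, "fun") <- function(t) f(t)
  out
}

#' Epoch ongoing at laser onset
#'
#' The grouping rule for perturbation analyses: the last canonical component
#' whose first frame precedes (or equals) laser onset; `"none"` if the laser
#' arrived before any component started.
#'
#' @param tr A laser [trial()].
#' @return Epoch label or `"none"`.
#' @export
epochAtLaserOnset <- function(tr) {
  if (is.na(tr@laserOnFrame)) stop("trial has no laser window")
  ep <- tr@epochs[!is.na(.canonicalIndex(tr@epochs$label)), , drop = FALSE]
  started <- ep[ep$start <= tr@laserOnFrame, , drop = FALSE]
  if (nrow(started) == 0) return("none")
  lab <- started$label[which.max(started$start)]
  if (lab == "ChewNoPellet") "Chew" else lab
}

#' Whether a trial achieves an epoch
#' @noRd
.achieves <- function(tr, label, after = -Inf) {
  !is.na(.firstStart(tr@epochs, label, after = after))
}

#' Epoch-progression histogram with matched controls
#'
#' For each group of laser trials (grouped by the epoch ongoing at laser
#' onset) and each subsequent canonical transition, the percentage of trials
#' containing the later component after the grouping epoch. For comparison, a
#' control subsample is drawn per animal with a seeded RNG, equal in count to
#' the laser trials and restricted to control trials achieving at least the
#' grouping epoch.
#'
#' @param laserTrials,controlTrials Lists of [trial()] objects.
#' @param seed Integer seed for the control subsampling.
#' @return Data frame `group, transition, condition, n, pct`.
#' @export
progressionHistogram <- function(laserTrials, controlTrials, seed = 1) {
  if (length(laserTrials) == 0) stop("at least one laser trial is required")
  set.seed(seed)
  groups <- vapply(laserTrials, epochAtLaserOnset, "")
  laserTrials <- laserTrials[groups != "none"]
  groups <- groups[groups != "none"]
  ctrlAnimal <- vapply(controlTrials, function(t) t@animalId, "")
  out <- NULL
  for (g in intersect(canonicalEpochs(), unique(groups))) {
    gi <- which(groups == g)
    lt <- laserTrials[gi]
    ## per-animal matched control subsample achieving at least the grouping epoch
    ctrl <- list()
    for (an in unique(vapply(lt, function(t) t@animalId, ""))) {
      nl <- sum(vapply(lt, function(t) t@animalId, "") == an)
      eligible <- controlTrials[ctrlAnimal == an &
                                vapply(controlTrials, .achieves, TRUE, label = g)]
      if (length(eligible) == 0)
        stop(sprintf("no eligible control trials for group %s (animal %s)", g, an))
      ctrl <- c(ctrl, eligible[sample.int(length(eligible), nl,
                                          replace = nl > length(eligible))])
    }
    gIdx <- match(g, canonicalEpochs())
    transitions <- canonicalEpochs()[seq(gIdx, length(canonicalEpochs()))]
    for (i in seq_len(length(transitions) - 1)) {
      a <- transitions[i]; b <- transitions[i + 1]
      pctOf <- function(ts) {
        after <- vapply(ts, function(t) {
          ga <- .firstStart(t@epochs, g)
          .achieves(t, b, after = if (is.na(ga)) -Inf else ga)
        }, TRUE)
        100 * mean(after)
      }
      out <- rbind(out,
        data.frame(group = g, transition = paste(a, b, sep = "->"),
                   condition = c("laser", "control"),
                   n = c(length(lt), length(ctrl)),
                   pct = c(pctOf(lt), pctOf(ctrl))))
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Session IO
## ---------------------------------------------------------------------------

#' Read/write behavioral sessions
#'
#' A session file is JSON: animal id, frame rate, and a list of trials with
#' their events, outcome and epoch intervals (trajectories are stored
#' separately as CSV; see [writeTrajectory3d()]). Epoch tables can also be
#' exported/imported as a flat CSV of epoch rows.
#'
#' @param trials List of [trial()] objects (one animal, one fps).
#' @param path File path.
#' @return `writeSession` returns `path` invisibly; `readSession` returns a
#'   list of `Trial` objects (without trajectories).
#' @export
writeSession <- function(trials, path) {
  ses <- list(
    animal = trials[[1]]@animalId, fps = trials[[1]]@fps,
    trials = lapply(trials, function(tr) list(
      trial_id = tr@trialId, cue = tr@cueFrame,
      laser_on = tr@laserOnFrame, laser_off = tr@laserOffFrame,
      pellet_present = tr@pelletPresent, outcome = tr@outcome,
      epochs = tr@epochs)))
  jsonlite::write_json(ses, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  trs <- s$trials
  lapply(seq_len(nrow(trs)), function(i) {
    ep <- trs$epochs[[i]]
    if (is.null(ep) || NROW(ep) == 0) ep <- emptyEpochs()
    num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
    trial(trs$trial_id[i], animalId = s$animal, fps = s$fps,
          cueFrame = num(trs$cue[i]), laserOnFrame = num(trs$laser_on[i]),
          laserOffFrame = num(trs$laser_off[i]),
          pelletPresent = isTRUE(trs$pellet_present[i]),
          epochs = as.data.frame(ep), outcome = trs$outcome[i])
  })
}

#' Flat epoch-row CSV export/import
#'
#' @param trials List of [trial()] objects.
#' @param path CSV path.
#' @return `trialsToEpochCSV` returns `path` invisibly; `epochCSVToFrame`
#'   returns the flat data frame `trial_id, animal_id, label, start, end`.
#' @export
trialsToEpochCSV <- function(trials, path) {
  rows <- do.call(rbind, lapply(trials, function(tr) {
    if (nrow(tr@epochs) == 0) return(NULL)
    data.frame(trial_id = tr@trialId, animal_id = tr@animalId,
               label = tr@epochs$label, start = tr@epochs$start,
               end = tr@epochs$end)
  }))
  if (is.null(rows))
    rows <- data.frame(trial_id = character(0), animal_id = character(0),
                       label = character(0), start = numeric(0), end = numeric(0))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trialsToEpochCSV
#' @export
epochCSVToFrame <- function(path) read.csv(path)

#' Write/read a 3D trajectory CSV
#'
#' Columns: `frame, x_mm, y_mm, z_mm` (frames 0-based).
#'
#' @param traj `n x 3` matrix, mm.
#' @param path CSV path.
#' @return `writeTrajectory3d` returns `path` invisibly; `readTrajectory3d`
#'   the matrix.
#' @export
writeTrajectory3d <- function(traj, path) {
  write.csv(data.frame(frame = seq_len(nrow(traj)) - 1, x_mm = traj[, 1],
                       y_mm = traj[, 2], z_mm = traj[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory3d
#' @export
readTrajectory3d <- function(path) {
  d <- read.csv(path)
  as.matrix(d[, c("x_mm", "y_mm", "z_mm")])
}
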