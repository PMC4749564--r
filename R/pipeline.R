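## Orchestration: configuration validation, staged end-to-end runs on
## synthetic data, manifests with checksums, and report generation.

#' Default pipeline configuration
#'
#' Nested list of all stage parameters with their defaults. Stages:
#' `synth` (simulate a behavioral session and render a stereo video of one
#' trial), `track` (train the cascade on synthetic labeled frames and track
#' the rendered video), `reconstruct` (triangulate the 2D tracks),
#' `analyze` (ethogram and kinematics tables), `ephys` (spike simulation and
#' PSTHs), `report` (plots and summary tables). Defaults are sized for a
#' quick desk-scale run; raise `track$nStages` and `synth$nTrials` for a
#' full-scale analysis.
#'
#' @return Configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    outdir = "prehensr-run",
    fps = 500,
    stages = c("synth", "track", "reconstruct", "analyze", "ephys", "report"),
    seeds = list(synth = 1, track = 2, analyze = 3, ephys = 4),
    synth = list(
      nTrials = 12, laserFraction = 0.25, laserDurationMs = 2000,
      laserAlign = "cue", nFrames = 3000, cueFrame = 400,
      videoTrial = 1, videoFrames = 60),
    track = list(
      nStages = 20, nFerns = 50, fernDepth = 5, poolSize = 200,
      featureRadius = 40, nTrainFrames = 60, nInits = 50),
    analyze = list(
      initiationWindowMs = c(0, 2000), horizonMs = 300, checkpoint = 3),
    ephys = list(
      baselineRate = 10, suppressionFraction = 0.9, reboundGain = 3,
      reboundDurationMs = 300, laserDurationS = 2, nTrials = 50))
}

#' Validate a pipeline configuration
#'
#' Merges the user configuration over [defaultRunConfig()], rejecting unknown
#' keys (listed by name) and requiring an explicit seed for every requested
#' stochastic stage.
#'
#' @param config Configuration list, or path to a YAML file.
#' @return The merged, validated configuration.
#' @export
validateRunConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- defaultRunConfig()
  checkKeys <- function(user, ref, prefix = "") {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (k in names(user))
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
        checkKeys(as.list(user[[k]]), ref[[k]], paste0(prefix, k, "$"))
  }
  checkKeys(config, def)
  merge2 <- function(ref, user) {
    for (k in names(user)) {
      ref[[k]] <- if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
        merge2(ref[[k]], as.list(user[[k]])) else user[[k]]
    }
    ref
  }
  cfg <- merge2(def, config)
  bad <- setdiff(cfg$stages, def$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in intersect(cfg$stages, names(def$seeds)))
    if (is.null(cfg$seeds[[st]]) || !is.finite(cfg$seeds[[st]]))
      stop("stage '", st, "' requires an explicit integer seed")
  cfg
}

.md5 <- function(path) unname(tools::md5sum(path))

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order on synthetic data,
#' writing each stage's outputs (CSV/JSON/PNG) under `config$outdir` and a
#' manifest (`manifest.json`) containing the configuration hash, package
#' version, per-file checksums and accumulated warnings. Identical
#' configuration and seeds reproduce identical checksums. If tracking or
#' reconstruction is disabled, downstream stages fall back to the generator's
#' ground-truth tracks/trajectories.
#'
#' @param config Configuration list or YAML path (see [defaultRunConfig()]).
#' @param resume Skip stages whose outputs already exist under a manifest with
#'   the same configuration hash.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config = list(), resume = FALSE) {
  cfg <- validateRunConfig(config)
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ## hash excludes the output location so runs into different directories with
  ## the same parameters share a configuration identity
  cfgHash <- .md5local(jsonlite::toJSON(cfg[setdiff(names(cfg), "outdir")],
                                        auto_unbox = TRUE, digits = NA))
  manifestPath <- file.path(out, "manifest.json")
  prev <- if (resume && file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL
  canResume <- !is.null(prev) && identical(prev$config_hash, cfgHash)
  if (canResume) {
    paths <- file.path(out, names(prev$files))
    if (all(file.exists(paths)) &&
        identical(unname(vapply(paths, .md5, "")), unname(unlist(prev$files)))) {
      message("resuming: outputs match previous manifest, nothing to do")
      return(invisible(prev))
    }
  }
  files <- list()
  warns <- character(0)
  note <- function(path) files[[basename(path)]] <<- .md5(path)
  state <- new.env(parent = emptyenv())

  needs <- function(stage, dep) {
    if (is.null(state[[dep]]))
      stop("stage '", stage, "' requires upstream output from stage '", dep, "'")
  }

  kin <- reachKinematicsParams(fps = cfg$fps)
  scene <- sceneParams()

  if ("synth" %in% cfg$stages) {
    trials <- simulateSession(cfg$synth$nTrials, kin,
      laserFraction = cfg$synth$laserFraction,
      laserDurationMs = cfg$synth$laserDurationMs,
      laserAlign = cfg$synth$laserAlign, seed = cfg$seeds$synth,
      nFrames = cfg$synth$nFrames, cueFrame = cfg$synth$cueFrame)
    state$trials <- trials
    p <- file.path(out, "session.json"); writeSession(trials, p); note(p)
    p <- file.path(out, "epochs.csv"); trialsToEpochCSV(trials, p); note(p)
    vt <- min(cfg$synth$videoTrial, length(trials))
    tr <- trials[[vt]]
    lift <- tr@epochs$start[tr@epochs$label == "Lift"][1]
    start <- if (length(lift) && !is.na(lift)) max(0, lift - 10) else tr@cueFrame
    fr <- c(start, min(start + cfg$synth$videoFrames - 1, nrow(tr@trajectory3d) - 1))
    state$video <- withCallingHandlers(
      renderStereoVideo(tr, scene, seed = cfg$seeds$synth + 1, frameRange = fr),
      warning = function(w) { warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning") })
    state$videoTrial <- tr
    for (v in c("front", "side")) {
      tk <- state$video$tracks[[v]]
      p <- file.path(out, paste0("groundtruth_track_", v, ".csv"))
      write.csv(data.frame(frame = state$video$frameIndex,
                           x_px = tk[, 1], y_px = tk[, 2]), p, row.names = FALSE)
      note(p)
    }
  }

  if ("track" %in% cfg$stages) {
    needs("track", "video")
    ts <- makeTrainingFrames(cfg$track$nTrainFrames, scene, kin,
                             seed = cfg$seeds$track)
    model <- trainCascade(ts$frames, ts$labels, nStages = cfg$track$nStages,
                          nFerns = cfg$track$nFerns, fernDepth = cfg$track$fernDepth,
                          poolSize = cfg$track$poolSize,
                          featureRadius = cfg$track$featureRadius,
                          seed = cfg$seeds$track + 1)
    p <- file.path(out, "cascade_model.json"); writeCascadeModel(model, p); note(p)
    tcfg <- trackConfig(nInits = cfg$track$nInits)
    state$tracks2d <- list()
    for (v in c("front", "side")) {
      res <- trackFrames(state$video$frames[[v]], model, tcfg,
                         seed = cfg$seeds$track + match(v, c("front", "side")))
      res$track$frame <- state$video$frameIndex
      state$tracks2d[[v]] <- res$track
      p <- file.path(out, paste0("track_", v, ".csv"))
      writeTrack(res$track, p, file.path(out, paste0("review_", v, ".json")))
      note(p); note(file.path(out, paste0("review_", v, ".json")))
    }
  }

  if ("reconstruct" %in% cfg$stages) {
    needs("reconstruct", "video")
    tks <- if (!is.null(state$tracks2d)) {
      lapply(state$tracks2d, function(t) cbind(t$x_px, t$y_px))
    } else {
      state$video$tracks  # ground-truth substitution when tracking is disabled
    }
    tk3 <- triangulateTrack(tks$front, tks$side, scene@cameras)
    tk3$frame <- state$video$frameIndex
    state$traj3d <- tk3
    p <- file.path(out, "trajectory3d.csv"); write.csv(tk3, p, row.names = FALSE); note(p)
  }

  if ("analyze" %in% cfg$stages) {
    needs("analyze", "trials")
    trials <- state$trials
    isLaser <- vapply(trials, function(t) !is.na(t@laserOnFrame), TRUE)
    ctrl <- trials[!isLaser]; laser <- trials[isLaser]
    win <- round(msToFrames(cfg$analyze$initiationWindowMs, cfg$fps))
    tab <- rbind(
      data.frame(condition = "control", reference = "cue",
                 t(initiationRate(ctrl, win, "cue"))),
      if (length(laser)) data.frame(condition = "laser", reference = "cue",
                 t(initiationRate(laser, win, "cue"))),
      if (length(laser)) data.frame(condition = "laser", reference = "laser_off",
                 t(initiationRate(laser, win, "laser_off"))))
    p <- file.path(out, "initiation_rates.csv"); write.csv(tab, p, row.names = FALSE); note(p)
    cfl <- cumulativeFirstLift(ctrl, "cue")
    p <- file.path(out, "cumulative_first_lift_control.csv")
    write.csv(cfl, p, row.names = FALSE); note(p)
    ivs <- do.call(rbind, lapply(ctrl, intervalStats, reference = "cue"))
    ivs <- cbind(trial_id = vapply(ctrl, function(t) t@trialId, ""), ivs)
    p <- file.path(out, "interval_stats_control.csv")
    write.csv(ivs, p, row.names = FALSE); note(p)
    succ <- ctrl[vapply(ctrl, function(t) t@outcome == "success", TRUE)]
    if (length(succ) >= 2) {
      tg <- inferTargets(succ, "mean")
      p <- file.path(out, "targets.csv")
      write.csv(data.frame(target = c("grab", "mouth"),
                           x_mm = c(tg$grabTarget[1], tg$mouthTarget[1]),
                           y_mm = c(tg$grabTarget[2], tg$mouthTarget[2]),
                           z_mm = c(tg$grabTarget[3], tg$mouthTarget[3])),
                p, row.names = FALSE); note(p)
      ge <- grabError(succ, succ)
      p <- file.path(out, "grab_error_control.csv")
      write.csv(data.frame(trial = seq_along(ge$distances_mm),
                           distance_mm = ge$distances_mm), p, row.names = FALSE)
      note(p)
    }
    rebound <- laser[vapply(laser, function(t)
      isTRUE(t@meta$rebounded) && t@outcome == "success", TRUE)]
    if (length(rebound) >= 2 && length(succ) >= 2) {
      alnC <- Filter(Negate(is.null), lapply(succ, function(t) {
        sg <- reachSegment(t); if (is.null(sg)) NULL else alignByArclength(sg) }))
      alnR <- Filter(Negate(is.null), lapply(rebound, function(t) {
        sg <- reachSegment(t); if (is.null(sg)) NULL else alignByArclength(sg) }))
      if (length(alnC) >= 2 && length(alnR) >= 2) {
        acc <- nnBalancedAccuracy(alnC, alnR, checkpoint = cfg$analyze$checkpoint)
        p <- file.path(out, "nn_accuracy.csv")
        write.csv(data.frame(checkpoint = cfg$analyze$checkpoint,
                             balanced_accuracy = acc), p, row.names = FALSE)
        note(p)
      }
    }
  }

  if ("ephys" %in% cfg$stages) {
    ep <- cfg$ephys
    params <- spikeSimParams(baselineRate = ep$baselineRate,
                             suppressionFraction = ep$suppressionFraction,
                             reboundGain = ep$reboundGain,
                             reboundDurationMs = ep$reboundDurationMs,
                             laserWindow = c(1, 1 + ep$laserDurationS),
                             trialDuration = 3 + ep$laserDurationS,
                             nTrials = ep$nTrials)
    trains <- simulateSpikeTrains(params, seed = cfg$seeds$ephys)
    p <- file.path(out, "spike_times.csv"); writeSpikeTimes(trains, p); note(p)
    ps <- psth(trains, alignTimes = 1, window = c(-1, 2 + ep$laserDurationS))
    p <- file.path(out, "psth.csv"); writePsth(ps, p); note(p)
    mod <- reboundModulation(ps, baselineWindow = c(-1, 0),
                             laserWindow = c(0, ep$laserDurationS),
                             postWindow = c(ep$laserDurationS,
                                            ep$laserDurationS + ep$reboundDurationMs / 1000))
    p <- file.path(out, "modulation.csv")
    write.csv(data.frame(suppression_ratio = mod$suppression_ratio,
                         rebound_ratio = mod$rebound_ratio), p, row.names = FALSE)
    note(p)
    state$psth <- ps
  }

  manifest <- list(config_hash = cfgHash,
                   package_version = as.character(utils::packageVersion("prehensr")),
                   files = files, warnings = warns)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)

  if ("report" %in% cfg$stages) exportReport(out)
  invisible(manifest)
}

.md5local <- function(txt) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(as.character(txt), tf)
  .md5(tf)
}

#' Generate a report bundle from pipeline outputs
#'
#' Reads the stage outputs under `outdir` and writes a `report/` subdirectory
#' with summary plots (ethogram raster, cumulative first-lift histogram,
#' distance time courses where available, PSTH) as PDF and copies of the
#' summary tables. Missing inputs skip the corresponding plot with a warning.
#'
#' @param outdir Pipeline output directory containing a `manifest.json`.
#' @return Path of the report directory, invisibly.
#' @export
exportReport <- function(outdir) {
  rep <- file.path(outdir, "report")
  dir.create(rep, recursive = TRUE, showWarnings = FALSE)
  have <- function(f) file.exists(file.path(outdir, f))

  if (have("epochs.csv") && have("session.json")) {
    ep <- read.csv(file.path(outdir, "epochs.csv"))
    grDevices::pdf(file.path(rep, "ethogram.pdf"), width = 7, height = 5)
    ids <- unique(ep$trial_id)
    graphics::plot(NULL, xlim = range(c(ep$start, ep$end, 0)),
                   ylim = c(0, length(ids) + 1), xlab = "frame",
                   ylab = "trial", main = "Ethogram")
    cols <- setNames(grDevices::hcl.colors(length(.epochLabels()), "Dark 3"),
                     .epochLabels())
    for (i in seq_along(ids)) {
      e <- ep[ep$trial_id == ids[i], ]
      if (nrow(e)) graphics::rect(e$start, i - 0.4, e$end, i + 0.4,
                                  col = cols[e$label], border = NA)
    }
    graphics::legend("topright", legend = names(cols), fill = cols, cex = 0.5)
    grDevices::dev.off()
  } else warning("ethogram inputs missing; plot skipped")

  if (have("cumulative_first_lift_control.csv")) {
    d <- read.csv(file.path(outdir, "cumulative_first_lift_control.csv"))
    grDevices::pdf(file.path(rep, "cumulative_first_lift.pdf"), width = 6, height = 4)
    if (nrow(d)) {
      graphics::plot(stats::stepfun(d$time_ms, c(0, d$cum_count)),
                     xlab = "time after cue (ms)", ylab = "cumulative first lifts",
                     main = "Cumulative first-lift histogram", do.points = FALSE)
    } else {
      graphics::plot(0, 0, type = "n", xlab = "time after cue (ms)",
                     ylab = "cumulative first lifts",
                     main = "Cumulative first-lift histogram (no initiations)")
    }
    grDevices::dev.off()
  } else warning("cumulative first-lift table missing; plot skipped")

  if (have("trajectory3d.csv")) {
    d <- read.csv(file.path(outdir, "trajectory3d.csv"))
    grDevices::pdf(file.path(rep, "trajectory3d.pdf"), width = 7, height = 3)
    op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    for (pair in list(c("x_mm", "y_mm"), c("x_mm", "z_mm"), c("y_mm", "z_mm")))
      graphics::plot(d[[pair[1]]], d[[pair[2]]], type = "l", xlab = pair[1],
                     ylab = pair[2], main = "Reconstructed 3D trajectory")
    graphics::par(op)
    grDevices::dev.off()
  } else warning("3D trajectory missing; plot skipped")

  if (have("psth.csv")) {
    d <- read.csv(file.path(outdir, "psth.csv"))
    grDevices::pdf(file.path(rep, "psth.pdf"), width = 6, height = 4)
    ctr <- (d$bin_start_s + d$bin_end_s) / 2
    graphics::plot(ctr, d$rate_hz, type = "s", xlab = "time from laser onset (s)",
                   ylab = "rate (Hz)", main = "PSTH (100 ms bins)")
    graphics::abline(v = 0, col = "blue", lty = 2)
    grDevices::dev.off()
  } else warning("PSTH missing; plot skipped")

  for (f in c("initiation_rates.csv", "grab_error_control.csv",
              "nn_accuracy.csv", "modulation.csv"))
    if (have(f)) file.copy(file.path(outdir, f), file.path(rep, f),
                           overwrite = TRUE)
  invisible(rep)
}
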