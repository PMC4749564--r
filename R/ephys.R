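## Spike-train analysis: trough-to-peak width classification, peristimulus
## time histograms, and suppression/rebound quantification around laser
## epochs.

#' Trough-to-peak spike width
#'
#' The interval from the global minimum (trough) of the mean extracellular
#' waveform to the subsequent global maximum (peak), in ms. Errors if the
#' waveform is monotone or its global peak precedes the trough (e.g. a
#' time-reversed waveform).
#'
#' @param meanWaveform Numeric vector of waveform samples (voltage), or a
#'   `UnitRecord`.
#' @param sampleRate Sampling rate, Hz (taken from the `UnitRecord` when one
#'   is supplied).
#' @return Spike width, ms.
#' @export
spikeWidth <- function(meanWaveform, sampleRate = 19531.25) {
  if (is(meanWaveform, "UnitRecord")) {
    sampleRate <- meanWaveform@sampleRate
    meanWaveform <- meanWaveform@meanWaveform
  }
  w <- as.numeric(meanWaveform)
  if (length(w) < 3) stop("waveform too short")
  dw <- diff(w)
  if (all(dw >= 0) || all(dw <= 0)) stop("monotone waveform has no trough-peak pair")
  trough <- which.min(w)
  if (which.max(w) < trough)
    stop("waveform peak precedes trough (expected trough-then-peak)")
  if (trough == length(w)) stop("no peak after the trough")
  peak <- trough + which.max(w[(trough + 1):length(w)])
  (peak - trough) / sampleRate * 1000
}

#' Classify a unit by spike width
#'
#' Units with trough-to-peak width below 0.35 ms are fast-spiking
#' (putative interneurons); widths above 0.45 ms are putative pyramidal
#' neurons; intermediate widths (including the boundary values, where the
#' defining inequalities are strict on both sides) are excluded.
#'
#' @param width Spike width, ms (positive).
#' @return `"fast_spiking"`, `"pyramidal"` or `"excluded"`.
#' @export
classifyUnit <- function(width) {
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0)
    stop("width must be a single positive number (ms)")
  if (width < 0.35) "fast_spiking"
  else if (width > 0.45) "pyramidal"
  else "excluded"
}

#' Peristimulus time histogram
#'
#' Spike counts pooled across trials in fixed bins aligned to an event,
#' divided by `nTrials * bin` to give Hz. Bins are half-open `[edge, next)`;
#' the default bin width is 0.1 s (100 ms).
#'
#' @param spikeTrains List of per-trial spike-time vectors, s (or a
#'   `UnitRecord`).
#' @param alignTimes Alignment event time per trial, s (recycled if scalar).
#' @param window `c(lo, hi)` window around the event, s.
#' @param bin Bin width, s.
#' @return A [`Psth`][psth-accessors] object.
#' @export
psth <- function(spikeTrains, alignTimes = 0, window = c(-1, 3), bin = 0.1) {
  if (is(spikeTrains, "UnitRecord")) spikeTrains <- spikeTrains@spikeTimes
  n <- length(spikeTrains)
  if (n == 0) stop("at least one trial is required")
  if (bin <= 0) stop("bin width must be positive")
  if (window[1] >= window[2]) stop("window must be ordered")
  alignTimes <- rep_len(alignTimes, n)
  nb <- max(1L, round((window[2] - window[1]) / bin))
  edges <- window[1] + (0:nb) * bin
  counts <- numeric(nb)
  for (i in seq_len(n)) {
    t <- spikeTrains[[i]] - alignTimes[i]
    t <- t[t >= edges[1] & t < edges[nb + 1]]
    if (length(t))
      counts <- counts + tabulate(findInterval(t, edges), nb)
  }
  new("Psth", binEdges = edges, rates = counts / (n * bin), nTrials = n)
}

#' Mean PSTH rate over a time window
#' @noRd
.meanRate <- function(p, window) {
  ctr <- (head(p@binEdges, -1) + tail(p@binEdges, -1)) / 2
  sel <- ctr >= window[1] & ctr < window[2]
  if (!any(sel)) stop("window does not cover any PSTH bin")
  mean(p@rates[sel])
}

#' Suppression and rebound modulation of a PSTH
#'
#' Ratios of the mean firing rate during the laser window and during the
#' post-laser window to the mean baseline rate. A flat PSTH gives both ratios
#' 1; strong photoinhibition gives a suppression ratio near
#' `1 - suppressionFraction`, and rebound spiking a post/baseline ratio above
#' 1.
#'
#' @param p A [`Psth`][psth-accessors].
#' @param baselineWindow,laserWindow,postWindow `c(lo, hi)` windows, s, within
#'   the PSTH range and non-overlapping.
#' @return Named list `suppression_ratio`, `rebound_ratio` (both `NA` with a
#'   warning when the baseline rate is zero).
#' @export
reboundModulation <- function(p, baselineWindow, laserWindow, postWindow) {
  rng <- range(p@binEdges)
  wins <- list(baselineWindow, laserWindow, postWindow)
  for (w in wins)
    if (w[1] < rng[1] - 1e-9 || w[2] > rng[2] + 1e-9)
      stop("window outside the PSTH range")
  ord <- wins[order(vapply(wins, `[`, 0, 1))]
  for (i in seq_len(length(ord) - 1))
    if (ord[[i]][2] > ord[[i + 1]][1] + 1e-9) stop("windows must not overlap")
  base <- .meanRate(p, baselineWindow)
  if (base <= 0) {
    warning("zero baseline rate; ratios undefined")
    return(list(suppression_ratio = NA_real_, rebound_ratio = NA_real_))
  }
  list(suppression_ratio = .meanRate(p, laserWindow) / base,
       rebound_ratio = .meanRate(p, postWindow) / base)
}

## ---------------------------------------------------------------------------
## Ephys IO
## ---------------------------------------------------------------------------

#' Read/write spike times as CSV
#'
#' Per-unit CSV with columns `trial` (1-based) and `time_s`; trials with no
#' spikes appear with zero rows but are preserved through the `nTrials`
#' attribute/argument.
#'
#' @param spikeTrains List of per-trial spike-time vectors, s.
#' @param path CSV path.
#' @param nTrials Number of trials (defaults to the list length on write, to
#'   the maximum trial index on read).
#' @return `writeSpikeTimes` returns `path` invisibly; `readSpikeTimes` the
#'   list of spike-time vectors.
#' @export
writeSpikeTimes <- function(spikeTrains, path) {
  rows <- do.call(rbind, lapply(seq_along(spikeTrains), function(i) {
    if (!length(spikeTrains[[i]])) return(NULL)
    data.frame(trial = i, time_s = spikeTrains[[i]])
  }))
  if (is.null(rows)) rows <- data.frame(trial = integer(0), time_s = numeric(0))
  attr(rows, "nTrials") <- length(spikeTrains)
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpikeTimes
#' @export
readSpikeTimes <- function(path, nTrials = NULL) {
  d <- read.csv(path)
  if (is.null(nTrials)) nTrials <- if (nrow(d)) max(d$trial) else 0
  lapply(seq_len(nTrials), function(i) sort(d$time_s[d$trial == i]))
}

#' Write a PSTH as CSV
#'
#' Columns: `bin_start_s, bin_end_s, rate_hz`.
#'
#' @param p A [`Psth`][psth-accessors].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writePsth <- function(p, path) {
  write.csv(data.frame(bin_start_s = head(p@binEdges, -1),
                       bin_end_s = tail(p@binEdges, -1),
                       rate_hz = p@rates), path, row.names = FALSE)
  invisible(path)
}
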