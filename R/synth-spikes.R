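## Inhomogeneous-Poisson spike trains with laser suppression and post-laser
## rebound, emulating cortical units under photostimulation of inhibitory
## interneurons.

#' Simulate spike trains for one unit
#'
#' Draws `nTrials` inhomogeneous Poisson spike trains with a piecewise
#' constant rate: baseline outside the laser window, suppressed to
#' `baseline * (1 - suppressionFraction)` during the laser, and elevated to
#' `baseline * reboundGain` for `reboundDurationMs` after laser offset.
#'
#' @param params A [spikeSimParams()].
#' @param seed Integer seed.
#' @return List of length `nTrials`; each element a sorted numeric vector of
#'   spike times (s).
#' @export
simulateSpikeTrains <- function(params, seed = NULL) {
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  base <- params@baselineRate
  segs <- .rateSegments(params)
  if (any(segs$rate < 0)) stop("negative firing rate in a segment")
  lapply(seq_len(params@nTrials), function(i) {
    spk <- unlist(lapply(seq_len(nrow(segs)), function(j) {
      dur <- segs$end[j] - segs$start[j]
      n <- rpois(1, segs$rate[j] * dur)
      if (n == 0) return(numeric(0))
      segs$start[j] + sort(runif(n, 0, dur))
    }))
    sort(spk)
  })
}

#' Piecewise-constant rate segments for a spike simulation
#' @noRd
.rateSegments <- function(params) {
  base <- params@baselineRate
  lw <- params@laserWindow
  if (length(lw) != 2 || any(is.na(lw))) {
    return(data.frame(start = 0, end = params@trialDuration, rate = base))
  }
  rbDur <- params@reboundDurationMs / 1000
  cuts <- sort(unique(pmin(params@trialDuration, pmax(0,
    c(0, lw[1], lw[2], lw[2] + rbDur, params@trialDuration)))))
  segs <- data.frame(start = head(cuts, -1), end = tail(cuts, -1))
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  mid <- (segs$start + segs$end) / 2
  segs$rate <- ifelse(mid >= lw[1] & mid < lw[2], base * (1 - params@suppressionFraction),
                ifelse(mid >= lw[2] & mid < lw[2] + rbDur, base * params@reboundGain,
                       base))
  segs
}

#' Expected firing rate of a spike simulation at given times
#'
#' Ground-truth rate profile of the generator, used for parameter-recovery
#' checks.
#'
#' @param params A [spikeSimParams()].
#' @param times Times, s.
#' @return Rates, Hz.
#' @export
spikeSimRate <- function(params, times) {
  segs <- .rateSegments(params)
  r <- rep(0, length(times))
  for (j in seq_len(nrow(segs)))
    r[times >= segs$start[j] & times < segs$end[j]] <- segs$rate[j]
  r
}
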