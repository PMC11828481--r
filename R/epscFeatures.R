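#' Averaged stimulus-locked trace
#'
#' Lightweight container for an averaged (or single) current trace used by
#' the feature extractors: samples in picoamperes, uniform sampling, stimulus
#' onset in seconds from trace start.
#'
#' @param current numeric vector of picoampere samples.
#' @param samplingInterval sampling interval in seconds.
#' @param stimulusOnset stimulus time in seconds from trace start.
#' @return an object of class `epsc_trace`.
#' @export
epscTrace <- function(current, samplingInterval, stimulusOnset) {
  stopifnot(length(current) > 0L, samplingInterval > 0,
            stimulusOnset >= 0,
            stimulusOnset < length(current) * samplingInterval)
  structure(list(current = as.numeric(current),
                 samplingInterval = samplingInterval,
                 stimulusOnset = stimulusOnset),
            class = "epsc_trace")
}

#' @rdname epscTrace
#' @param x an `epsc_trace`.
#' @return `traceTimes`: sample times in seconds from trace start.
#' @export
traceTimes <- function(x) {
  (seq_along(x$current) - 1L) * x$samplingInterval
}

.asTrace <- function(x) {
  if (inherits(x, "epsc_trace")) return(x)
  if (is(x, "Sweep")) {
    return(epscTrace(x@current, x@samplingInterval, x@stimulusOnset))
  }
  stop("expected an epsc_trace or Sweep")
}

.windowIdx <- function(trace, from, to, relativeToStimulus = TRUE) {
  t0 <- if (relativeToStimulus) trace$stimulusOnset else 0
  tt <- traceTimes(trace)
  idx <- which(tt >= t0 + from & tt <= t0 + to)
  if (length(idx) == 0L) {
    stop(sprintf("window [%g, %g] s lies outside the trace", from, to))
  }
  idx
}

#' Pointwise average of a cell's sweeps
#'
#' Averages a group of sweeps recorded at one holding potential. At least
#' `minSweeps` sweeps (default 10, the minimum used for amplitude analysis)
#' with identical sampling interval, stimulus onset and length are required.
#'
#' @param sweeps list of [Sweep-class] (or `epsc_trace`) objects.
#' @param minSweeps minimum number of sweeps required (default 10).
#' @return an `epsc_trace` holding the pointwise mean.
#' @export
averageSweeps <- function(sweeps, minSweeps = 10) {
  if (length(sweeps) < minSweeps) {
    stop("InsufficientSweeps: need at least ", minSweeps,
         " sweeps, got ", length(sweeps))
  }
  traces <- lapply(sweeps, .asTrace)
  si <- vapply(traces, `[[`, numeric(1L), "samplingInterval")
  on <- vapply(traces, `[[`, numeric(1L), "stimulusOnset")
  nn <- vapply(traces, function(t) length(t$current), integer(1L))
  if (length(unique(si)) > 1L || length(unique(on)) > 1L ||
      length(unique(nn)) > 1L) {
    stop("sweeps must share sampling interval, stimulus onset and length")
  }
  avg <- rowMeans(vapply(traces, `[[`, numeric(nn[1L]), "current"))
  epscTrace(avg, si[1L], on[1L])
}

#' Subtract the pre-stimulus baseline from a trace
#'
#' Subtracts the mean current over a baseline window ending at (or before)
#' the stimulus onset, so that amplitudes are measured from baseline.
#'
#' @param trace an `epsc_trace` or [Sweep-class].
#' @param baselineWindow length-2 numeric, window in seconds from trace start
#'   (default: trace start to stimulus onset).
#' @return the baseline-subtracted `epsc_trace`.
#' @export
subtractBaseline <- function(trace, baselineWindow = NULL) {
  trace <- .asTrace(trace)
  if (is.null(baselineWindow)) {
    baselineWindow <- c(0, trace$stimulusOnset)
  }
  if (baselineWindow[2L] > trace$stimulusOnset + 1e-12) {
    stop("baseline window must end at or before the stimulus onset")
  }
  idx <- .windowIdx(trace, baselineWindow[1L], baselineWindow[2L],
                    relativeToStimulus = FALSE)
  trace$current <- trace$current - mean(trace$current[idx])
  trace
}

#' Baseline noise SD of a trace
#'
#' @inheritParams subtractBaseline
#' @return SD of the samples in the baseline window, in picoamperes.
#' @export
baselineNoiseSd <- function(trace, baselineWindow = NULL) {
  trace <- .asTrace(trace)
  if (is.null(baselineWindow)) baselineWindow <- c(0, trace$stimulusOnset)
  idx <- .windowIdx(trace, baselineWindow[1L], baselineWindow[2L],
                    relativeToStimulus = FALSE)
  stats::sd(trace$current[idx])
}

# Centred boxcar moving average via cumulative sums (matrix columns or a
# vector); incomplete edge windows are filled with the unsmoothed samples.
# Alignment matches a centred convolution: for even widths the window extends
# one sample further forward in time.
.movingAverage <- function(M, w) {
  vec <- is.null(dim(M))
  if (vec) M <- matrix(M, ncol = 1L)
  n <- nrow(M)
  lo <- if (w %% 2L) (w - 1L) %/% 2L else w %/% 2L - 1L
  hi <- w - 1L - lo
  S <- rbind(0, apply(M, 2L, cumsum))
  out <- M
  i <- (lo + 1L):(n - hi)
  out[i, ] <- (S[i + hi + 1L, , drop = FALSE] - S[i - lo, , drop = FALSE]) / w
  if (vec) out[, 1L] else out
}

.smoothCurrent <- function(current, width) {
  if (width <= 1L) return(current)
  .movingAverage(current, as.integer(width))
}

#' AMPA peak amplitude of an averaged -90 mV trace
#'
#' Finds the peak inward (negative) current within a response window after
#' the stimulus on a baseline-subtracted averaged trace. The peak must exceed
#' `k` times the baseline noise SD to count as a response; otherwise the cell
#' is flagged `NO_RESPONSE`. The first millisecond after the stimulus is
#' excluded by default to blank the stimulus artifact.
#'
#' @param trace baseline-subtracted averaged -90 mV `epsc_trace`.
#' @param responseWindow length-2 numeric, seconds after stimulus onset
#'   (default `c(0.001, 0.020)`).
#' @param noiseSd baseline noise SD in pA; estimated from the trace's
#'   baseline when `NULL`.
#' @param k detection threshold in noise SDs (default 3).
#' @return a list with `amplitude` (pA, magnitude of the inward peak),
#'   `latency` (seconds after stimulus onset) and `noResponse` (logical).
#'   When no response is detected, amplitude and latency are `NA`.
#' @export
ampaPeak <- function(trace, responseWindow = c(1e-3, 20e-3),
                     noiseSd = NULL, k = 3) {
  trace <- .asTrace(trace)
  if (is.null(noiseSd)) noiseSd <- baselineNoiseSd(trace)
  idx <- .windowIdx(trace, responseWindow[1L], responseWindow[2L])
  i <- idx[which.min(trace$current[idx])]
  peak <- trace$current[i]
  if (!(peak < 0) || abs(peak) <= k * noiseSd) {
    return(list(amplitude = NA_real_, latency = NA_real_, noResponse = TRUE))
  }
  list(amplitude = abs(peak),
       latency = traceTimes(trace)[i] - trace$stimulusOnset,
       noResponse = FALSE)
}

#' Detect polysynaptic responses at -90 mV
#'
#' Flags traces with two or more prominent inward deflections separated in
#' time; such multi-peaked responses indicate recruitment of polysynaptic
#' pathways and are excluded from the AMPA/NMDA analysis. Events are counted
#' with hysteresis: an event opens when the smoothed trace drops below
#' `-prominence` and closes when it recovers above half that level, so noise
#' ripples riding on one EPSC flank are not counted as extra peaks. A second
#' event only counts when it starts at least `separationMin` after the
#' previous one.
#'
#' @param trace baseline-subtracted averaged -90 mV `epsc_trace`.
#' @param separationMin minimum separation between event onsets in seconds
#'   (default 5 ms).
#' @param prominence minimum inward deflection in pA; by default the largest
#'   of 5 baseline-noise SDs, `relativeProminence` times the principal peak
#'   magnitude (so the criterion scales with the response), and
#'   `minProminence`.
#' @param relativeProminence fraction of the principal peak used for the
#'   default prominence (default 0.1).
#' @param minProminence absolute floor on the default prominence
#'   (default 2 pA).
#' @param searchWindow window (seconds after stimulus) scanned for peaks;
#'   defaults to the 1-25 ms epoch where mono- and polysynaptic AMPA
#'   responses occur.
#' @param smoothWidthS boxcar smoothing width in seconds applied before event
#'   counting (default 0.5 ms).
#' @return `TRUE` when the trace is polysynaptic.
#' @export
detectPolysynaptic <- function(trace, separationMin = 5e-3, prominence = NULL,
                               relativeProminence = 0.1, minProminence = 2,
                               searchWindow = c(1e-3, 25e-3),
                               smoothWidthS = 0.5e-3) {
  trace <- .asTrace(trace)
  if (is.null(prominence)) {
    mainPeak <- max(0, -min(trace$current))
    prominence <- max(5 * baselineNoiseSd(trace),
                      relativeProminence * mainPeak,
                      minProminence)
  }
  idx <- .windowIdx(trace, searchWindow[1L], searchWindow[2L])
  w <- max(1L, round(smoothWidthS / trace$samplingInterval))
  y <- .smoothCurrent(trace$current, w)[idx]
  tt <- traceTimes(trace)[idx]
  active <- FALSE
  starts <- numeric()
  for (i in seq_along(y)) {
    if (!active && y[i] < -prominence) {
      active <- TRUE
      starts <- c(starts, tt[i])
    } else if (active && y[i] > -prominence / 2) {
      active <- FALSE
    }
  }
  if (length(starts) < 2L) return(FALSE)
  counted <- starts[1L]
  for (s in starts[-1L]) {
    if (s - counted[length(counted)] >= separationMin) counted <- c(counted, s)
  }
  length(counted) >= 2L
}

#' NMDA current of an averaged +50 mV trace
#'
#' Measures the outward NMDA current at +50 mV in a short window placed
#' 40 ms after the AMPA peak of the same cell's -90 mV response (window
#' anchor and width configurable). By default the mean over the window is
#' returned; `pointEstimate = TRUE` instead samples the window centre.
#'
#' @param trace baseline-subtracted averaged +50 mV `epsc_trace`.
#' @param ampaPeakLatency AMPA peak latency in seconds after stimulus onset,
#'   from the same cell's -90 mV analysis.
#' @param delay window start relative to the AMPA peak (default 40 ms).
#' @param window window width (default 5 ms).
#' @param pointEstimate measure at the window centre instead of the mean.
#' @return NMDA current in picoamperes (outward positive).
#' @export
nmdaAmplitude <- function(trace, ampaPeakLatency, delay = 40e-3,
                          window = 5e-3, pointEstimate = FALSE) {
  trace <- .asTrace(trace)
  from <- ampaPeakLatency + delay
  to <- from + window
  dur <- length(trace$current) * trace$samplingInterval
  if (trace$stimulusOnset + to > dur) {
    stop("NMDA window extends beyond the end of the trace")
  }
  if (pointEstimate) {
    mid <- trace$stimulusOnset + (from + to) / 2
    i <- which.min(abs(traceTimes(trace) - mid))
    return(trace$current[i])
  }
  idx <- .windowIdx(trace, from, to)
  mean(trace$current[idx])
}

#' AMPA/NMDA EPSC ratio
#'
#' @param ampaAmplitude AMPA peak magnitude (pA) at -90 mV.
#' @param nmdaAmplitude NMDA window current (pA) at +50 mV.
#' @return the dimensionless ratio.
#' @export
ampaNmdaRatio <- function(ampaAmplitude, nmdaAmplitude) {
  if (!is.finite(nmdaAmplitude) || nmdaAmplitude <= 0) {
    stop("UndefinedRatio: NMDA amplitude must be positive")
  }
  if (!is.finite(ampaAmplitude) || ampaAmplitude <= 0) {
    stop("UndefinedRatio: AMPA amplitude must be positive")
  }
  ampaAmplitude / nmdaAmplitude
}

#' Series-resistance stability QC
#'
#' A recording is flagged when the series resistance changes by more than
#' `maxChange` (strictly greater than, default 25%) across its sweeps,
#' measured as (max - min)/min. Missing values leave the flag unset with a
#' warning.
#'
#' @param recording a [CellRecording-class].
#' @param maxChange maximal tolerated relative change (default 0.25).
#' @return `TRUE` when the recording fails the QC.
#' @export
qcSeriesResistance <- function(recording, maxChange = 0.25) {
  rs <- vapply(c(recording@sweepsMinus90, recording@sweepsPlus50),
               slot, numeric(1L), "seriesResistance")
  rs <- rs[is.finite(rs)]
  if (length(rs) < 2L) {
    warning("series resistance missing for cell ", recording@cellId,
            "; QC flag not set")
    return(FALSE)
  }
  (max(rs) - min(rs)) / min(rs) > maxChange
}

#' Extract per-cell EPSC features
#'
#' Runs the full amplitude analysis for one recording: averages at least
#' `minSweeps` sweeps per potential, subtracts baselines, measures the AMPA
#' peak at -90 mV and the NMDA window current at +50 mV (window anchored
#' `nmdaDelay` after the AMPA peak), applies the QC rules (series-resistance
#' drift, polysynaptic responses, no detectable response) and computes the
#' AMPA/NMDA ratio for clean cells.
#'
#' @param recording a [CellRecording-class].
#' @param responseWindow AMPA search window, seconds after stimulus.
#' @param nmdaDelay,nmdaWindow NMDA window anchor delay and width (seconds).
#' @param k detection threshold in baseline-noise SDs.
#' @param minSweeps minimum sweeps per potential.
#' @param nmdaPointEstimate measure the NMDA window centre instead of the
#'   window mean.
#' @return one-row data.frame with columns `cell_id`, `condition`,
#'   `ampa_amplitude`, `ampa_peak_latency`, `nmda_amplitude`,
#'   `ampa_nmda_ratio`, `qc_flags` (comma-separated, empty when clean).
#' @export
epscFeatures <- function(recording, responseWindow = c(1e-3, 20e-3),
                         nmdaDelay = 40e-3, nmdaWindow = 5e-3, k = 3,
                         minSweeps = 10, nmdaPointEstimate = FALSE) {
  flags <- character()
  if (qcSeriesResistanceQuiet(recording)) flags <- c(flags, "SERIES_RESISTANCE_DRIFT")
  avg90 <- subtractBaseline(averageSweeps(recording@sweepsMinus90, minSweeps))
  avg50 <- subtractBaseline(averageSweeps(recording@sweepsPlus50, minSweeps))
  if (detectPolysynaptic(avg90)) flags <- c(flags, "POLYSYNAPTIC")
  pk <- ampaPeak(avg90, responseWindow = responseWindow, k = k)
  if (pk$noResponse) flags <- c(flags, "NO_RESPONSE")
  nmda <- if (pk$noResponse) NA_real_ else {
    nmdaAmplitude(avg50, pk$latency, delay = nmdaDelay, window = nmdaWindow,
                  pointEstimate = nmdaPointEstimate)
  }
  ratio <- NA_real_
  if (length(flags) == 0L && isTRUE(pk$amplitude > 0) && isTRUE(nmda > 0)) {
    ratio <- pk$amplitude / nmda
  }
  data.frame(
    cell_id = recording@cellId,
    condition = recording@condition,
    ampa_amplitude = pk$amplitude,
    ampa_peak_latency = pk$latency,
    nmda_amplitude = nmda,
    ampa_nmda_ratio = ratio,
    qc_flags = paste(flags, collapse = ","),
    stringsAsFactors = FALSE)
}

qcSeriesResistanceQuiet <- function(recording, maxChange = 0.25) {
  suppressWarnings(qcSeriesResistance(recording, maxChange))
}

#' @rdname epscFeatures
#' @param recordings list of [CellRecording-class].
#' @param ... passed to `epscFeatures`.
#' @return `epscFeatureTable`: data.frame with one row per cell.
#' @export
epscFeatureTable <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, epscFeatures, ...))
}
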