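#' Classify a minimal-stimulation sweep as success or failure
#'
#' Decides whether a single sweep contains an evoked response. The sweep is
#' baseline-subtracted, boxcar-smoothed, and the extremum in the response
#' window in the expected direction (inward at -90 mV, outward at +50 mV) is
#' compared against `k` times the noise SD of the smoothed baseline.
#'
#' @param sweep a [Sweep-class] (or `epsc_trace` plus explicit `potential`).
#' @param noiseSd noise SD of the decision statistic in pA (smoothed-trace
#'   noise plus baseline-offset uncertainty); estimated from the sweep's own
#'   baseline when `NULL`.
#' @param k threshold in noise SDs (default 3).
#' @param responseWindow seconds after stimulus onset searched for a
#'   response; defaults to 1-20 ms at -90 mV and 1-50 ms at +50 mV (the NMDA
#'   response rises slowly).
#' @param smoothWidthS boxcar width in seconds; defaults to 1 ms at -90 mV
#'   and 4 ms at +50 mV, roughly matching the AMPA and NMDA kinetics.
#' @param potential holding potential; taken from the sweep when `NULL`.
#' @return `TRUE` for a success, `FALSE` for a failure.
#' @export
classifySuccess <- function(sweep, noiseSd = NULL, k = 3,
                            responseWindow = NULL, smoothWidthS = NULL,
                            potential = NULL) {
  if (is.null(potential)) {
    if (!is(sweep, "Sweep")) stop("potential must be given for bare traces")
    potential <- sweep@holdingPotential
  }
  raw <- .asTrace(sweep)
  trace <- subtractBaseline(raw)
  if (is.null(responseWindow)) {
    responseWindow <- if (potential < 0) c(1e-3, 20e-3) else c(1e-3, 50e-3)
  }
  if (is.null(smoothWidthS)) {
    smoothWidthS <- if (potential < 0) 1e-3 else 4e-3
  }
  w <- max(1L, round(smoothWidthS / trace$samplingInterval))
  sm <- trace
  sm$current <- .smoothCurrent(trace$current, w)
  if (is.null(noiseSd)) {
    baseIdx <- .windowIdx(trace, 0, trace$stimulusOnset,
                          relativeToStimulus = FALSE)
    # smoothed-noise variance plus the variance of the subtracted baseline mean
    noiseSd <- sqrt(baselineNoiseSd(sm)^2 +
                      baselineNoiseSd(trace)^2 / length(baseIdx))
  }
  idx <- .windowIdx(sm, responseWindow[1L], responseWindow[2L])
  y <- sm$current[idx]
  extremum <- if (potential < 0) -min(y) else max(y)
  isTRUE(extremum > k * noiseSd)
}

#' Classify all sweeps of one group at once
#'
#' Vectorized equivalent of applying [classifySuccess()] to every sweep of a
#' cell at one holding potential: the sweeps (which share sampling interval,
#' stimulus onset and length) are stacked into a matrix and
#' baseline-subtracted, smoothed, and thresholded column-wise.
#'
#' @inheritParams classifySuccess
#' @param sweeps list of [Sweep-class] objects at one potential.
#' @return logical vector, one entry per sweep.
#' @export
classifySweeps <- function(sweeps, noiseSd = NULL, k = 3,
                           responseWindow = NULL, smoothWidthS = NULL,
                           potential = NULL) {
  if (length(sweeps) == 0L) return(logical())
  if (is.null(potential)) potential <- sweeps[[1L]]@holdingPotential
  if (is.null(responseWindow)) {
    responseWindow <- if (potential < 0) c(1e-3, 20e-3) else c(1e-3, 50e-3)
  }
  if (is.null(smoothWidthS)) {
    smoothWidthS <- if (potential < 0) 1e-3 else 4e-3
  }
  proto <- .asTrace(sweeps[[1L]])
  M <- vapply(sweeps, function(s) s@current,
              numeric(length(proto$current)))
  baseIdx <- .windowIdx(proto, 0, proto$stimulusOnset,
                        relativeToStimulus = FALSE)
  respIdx <- .windowIdx(proto, responseWindow[1L], responseWindow[2L])
  M <- M - rep(colMeans(M[baseIdx, , drop = FALSE]), each = nrow(M))
  w <- max(1L, round(smoothWidthS / proto$samplingInterval))
  SM <- if (w > 1L) .movingAverage(M, w) else M
  if (is.null(noiseSd)) {
    B <- SM[baseIdx, , drop = FALSE]
    B <- B - rep(colMeans(B), each = nrow(B))
    smVar <- colSums(B * B) / (nrow(B) - 1L)
    R0 <- M[baseIdx, , drop = FALSE]
    R0 <- R0 - rep(colMeans(R0), each = nrow(R0))
    rawVar <- colSums(R0 * R0) / (nrow(R0) - 1L)
    noiseSd <- sqrt(smVar + rawVar / length(baseIdx))
  }
  R <- SM[respIdx, , drop = FALSE]
  ext <- if (potential < 0) {
    ii <- max.col(-t(R), ties.method = "first")
    -R[cbind(ii, seq_len(ncol(R)))]
  } else {
    ii <- max.col(t(R), ties.method = "first")
    R[cbind(ii, seq_len(ncol(R)))]
  }
  as.logical(ext > k * noiseSd)
}

#' Failure rate from classified sweeps
#'
#' @param successes logical vector, one entry per stimulus (`TRUE` =
#'   response detected).
#' @return a list with `nStimuli`, `nFailures` and `failureRate`
#'   (= failures / stimuli, exactly).
#' @export
failureRate <- function(successes) {
  if (length(successes) == 0L) stop("failure rate needs at least one stimulus")
  stopifnot(is.logical(successes), !anyNA(successes))
  nFail <- sum(!successes)
  list(nStimuli = length(successes), nFailures = nFail,
       failureRate = nFail / length(successes))
}

#' Correct the +50 mV failure rate
#'
#' The raw failure rate at +50 mV overestimates the true rate (the
#' +50/-90 failure-rate ratio cannot exceed 1 under constant release
#' probability, yet uncorrected sleep-deprived data show ~1.3, attributable
#' to decreased input resistance at depolarized holding potentials). The raw
#' rate is therefore divided by a correction factor, 1.3 by default, applied
#' identically in all sleep conditions, and clamped to [0, 1].
#'
#' @param frPlus50Raw raw failure rate at +50 mV, in [0, 1].
#' @param factor correction factor, must be >= 1 (default 1.3).
#' @return the corrected failure rate.
#' @export
correctFrPlus50 <- function(frPlus50Raw, factor = 1.3) {
  if (any(!is.finite(factor)) || any(factor < 1)) {
    stop("correction factor must be >= 1")
  }
  if (any(frPlus50Raw < 0 | frPlus50Raw > 1)) {
    stop("failure rates must lie in [0, 1]")
  }
  pmin(1, frPlus50Raw / factor)
}

#' Silent/active synapse ratio from matched failure rates
#'
#' Under the binomial release model (every stimulus activates the same
#' terminals, each releasing independently with constant probability p), the
#' failure probabilities are FR(-90) = (1-p)^As and FR(+50) = (1-p)^(As+Ss),
#' where As counts active (AMPA + NMDA) and Ss silent (NMDA-only) synapses.
#' Hence ln FR(+50) / ln FR(-90) = (As+Ss)/As = 1 + Ss/As, and the estimator
#' returns Ss/As = ln FR(+50)/ln FR(-90) - 1 together with the plain
#' failure-rate ratio FRR = FR(+50)/FR(-90).
#'
#' @param frMinus90 failure rate at -90 mV, strictly in (0, 1).
#' @param frPlus50Corrected corrected failure rate at +50 mV, strictly in
#'   (0, 1) (see [correctFrPlus50()]).
#' @return list with `frr`, `logRatio` and `ssOverAs`.
#' @examples
#' # As = 2 active, Ss = 3 silent, p = 0.3: FRs are 0.7^2 and 0.7^5
#' silentFraction(0.49, 0.16807)$ssOverAs   # 1.5
#' @export
silentFraction <- function(frMinus90, frPlus50Corrected) {
  for (fr in c(frMinus90, frPlus50Corrected)) {
    if (!is.finite(fr) || fr <= 0 || fr >= 1) {
      stop("DegenerateFailureRate: estimator needs failure rates strictly ",
           "inside (0, 1), got ", fr)
    }
  }
  logRatio <- log(frPlus50Corrected) / log(frMinus90)
  list(frr = frPlus50Corrected / frMinus90,
       logRatio = logRatio,
       ssOverAs = logRatio - 1)
}

# Pooled decision-noise SD across all sweeps of one group: smoothed-baseline
# variance plus the variance of the per-sweep baseline-mean subtraction.
.pooledNoiseSd <- function(sweeps, smoothWidthS = 1e-3) {
  proto <- .asTrace(sweeps[[1L]])
  M <- vapply(sweeps, function(s) s@current, numeric(length(proto$current)))
  baseIdx <- .windowIdx(proto, 0, proto$stimulusOnset,
                        relativeToStimulus = FALSE)
  pooledVar <- function(X) {
    X <- X[stats::complete.cases(X), , drop = FALSE]
    X <- X - rep(colMeans(X), each = nrow(X))
    sum(X * X) / (ncol(X) * (nrow(X) - 1L))
  }
  rawVar <- pooledVar(M[baseIdx, , drop = FALSE])
  w <- max(1L, round(smoothWidthS / proto$samplingInterval))
  if (w > 1L) M <- .movingAverage(M, w)
  smVar <- pooledVar(M[baseIdx, , drop = FALSE])
  sqrt(smVar + rawVar / length(baseIdx))
}

# Measurement window centred on the evoked-response latency of the averaged
# trace, clipped to the broad search window.
.responseWindowFromAverage <- function(sweeps, potential, halfWidthS,
                                       smoothWidthS = 1e-3) {
  broad <- if (potential < 0) c(1e-3, 20e-3) else c(1e-3, 50e-3)
  avg <- subtractBaseline(averageSweeps(sweeps, minSweeps = 1))
  w <- max(1L, round(smoothWidthS / avg$samplingInterval))
  avg$current <- .smoothCurrent(avg$current, w)
  idx <- .windowIdx(avg, broad[1L], broad[2L])
  y <- avg$current[idx]
  i <- if (potential < 0) which.min(y) else which.max(y)
  lat <- traceTimes(avg)[idx[i]] - avg$stimulusOnset
  c(max(broad[1L], lat - halfWidthS), min(broad[2L], lat + halfWidthS))
}

#' Per-cell failure rates and silent-synapse estimates from recordings
#'
#' Classifies every minimal-stimulation sweep at both potentials, computes
#' raw failure rates, applies the +50 mV correction, and evaluates the
#' silent-synapse estimator per cell. Cells whose corrected failure rates hit
#' an endpoint (0 or 1, where the log-ratio estimator diverges) get
#' `qc_flags = "DEGENERATE_FR"` and `NA` estimates rather than an imputed
#' value.
#'
#' Classification pools the baseline-noise estimate across all sweeps of a
#' cell at one potential and measures within a narrow window (half-width
#' `responseHalfWidthS`) centred on the evoked-response latency of the
#' averaged trace, which keeps the false-success rate of the threshold
#' detector low; both choices can be overridden by passing `noiseSd` or
#' `responseWindow` through `...`.
#'
#' @param recordings list of [CellRecording-class].
#' @param correctionFactor +50 mV failure-rate correction (default 1.3).
#' @param k classification threshold in noise SDs (default 3).
#' @param responseHalfWidthS half-width of the measurement window around the
#'   averaged-trace response latency, in seconds (default 2 ms).
#' @param ... further arguments for [classifySweeps()].
#' @return data.frame with one row per cell: counts, raw/corrected failure
#'   rates, `frr`, `log_ratio`, `ss_over_as` and `qc_flags`.
#' @export
silentSynapseTable <- function(recordings, correctionFactor = 1.3, k = 3,
                               responseHalfWidthS = 2e-3, ...) {
  extras <- list(...)
  classify <- function(sweeps, potential) {
    width <- if (!is.null(extras$smoothWidthS)) extras$smoothWidthS
             else if (potential < 0) 1e-3 else 4e-3
    args <- list(sweeps = sweeps, k = k, potential = potential)
    if (!"noiseSd" %in% names(extras)) {
      args$noiseSd <- .pooledNoiseSd(sweeps, smoothWidthS = width)
    }
    if (!"responseWindow" %in% names(extras)) {
      args$responseWindow <- .responseWindowFromAverage(
        sweeps, potential, responseHalfWidthS, smoothWidthS = width)
    }
    do.call(classifySweeps, c(args, extras))
  }
  rows <- lapply(recordings, function(rec) {
    s90 <- classify(rec@sweepsMinus90, -90)
    s50 <- classify(rec@sweepsPlus50, +50)
    fr90 <- failureRate(s90)
    fr50 <- failureRate(s50)
    corr <- correctFrPlus50(fr50$failureRate, correctionFactor)
    degenerate <- fr90$failureRate <= 0 || fr90$failureRate >= 1 ||
      corr <= 0 || corr >= 1
    est <- if (degenerate) {
      list(frr = NA_real_, logRatio = NA_real_, ssOverAs = NA_real_)
    } else {
      silentFraction(fr90$failureRate, corr)
    }
    data.frame(
      cell_id = rec@cellId,
      condition = rec@condition,
      n_stimuli_minus90 = fr90$nStimuli,
      n_failures_minus90 = fr90$nFailures,
      n_stimuli_plus50 = fr50$nStimuli,
      n_failures_plus50 = fr50$nFailures,
      fr_minus90 = fr90$failureRate,
      fr_plus50_raw = fr50$failureRate,
      fr_plus50_corrected = corr,
      correction_factor = correctionFactor,
      frr = est$frr,
      log_ratio = est$logRatio,
      ss_over_as = est$ssOverAs,
      qc_flags = if (degenerate) "DEGENERATE_FR" else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Silent-synapse estimates from a published failure-rate table
#'
#' Runs the correction and estimator directly on a per-cell failure-rate
#' table (columns `cell_id`, `condition`, `fr_minus90`, `fr_plus50`), e.g. a
#' published source-data table, bypassing sweep classification.
#'
#' @param frTable data.frame or path to a delimited file with the columns
#'   above; `fr_plus50` is taken as the raw (uncorrected) rate unless
#'   `alreadyCorrected = TRUE`.
#' @param correctionFactor +50 mV correction factor (default 1.3).
#' @param alreadyCorrected set when `fr_plus50` is already corrected.
#' @return list with `cells` (per-cell estimates) and `summary`
#'   (per-condition summary from [conditionSummary()]).
#' @export
silentFromTable <- function(frTable, correctionFactor = 1.3,
                            alreadyCorrected = FALSE) {
  if (is.character(frTable)) frTable <- readFeatureTable(frTable)
  required <- c("cell_id", "condition", "fr_minus90", "fr_plus50")
  missingCols <- setdiff(required, names(frTable))
  if (length(missingCols)) {
    stop("failure-rate table is missing columns: ",
         paste(missingCols, collapse = ", "))
  }
  corr <- if (alreadyCorrected) frTable$fr_plus50 else {
    correctFrPlus50(frTable$fr_plus50, correctionFactor)
  }
  est <- lapply(seq_len(nrow(frTable)), function(i) {
    f90 <- frTable$fr_minus90[i]
    f50 <- corr[i]
    if (f90 <= 0 || f90 >= 1 || f50 <= 0 || f50 >= 1) {
      list(frr = NA_real_, logRatio = NA_real_, ssOverAs = NA_real_,
           degenerate = TRUE)
    } else {
      c(silentFraction(f90, f50), degenerate = FALSE)
    }
  })
  cells <- data.frame(
    cell_id = frTable$cell_id,
    condition = frTable$condition,
    fr_minus90 = frTable$fr_minus90,
    fr_plus50_raw = frTable$fr_plus50,
    fr_plus50_corrected = corr,
    correction_factor = if (alreadyCorrected) NA_real_ else correctionFactor,
    frr = vapply(est, `[[`, numeric(1L), "frr"),
    log_ratio = vapply(est, `[[`, numeric(1L), "logRatio"),
    ss_over_as = vapply(est, `[[`, numeric(1L), "ssOverAs"),
    qc_flags = ifelse(vapply(est, `[[`, logical(1L), "degenerate"),
                      "DEGENERATE_FR", ""),
    stringsAsFactors = FALSE)
  list(cells = cells, summary = conditionSummary(cells))
}

#' Per-condition summary of silent-synapse estimates
#'
#' Aggregates per-cell results in both orders, since a condition-level Ss/As
#' can be formed either way: (i) mean and SEM of the per-cell estimates, and
#' (ii) the estimator evaluated on the condition-mean failure rates (pooled).
#' Cells flagged degenerate are excluded from the per-cell means but their
#' failure rates still enter the condition means.
#'
#' @param cellTable per-cell table from [silentSynapseTable()] or
#'   [silentFromTable()].
#' @return data.frame with one row per condition: `n_cells`,
#'   `mean_ss_over_as`, `sem_ss_over_as`, `mean_frr`, `sem_frr`,
#'   `mean_fr_minus90`, `mean_fr_plus50_corrected`, `mean_fr_plus50_raw`,
#'   `pooled_ss_over_as`, `pooled_frr`, `pooled_frr_raw`.
#' @export
conditionSummary <- function(cellTable) {
  conds <- intersect(SLEEP_CONDITIONS, unique(cellTable$condition))
  extra <- setdiff(unique(cellTable$condition), SLEEP_CONDITIONS)
  conds <- c(conds, extra)
  rows <- lapply(conds, function(cond) {
    sub <- cellTable[cellTable$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("condition ", cond, " has no cells; omitted")
      return(NULL)
    }
    ss <- sub$ss_over_as[is.finite(sub$ss_over_as)]
    frr <- sub$frr[is.finite(sub$frr)]
    m90 <- mean(sub$fr_minus90)
    m50c <- mean(sub$fr_plus50_corrected)
    m50r <- mean(sub$fr_plus50_raw)
    pooled <- if (m90 > 0 && m90 < 1 && m50c > 0 && m50c < 1) {
      silentFraction(m90, m50c)
    } else {
      list(frr = NA_real_, ssOverAs = NA_real_)
    }
    sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    data.frame(
      condition = cond,
      n_cells = nrow(sub),
      mean_ss_over_as = if (length(ss)) mean(ss) else NA_real_,
      sem_ss_over_as = sem(ss),
      mean_frr = if (length(frr)) mean(frr) else NA_real_,
      sem_frr = sem(frr),
      mean_fr_minus90 = m90,
      mean_fr_plus50_corrected = m50c,
      mean_fr_plus50_raw = m50r,
      pooled_ss_over_as = pooled$ssOverAs,
      pooled_frr = pooled$frr,
      pooled_frr_raw = m50r / m90,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
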