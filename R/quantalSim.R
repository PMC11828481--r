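#' Normalized synaptic conductance waveform
#'
#' Difference-of-exponentials waveform, normalized to unit peak, evaluated at
#' times `t` (seconds) after release onset; zero for `t < 0`.
#'
#' @param t numeric vector of times in seconds.
#' @param rise,decay rise and decay time constants in seconds (decay > rise).
#' @return numeric vector of the same length as `t`.
#' @export
synapticWaveform <- function(t, rise, decay) {
  stopifnot(decay > rise, rise > 0)
  tPeak <- log(decay / rise) * rise * decay / (decay - rise)
  norm <- exp(-tPeak / decay) - exp(-tPeak / rise)
  out <- ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / norm)
  out
}

#' Miss probability matching a target +50 mV failure-rate inflation
#'
#' Computes the per-stimulus probability that a true success at +50 mV is
#' scored as a failure such that the expected raw failure rate equals
#' `factor` times the true binomial failure rate (1-p)^(As+Ss). This is the
#' generator-side counterpart of [correctFrPlus50()].
#'
#' @param pop a [SynapsePopulation-class].
#' @param factor target multiplicative inflation of the raw +50 mV failure
#'   rate (default 1.3).
#' @return the miss probability in [0, 1).
#' @export
plus50InflationFor <- function(pop, factor = 1.3) {
  stopifnot(factor >= 1)
  f50 <- (1 - pop@pRelease)^(pop@nActive + pop@nSilent)
  if (factor * f50 > 1) {
    stop("target inflation is infeasible: factor * FR(+50) exceeds 1")
  }
  if (f50 >= 1) return(0)
  (factor - 1) * f50 / (1 - f50)
}

.quantalSums <- function(k, q, cv) {
  # total amplitude contributed by k released quanta of mean size q
  if (cv <= 0) return(k * q)
  out <- numeric(length(k))
  pos <- which(k > 0)
  if (length(pos)) {
    draws <- pmax(0, rnorm(sum(k[pos]), mean = q, sd = cv * q))
    out[pos] <- vapply(split(draws, rep(seq_along(pos), k[pos])),
                       sum, numeric(1L))
  }
  out
}

#' Simulate one minimal-stimulation recording
#'
#' Draws independent binomial release for every terminal at every stimulus
#' and synthesizes stimulus-locked sweeps at -90 mV and +50 mV. At -90 mV the
#' current is the inward AMPA response of released active synapses plus the
#' magnesium-attenuated NMDA tail of all released synapses; at +50 mV it is
#' the outward NMDA response of all released synapses plus the
#' driving-force-attenuated AMPA component of released active synapses, each
#' with additive Gaussian noise. A true success at +50 mV is omitted from the
#' trace with probability `pop@plus50Inflation`, emulating the overestimation
#' of the +50 mV failure rate.
#'
#' @param pop a [SynapsePopulation-class].
#' @param kin a [KineticParams-class].
#' @param nStimuli number of stimuli per holding potential.
#' @param cellId,condition,animalId labels for the resulting recording.
#' @param seed optional integer seed (set before any drawing).
#' @param samplingInterval sampling interval in seconds (default 2e-4, 5 kHz).
#' @param traceDuration sweep length in seconds (default 0.12).
#' @param stimulusOnset stimulus time within the sweep (default 0.02 s).
#' @param seriesResistance baseline series resistance in megaohms.
#' @return list with `recording` (a [CellRecording-class]) and `truth`, a
#'   data.frame logging, per stimulus and potential, the number of released
#'   active and total synapses and whether a response is present in the
#'   trace (`evoked`; at +50 mV this is the post-miss indicator).
#' @export
simulateCell <- function(pop, kin = KineticParams(), nStimuli,
                         cellId = "cell1", condition = "CS",
                         animalId = NA_character_, seed = NULL,
                         samplingInterval = 2e-4, traceDuration = 0.12,
                         stimulusOnset = 0.02, seriesResistance = 10) {
  stopifnot(nStimuli >= 1)
  validObject(pop)
  validObject(kin)
  if (!is.null(seed)) set.seed(seed)
  nSamples <- round(traceDuration / samplingInterval)
  tt <- (seq_len(nSamples) - 1L) * samplingInterval - stimulusOnset
  wA <- synapticWaveform(tt, kin@ampaRise, kin@ampaDecay)
  wN <- synapticWaveform(tt, kin@nmdaRise, kin@nmdaDecay)

  makeSweeps <- function(potential) {
    relA <- rbinom(nStimuli, pop@nActive, pop@pRelease)
    relS <- rbinom(nStimuli, pop@nSilent, pop@pRelease)
    relT <- relA + relS
    ampA <- .quantalSums(relA, pop@qAmpa, pop@quantalCv)
    ampN <- .quantalSums(relT, pop@qNmda, pop@quantalCv)
    evoked <- relT > 0
    if (potential > 0 && pop@plus50Inflation > 0) {
      missed <- runif(nStimuli) < pop@plus50Inflation
      suppress <- evoked & missed
      ampA[suppress] <- 0
      ampN[suppress] <- 0
      evoked <- evoked & !missed
    }
    signal <- if (potential < 0) {
      -(outer(wA, ampA) + kin@mgBlockFactor * outer(wN, ampN))
    } else {
      outer(wN, ampN) + kin@ampaDrivingFactor * outer(wA, ampA)
    }
    if (pop@noiseSd > 0) {
      signal <- signal + matrix(rnorm(nSamples * nStimuli, sd = pop@noiseSd),
                                nSamples, nStimuli)
    }
    rs <- seriesResistance * (1 + 0.01 * cumsum(rnorm(nStimuli, sd = 0.1)))
    # clone a validated prototype instead of re-validating every sweep
    proto <- Sweep(cellId, 0L, potential, samplingInterval, stimulusOnset,
                   signal[, 1L], rs[1L])
    sweeps <- lapply(seq_len(nStimuli), function(i) {
      s <- proto
      s@sweepIndex <- i - 1L
      s@current <- signal[, i]
      s@seriesResistance <- rs[i]
      s
    })
    list(sweeps = sweeps,
         truth = data.frame(
           cell_id = cellId, condition = condition,
           holding_potential = potential,
           stimulus = seq_len(nStimuli) - 1L,
           n_released_active = relA,
           n_released_total = relT,
           evoked = evoked,
           stringsAsFactors = FALSE))
  }

  m90 <- makeSweeps(-90)
  p50 <- makeSweeps(+50)
  rec <- CellRecording(cellId, condition,
                       sweepsMinus90 = m90$sweeps, sweepsPlus50 = p50$sweeps,
                       animalId = animalId)
  list(recording = rec, truth = rbind(m90$truth, p50$truth))
}

#' Default three-condition cohort design
#'
#' Ground-truth populations for the three sleep conditions: control sleep and
#' recovery sleep carry silent synapses (As = 5, Ss = 7, Ss/As = 1.4) while
#' sleep deprivation has none (As = 5, Ss = 0) and a larger quantal AMPA
#' amplitude, reflecting sleep-loss synaptic strengthening. Release
#' probability is 0.15 per terminal, noise 2 pA, and the +50 mV miss
#' probability is set per condition so the expected raw +50 mV failure rate
#' is inflated by `inflationFactor` (matching the 1.3 correction).
#'
#' @param inflationFactor target raw +50 mV failure-rate inflation
#'   (default 1.3; 1 disables the miss process).
#' @param noiseSd recording noise SD in pA.
#' @return named list of [SynapsePopulation-class] for CS, SD, RS.
#' @export
defaultCohortDesign <- function(inflationFactor = 1.3, noiseSd = 2) {
  mk <- function(nActive, nSilent, qAmpa) {
    pop <- SynapsePopulation(nActive, nSilent, pRelease = 0.15,
                             qAmpa = qAmpa, qNmda = 10, noiseSd = noiseSd)
    pop@plus50Inflation <- plus50InflationFor(pop, inflationFactor)
    pop
  }
  list(CS = mk(5L, 7L, 10),
       SD = mk(5L, 0L, 14),
       RS = mk(5L, 7L, 10))
}

.cellSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 7919) %% 2147483647)
}

#' Simulate a three-condition cohort
#'
#' Simulates `nCells` cells per condition from the per-condition ground-truth
#' populations, optionally writing the sweeps and manifest to disk in the
#' format read by [readSweeps()]. Per-cell random substreams are derived
#' deterministically from `seed`.
#'
#' @param design named list of [SynapsePopulation-class], one per condition
#'   (default [defaultCohortDesign()]).
#' @param nCells cells per condition (default 6).
#' @param nStimuli stimuli per holding potential (default 300).
#' @param seed integer seed.
#' @param dir output directory; when `NULL` the cohort stays in memory.
#' @param kin a [KineticParams-class].
#' @param ... further arguments for [simulateCell()].
#' @return list with `recordings` (list of [CellRecording-class]), `truth`
#'   (per-cell planted parameters and closed-form expected failure rates) and
#'   `manifest` (manifest path, or `NULL` for in-memory cohorts).
#' @export
simulateCohort <- function(design = defaultCohortDesign(), nCells = 6,
                           nStimuli = 300, seed = 1, dir = NULL,
                           kin = KineticParams(), ...) {
  recordings <- list()
  truthRows <- list()
  idx <- 0L
  for (cond in names(design)) {
    pop <- design[[cond]]
    for (j in seq_len(nCells)) {
      idx <- idx + 1L
      cid <- sprintf("%s_%02d", cond, j)
      sim <- simulateCell(pop, kin, nStimuli, cellId = cid, condition = cond,
                          animalId = sprintf("%s_animal%d", cond, 1L + (j - 1L) %/% 2L),
                          seed = .cellSeed(seed, idx), ...)
      recordings[[cid]] <- sim$recording
      f90 <- (1 - pop@pRelease)^pop@nActive
      f50 <- (1 - pop@pRelease)^(pop@nActive + pop@nSilent)
      truthRows[[cid]] <- data.frame(
        cell_id = cid, condition = cond,
        n_active = pop@nActive, n_silent = pop@nSilent,
        p_release = pop@pRelease,
        ss_over_as = pop@nSilent / pop@nActive,
        expected_fr_minus90 = f90,
        expected_fr_plus50 = f50,
        expected_fr_plus50_raw = f50 + (1 - f50) * pop@plus50Inflation,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truthRows)) {
    out <- do.call(rbind, truthRows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(cell_id = character(), condition = character(),
               n_active = integer(), n_silent = integer(),
               p_release = numeric(), ss_over_as = numeric(),
               expected_fr_minus90 = numeric(),
               expected_fr_plus50 = numeric(),
               expected_fr_plus50_raw = numeric())
  }
  manifest <- NULL
  if (!is.null(dir)) {
    manifest <- writeSweeps(recordings, dir)
    writeFeatureTable(truth, file.path(dir, "truth.tsv"))
  }
  list(recordings = recordings, truth = truth, manifest = manifest)
}

#' Release-level cohort simulation (no traces)
#'
#' Draws the same binomial release process as [simulateCohort()] but records
#' only the per-stimulus success/failure outcome (with the +50 mV miss
#' process applied), skipping waveform synthesis. This is the generator's own
#' bookkeeping level: the returned failure rates are exactly the empirical
#' binomial rates an ideal classifier would recover.
#'
#' @inheritParams simulateCohort
#' @return per-cell failure-rate table with the same columns as
#'   [silentSynapseTable()].
#' @param correctionFactor +50 mV correction applied to the raw rate.
#' @export
simulateCohortOutcomes <- function(design = defaultCohortDesign(), nCells = 6,
                                   nStimuli = 300, seed = 1,
                                   correctionFactor = 1.3) {
  rows <- list()
  idx <- 0L
  for (cond in names(design)) {
    pop <- design[[cond]]
    for (j in seq_len(nCells)) {
      idx <- idx + 1L
      set.seed(.cellSeed(seed, idx))
      cid <- sprintf("%s_%02d", cond, j)
      s90 <- rbinom(nStimuli, pop@nActive, pop@pRelease) > 0
      relT <- rbinom(nStimuli, pop@nActive + pop@nSilent, pop@pRelease)
      s50 <- relT > 0
      if (pop@plus50Inflation > 0) {
        s50 <- s50 & (runif(nStimuli) >= pop@plus50Inflation)
      }
      fr90 <- failureRate(s90)
      fr50 <- failureRate(s50)
      corr <- correctFrPlus50(fr50$failureRate, correctionFactor)
      degenerate <- fr90$failureRate <= 0 || fr90$failureRate >= 1 ||
        corr <= 0 || corr >= 1
      est <- if (degenerate) {
        list(frr = NA_real_, logRatio = NA_real_, ssOverAs = NA_real_)
      } else silentFraction(fr90$failureRate, corr)
      rows[[cid]] <- data.frame(
        cell_id = cid, condition = cond,
        n_stimuli_minus90 = fr90$nStimuli, n_failures_minus90 = fr90$nFailures,
        n_stimuli_plus50 = fr50$nStimuli, n_failures_plus50 = fr50$nFailures,
        fr_minus90 = fr90$failureRate, fr_plus50_raw = fr50$failureRate,
        fr_plus50_corrected = corr, correction_factor = correctionFactor,
        frr = est$frr, log_ratio = est$logRatio, ss_over_as = est$ssOverAs,
        qc_flags = if (degenerate) "DEGENERATE_FR" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Closed-form expectations from a cohort truth table
#'
#' @param truth truth table from [simulateCohort()].
#' @return per-condition data.frame of planted Ss/As and expected failure
#'   rates (exact closed forms from the planted parameters).
#' @export
truthSummary <- function(truth) {
  if (nrow(truth) == 0L) {
    return(data.frame(condition = character(), ss_over_as = numeric(),
                      expected_fr_minus90 = numeric(),
                      expected_fr_plus50 = numeric(),
                      expected_fr_plus50_raw = numeric()))
  }
  conds <- unique(truth$condition)
  do.call(rbind, lapply(conds, function(cond) {
    sub <- truth[truth$condition == cond, , drop = FALSE]
    data.frame(condition = cond,
               ss_over_as = mean(sub$ss_over_as),
               expected_fr_minus90 = mean(sub$expected_fr_minus90),
               expected_fr_plus50 = mean(sub$expected_fr_plus50),
               expected_fr_plus50_raw = mean(sub$expected_fr_plus50_raw),
               stringsAsFactors = FALSE)
  }))
}
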