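#' @import methods
#' @importFrom stats rbinom rgamma rnbinom rnorm runif
NULL

SLEEP_CONDITIONS <- c("CS", "SD", "RS")

#' Single stimulus-locked voltage-clamp sweep
#'
#' One current trace recorded at a fixed holding potential, time-locked to an
#' extracellular stimulus. Current is stored with physiological sign (inward
#' negative) in picoamperes; times are in seconds from the start of the trace.
#'
#' @slot cellId character, recorded cell identifier.
#' @slot sweepIndex integer, zero-based index within the cell/potential.
#' @slot holdingPotential numeric, holding potential in millivolts (analysis
#'   supports -90 and +50).
#' @slot samplingInterval numeric, uniform sampling interval in seconds.
#' @slot stimulusOnset numeric, stimulus time in seconds from trace start.
#' @slot current numeric vector of current samples in picoamperes.
#' @slot seriesResistance numeric, series resistance in megaohms (`NA` when
#'   not recorded for this sweep).
#' @exportClass Sweep
setClass("Sweep",
  representation(
    cellId = "character",
    sweepIndex = "integer",
    holdingPotential = "numeric",
    samplingInterval = "numeric",
    stimulusOnset = "numeric",
    current = "numeric",
    seriesResistance = "numeric"
  ),
  prototype(seriesResistance = NA_real_)
)

setValidity("Sweep", function(object) {
  msg <- character()
  if (length(object@current) == 0L) {
    msg <- c(msg, "current trace must be non-empty")
  }
  if (length(object@samplingInterval) != 1L || !is.finite(object@samplingInterval) ||
      object@samplingInterval <= 0) {
    msg <- c(msg, "samplingInterval must be a single positive number")
  }
  dur <- length(object@current) * object@samplingInterval
  if (length(object@stimulusOnset) != 1L || !is.finite(object@stimulusOnset) ||
      object@stimulusOnset < 0 || object@stimulusOnset >= dur) {
    msg <- c(msg, "stimulusOnset must lie within [0, trace duration)")
  }
  if (length(object@sweepIndex) != 1L || is.na(object@sweepIndex) ||
      object@sweepIndex < 0L) {
    msg <- c(msg, "sweepIndex must be a single non-negative integer")
  }
  if (length(msg)) msg else TRUE
})

#' Sweeps of one cell grouped by holding potential
#'
#' All sweeps recorded from one neuron under one sleep condition, split by
#' holding potential (-90 mV for the AMPA-dominated response, +50 mV for the
#' NMDA-dominated response). All sweeps at one potential must share sampling
#' interval and stimulus onset.
#'
#' @slot cellId character identifier.
#' @slot animalId character identifier of the source animal.
#' @slot condition character, one of `"CS"`, `"SD"`, `"RS"` (control sleep,
#'   sleep deprivation, recovery sleep).
#' @slot sweepsMinus90 list of [Sweep-class] at -90 mV.
#' @slot sweepsPlus50 list of [Sweep-class] at +50 mV.
#' @exportClass CellRecording
setClass("CellRecording",
  representation(
    cellId = "character",
    animalId = "character",
    condition = "character",
    sweepsMinus90 = "list",
    sweepsPlus50 = "list"
  )
)

.checkSweepGroup <- function(sweeps, potential, label) {
  msg <- character()
  if (!all(vapply(sweeps, is, logical(1L), "Sweep"))) {
    return(sprintf("%s must contain only Sweep objects", label))
  }
  if (length(sweeps) == 0L) return(character())
  vh <- vapply(sweeps, slot, numeric(1L), "holdingPotential")
  if (!all(vh == potential)) {
    msg <- c(msg, sprintf("%s sweeps must all be held at %g mV", label, potential))
  }
  si <- vapply(sweeps, slot, numeric(1L), "samplingInterval")
  on <- vapply(sweeps, slot, numeric(1L), "stimulusOnset")
  if (length(unique(si)) > 1L) {
    msg <- c(msg, sprintf("%s sweeps have mixed sampling intervals", label))
  }
  if (length(unique(on)) > 1L) {
    msg <- c(msg, sprintf("%s sweeps have mixed stimulus onsets", label))
  }
  msg
}

setValidity("CellRecording", function(object) {
  msg <- character()
  if (!object@condition %in% SLEEP_CONDITIONS) {
    msg <- c(msg, "condition must be one of CS, SD, RS")
  }
  msg <- c(msg,
           .checkSweepGroup(object@sweepsMinus90, -90, "sweepsMinus90"),
           .checkSweepGroup(object@sweepsPlus50, +50, "sweepsPlus50"))
  if (length(msg)) msg else TRUE
})

#' Ground-truth synapse population for the release simulator
#'
#' Parameters of the binomial release model: `nActive` synapses carry both
#' AMPA and NMDA receptors and respond at -90 mV; `nSilent` synapses carry
#' NMDA receptors only and respond only at +50 mV. Each terminal releases
#' independently with probability `pRelease` per stimulus, so the failure
#' probability is (1 - pRelease)^nActive at -90 mV and
#' (1 - pRelease)^(nActive + nSilent) at +50 mV.
#'
#' @slot nActive integer, number of active (AMPA + NMDA) synapses.
#' @slot nSilent integer, number of silent (NMDA-only) synapses.
#' @slot pRelease numeric in (0, 1), release probability per terminal per
#'   stimulus.
#' @slot qAmpa numeric, quantal AMPA amplitude at -90 mV in picoamperes.
#' @slot qNmda numeric, quantal NMDA amplitude at +50 mV in picoamperes.
#' @slot quantalCv numeric, coefficient of variation of quantal amplitudes
#'   (0 disables quantal variability).
#' @slot noiseSd numeric, Gaussian recording-noise SD in picoamperes.
#' @slot plus50Inflation numeric in [0, 1): probability that a true success
#'   at +50 mV is scored as a failure, modelling the overestimation of the
#'   +50 mV failure rate by decreased input resistance at depolarized
#'   potentials.
#' @seealso [plus50InflationFor()] to derive the miss probability that
#'   inflates the expected raw +50 mV failure rate by a given factor.
#' @exportClass SynapsePopulation
setClass("SynapsePopulation",
  representation(
    nActive = "integer",
    nSilent = "integer",
    pRelease = "numeric",
    qAmpa = "numeric",
    qNmda = "numeric",
    quantalCv = "numeric",
    noiseSd = "numeric",
    plus50Inflation = "numeric"
  ),
  prototype(
    nActive = 5L, nSilent = 7L, pRelease = 0.15,
    qAmpa = 10, qNmda = 10, quantalCv = 0,
    noiseSd = 2, plus50Inflation = 0
  )
)

setValidity("SynapsePopulation", function(object) {
  msg <- character()
  if (object@nActive < 0L || object@nSilent < 0L ||
      object@nActive + object@nSilent < 1L) {
    msg <- c(msg, "need nActive >= 0, nSilent >= 0 and at least one synapse")
  }
  if (!is.finite(object@pRelease) || object@pRelease <= 0 || object@pRelease >= 1) {
    msg <- c(msg, "pRelease must lie strictly in (0, 1)")
  }
  if (object@qAmpa <= 0 || object@qNmda <= 0) {
    msg <- c(msg, "quantal amplitudes must be positive")
  }
  if (object@quantalCv < 0) msg <- c(msg, "quantalCv must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@plus50Inflation < 0 || object@plus50Inflation >= 1) {
    msg <- c(msg, "plus50Inflation must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Synaptic current kinetics for the sweep simulator
#'
#' Difference-of-exponential waveform parameters and the two cross-potential
#' attenuation factors: magnesium block suppresses the NMDA component at
#' -90 mV, and the reduced AMPA driving force suppresses the AMPA component
#' at +50 mV (the NMDA reversal potential is ~0 mV, so NMDA currents are
#' outward at +50 mV).
#'
#' @slot ampaRise,ampaDecay numeric, AMPA rise/decay time constants (seconds).
#' @slot nmdaRise,nmdaDecay numeric, NMDA rise/decay time constants (seconds).
#' @slot mgBlockFactor numeric in [0, 1], residual NMDA conductance at -90 mV.
#' @slot ampaDrivingFactor numeric in [0, 1], residual AMPA conductance at
#'   +50 mV.
#' @exportClass KineticParams
setClass("KineticParams",
  representation(
    ampaRise = "numeric",
    ampaDecay = "numeric",
    nmdaRise = "numeric",
    nmdaDecay = "numeric",
    mgBlockFactor = "numeric",
    ampaDrivingFactor = "numeric"
  ),
  prototype(
    ampaRise = 0.5e-3, ampaDecay = 3e-3,
    nmdaRise = 5e-3, nmdaDecay = 80e-3,
    mgBlockFactor = 0.02, ampaDrivingFactor = 0.1
  )
)

setValidity("KineticParams", function(object) {
  msg <- character()
  if (!(object@ampaDecay > object@ampaRise && object@ampaRise > 0)) {
    msg <- c(msg, "need ampaDecay > ampaRise > 0")
  }
  if (!(object@nmdaDecay > object@nmdaRise && object@nmdaRise > 0)) {
    msg <- c(msg, "need nmdaDecay > nmdaRise > 0")
  }
  if (object@mgBlockFactor < 0 || object@mgBlockFactor > 1 ||
      object@ampaDrivingFactor < 0 || object@ampaDrivingFactor > 1) {
    msg <- c(msg, "attenuation factors must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
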