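#' Constructors and accessors for the ephys domain classes
#'
#' `Sweep()`, `CellRecording()`, `SynapsePopulation()` and `KineticParams()`
#' construct validated objects; the accessors below read their core fields.
#'
#' @param cellId,animalId character identifiers.
#' @param sweepIndex non-negative integer index of the sweep.
#' @param holdingPotential holding potential in mV.
#' @param samplingInterval sampling interval in seconds.
#' @param stimulusOnset stimulus time in seconds from trace start.
#' @param current numeric vector of picoampere samples (inward negative).
#' @param seriesResistance series resistance in megaohms, `NA` if unknown.
#' @return the constructed object.
#' @examples
#' sw <- Sweep("c1", 0L, -90, 1e-4, 0.01, rnorm(200))
#' holdingPotential(sw)
#' @export
Sweep <- function(cellId, sweepIndex, holdingPotential, samplingInterval,
                  stimulusOnset, current, seriesResistance = NA_real_) {
  new("Sweep",
      cellId = as.character(cellId),
      sweepIndex = as.integer(sweepIndex),
      holdingPotential = as.numeric(holdingPotential),
      samplingInterval = as.numeric(samplingInterval),
      stimulusOnset = as.numeric(stimulusOnset),
      current = as.numeric(current),
      seriesResistance = as.numeric(seriesResistance))
}

#' @rdname Sweep
#' @param condition sleep condition, one of `"CS"`, `"SD"`, `"RS"`.
#' @param sweepsMinus90,sweepsPlus50 lists of [Sweep-class] objects at
#'   -90 mV and +50 mV respectively.
#' @export
CellRecording <- function(cellId, condition, sweepsMinus90 = list(),
                          sweepsPlus50 = list(), animalId = NA_character_) {
  new("CellRecording",
      cellId = as.character(cellId),
      animalId = as.character(animalId),
      condition = as.character(condition),
      sweepsMinus90 = sweepsMinus90,
      sweepsPlus50 = sweepsPlus50)
}

#' @rdname Sweep
#' @param nActive,nSilent counts of active and silent synapses.
#' @param pRelease per-terminal release probability per stimulus.
#' @param qAmpa,qNmda quantal amplitudes (pA) at -90 / +50 mV.
#' @param quantalCv coefficient of variation of quantal amplitudes.
#' @param noiseSd recording noise SD (pA).
#' @param plus50Inflation probability that a true success at +50 mV is
#'   scored as a failure.
#' @export
SynapsePopulation <- function(nActive, nSilent, pRelease, qAmpa = 10,
                              qNmda = 10, quantalCv = 0, noiseSd = 2,
                              plus50Inflation = 0) {
  new("SynapsePopulation",
      nActive = as.integer(nActive), nSilent = as.integer(nSilent),
      pRelease = as.numeric(pRelease), qAmpa = as.numeric(qAmpa),
      qNmda = as.numeric(qNmda), quantalCv = as.numeric(quantalCv),
      noiseSd = as.numeric(noiseSd),
      plus50Inflation = as.numeric(plus50Inflation))
}

#' @rdname Sweep
#' @param ampaRise,ampaDecay,nmdaRise,nmdaDecay time constants in seconds.
#' @param mgBlockFactor residual NMDA conductance at -90 mV, in [0, 1].
#' @param ampaDrivingFactor residual AMPA conductance at +50 mV, in [0, 1].
#' @export
KineticParams <- function(ampaRise = 0.5e-3, ampaDecay = 3e-3,
                          nmdaRise = 5e-3, nmdaDecay = 80e-3,
                          mgBlockFactor = 0.02, ampaDrivingFactor = 0.1) {
  new("KineticParams",
      ampaRise = ampaRise, ampaDecay = ampaDecay,
      nmdaRise = nmdaRise, nmdaDecay = nmdaDecay,
      mgBlockFactor = mgBlockFactor, ampaDrivingFactor = ampaDrivingFactor)
}

#' @rdname Sweep
#' @param object a package object.
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))
#' @rdname Sweep
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname Sweep
#' @export
setGeneric("holdingPotential", function(object) standardGeneric("holdingPotential"))
#' @rdname Sweep
#' @export
setGeneric("sweepCurrent", function(object) standardGeneric("sweepCurrent"))
#' @rdname Sweep
#' @export
setGeneric("sweeps", function(object, potential) standardGeneric("sweeps"))
#' @rdname Sweep
#' @export
setGeneric("silentActiveRatio", function(object) standardGeneric("silentActiveRatio"))

#' @rdname Sweep
#' @export
setMethod("cellId", "Sweep", function(object) object@cellId)
#' @rdname Sweep
#' @export
setMethod("cellId", "CellRecording", function(object) object@cellId)
#' @rdname Sweep
#' @export
setMethod("condition", "CellRecording", function(object) object@condition)
#' @rdname Sweep
#' @export
setMethod("holdingPotential", "Sweep", function(object) object@holdingPotential)
#' @rdname Sweep
#' @export
setMethod("sweepCurrent", "Sweep", function(object) object@current)

#' @rdname Sweep
#' @param potential -90 or +50, selecting the sweep group.
#' @export
setMethod("sweeps", "CellRecording", function(object, potential) {
  if (potential == -90) object@sweepsMinus90
  else if (potential == 50) object@sweepsPlus50
  else stop("potential must be -90 or 50")
})

#' @rdname Sweep
#' @export
setMethod("silentActiveRatio", "SynapsePopulation", function(object) {
  object@nSilent / object@nActive
})

setMethod("show", "Sweep", function(object) {
  cat(sprintf("Sweep %s #%d @ %+g mV: %d samples @ %g kHz, stimulus %.1f ms\n",
              object@cellId, object@sweepIndex, object@holdingPotential,
              length(object@current), 1e-3 / object@samplingInterval,
              1e3 * object@stimulusOnset))
})

setMethod("show", "CellRecording", function(object) {
  cat(sprintf("CellRecording %s [%s]: %d sweeps @ -90 mV, %d sweeps @ +50 mV\n",
              object@cellId, object@condition,
              length(object@sweepsMinus90), length(object@sweepsPlus50)))
})

setMethod("show", "SynapsePopulation", function(object) {
  cat(sprintf(
    "SynapsePopulation: As=%d Ss=%d (Ss/As=%.3g), p=%.3g, q=%.3g/%.3g pA, noise %.3g pA\n",
    object@nActive, object@nSilent,
    if (object@nActive > 0) object@nSilent / object@nActive else NA_real_,
    object@pRelease, object@qAmpa, object@qNmda, object@noiseSd))
})
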