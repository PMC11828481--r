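# shared fixture builders (all generated in code, nothing on disk)

# a sweep with constant current
constSweep <- function(value, n = 200, dt = 2e-4, onset = 0.01,
                       potential = -90, cellId = "c1", idx = 0L, rs = 10) {
  Sweep(cellId, idx, potential, dt, onset, rep(value, n), rs)
}

# a sweep/trace with alpha-like deflections: peaks is a data.frame with
# columns t (s after stimulus) and amp (pA, signed)
deflectionTrace <- function(peaks, n = 500, dt = 2e-4, onset = 0.01,
                            rise = 0.5e-3, decay = 3e-3) {
  tt <- (seq_len(n) - 1L) * dt
  cur <- numeric(n)
  for (i in seq_len(nrow(peaks))) {
    cur <- cur + peaks$amp[i] *
      synapticWaveform(tt - onset - peaks$t[i], rise, decay)
  }
  epscTrace(cur, dt, onset)
}

# recording with given per-sweep series resistances and flat sweeps
rsRecording <- function(rsValues, potential = -90) {
  sweeps <- lapply(seq_along(rsValues), function(i) {
    constSweep(0, idx = i - 1L, potential = potential, rs = rsValues[i])
  })
  if (potential < 0) {
    CellRecording("c1", "CS", sweepsMinus90 = sweeps)
  } else {
    CellRecording("c1", "CS", sweepsPlus50 = sweeps)
  }
}

# independently coded BKY two-stage evaluation: literal, loop-based
# transcription of the two-stage definition (stage 1 BH at q/(1+q) to
# estimate m0, stage 2 BH at q' * m / m0)
bkyOracle <- function(p, q) {
  m <- length(p)
  qp <- q / (1 + q)
  bhReject <- function(pv, level) {
    o <- order(pv)
    k <- 0L
    for (i in seq_len(m)) {
      if (pv[o[i]] <= i * level / m) k <- i
    }
    rej <- rep(FALSE, m)
    if (k > 0L) rej[o[1:k]] <- TRUE
    rej
  }
  s1 <- bhReject(p, qp)
  r1 <- sum(s1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bhReject(p, qp * m / (m - r1))
}

# noise-free simulator settings for oracle checks: no quantal variability,
# no cross-potential leak, no +50 miss process
idealKinetics <- function() {
  KineticParams(mgBlockFactor = 0, ampaDrivingFactor = 0)
}

# scaled-down transcriptome design (fewer genes, same cells per type and
# sample layout as the full default, so per-type UMI summaries keep their
# sampling precision); overrides merge over these defaults
smallTranscriptomeDesign <- function(...) {
  args <- list(nGenes = 800L, nCellsPerType = 50L, nDeg = 200L,
               exprRange = list(ExIT = c(0.5, 0.7),
                                ExCT = c(0.45, 0.55),
                                IN = c(0.38, 0.5),
                                NonNeuronal = c(0.3, 0.38)))
  args[names(list(...))] <- list(...)
  do.call(transcriptomeDesign, args)
}
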