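test_that("averaging sweeps is idempotent and symmetric", {
  sw <- constSweep(3)
  avg <- averageSweeps(rep(list(sw), 10))
  expect_equal(avg$current, sweepCurrent(sw))

  mixed <- c(rep(list(constSweep(1)), 5), rep(list(constSweep(-1)), 5))
  expect_equal(averageSweeps(mixed)$current, rep(0, 200))

  expect_error(averageSweeps(rep(list(sw), 9)), "InsufficientSweeps")
})

test_that("baseline subtraction zeroes the baseline and shifts peaks", {
  tr <- epscTrace(rep(5, 200), 2e-4, 0.01)
  out <- subtractBaseline(tr)
  expect_equal(out$current, rep(0, 200))

  tr2 <- deflectionTrace(data.frame(t = 5e-3, amp = -104))
  tr2$current <- tr2$current + 2
  out2 <- subtractBaseline(tr2)
  expect_equal(min(out2$current), min(tr2$current) - 2, tolerance = 1e-12)
  expect_equal(mean(out2$current[1:50]), 0, tolerance = 1e-12)

  set.seed(3)
  noisy <- epscTrace(rnorm(300) + 17.3, 2e-4, 0.01)
  sub <- subtractBaseline(noisy)
  base <- which(traceTimes(sub) <= 0.01)
  expect_lt(abs(mean(sub$current[base])), 1e-9)

  expect_error(subtractBaseline(tr, c(0, 0.02)), "stimulus onset")
})

test_that("AMPA peak detection returns magnitude and latency or NO_RESPONSE", {
  flat <- epscTrace(rep(0, 500), 2e-4, 0.01)
  res <- ampaPeak(flat, noiseSd = 1)
  expect_true(res$noResponse)

  tr <- deflectionTrace(data.frame(t = 5e-3, amp = -120))
  res <- ampaPeak(tr, noiseSd = 2)
  expect_false(res$noResponse)
  # waveform peaks slightly after onset; magnitude is |min| on the grid
  expect_equal(res$amplitude, max(-tr$current), tolerance = 1e-12)
  expect_lt(abs(res$latency - (5e-3 + log(3 / 0.5) * 0.5e-3 * 3e-3 / 2.5e-3)),
            3e-4)

  # amplitude within 3 SE of the binomial-release expectation
  pop <- SynapsePopulation(3, 0, pRelease = 0.3, qAmpa = 10, noiseSd = 2)
  sim <- simulateCell(pop, idealKinetics(), nStimuli = 200, seed = 11)
  avg <- subtractBaseline(averageSweeps(sim$recording@sweepsMinus90))
  res <- ampaPeak(avg)
  se <- sqrt((10^2 * 3 * 0.3 * 0.7 + 2^2) / 200)
  expect_lt(abs(res$amplitude - 3 * 0.3 * 10), 3 * se + 0.2)
})

test_that("polysynaptic traces are flagged only for separated peaks", {
  single <- deflectionTrace(data.frame(t = 5e-3, amp = -80))
  expect_false(detectPolysynaptic(single, prominence = 5))

  double <- deflectionTrace(data.frame(t = c(5e-3, 20e-3), amp = c(-80, -80)))
  expect_true(detectPolysynaptic(double, prominence = 5))

  close <- deflectionTrace(data.frame(t = c(5e-3, 6e-3), amp = c(-80, -80)))
  expect_false(detectPolysynaptic(close, prominence = 5))
})

test_that("NMDA amplitude is the mean over the delayed window", {
  flat <- epscTrace(rep(80, 500), 2e-4, 0.01)
  expect_equal(nmdaAmplitude(flat, ampaPeakLatency = 2e-3), 80)
  zero <- epscTrace(rep(0, 500), 2e-4, 0.01)
  expect_equal(nmdaAmplitude(zero, ampaPeakLatency = 2e-3), 0)

  # oracle: the generator waveform averaged over the same window (allow one
  # grid sample of slack at the float window boundaries)
  tr <- deflectionTrace(data.frame(t = 0, amp = 90), rise = 5e-3, decay = 80e-3)
  lat <- 2e-3
  got <- nmdaAmplitude(tr, lat)
  tt <- traceTimes(tr)
  idx <- which(tt >= 0.01 + lat + 40e-3 & tt <= 0.01 + lat + 45e-3)
  expect_equal(got, mean(tr$current[idx]), tolerance = 5e-3)

  # point-estimate variant samples the window centre
  pt <- nmdaAmplitude(tr, lat, pointEstimate = TRUE)
  mid <- which.min(abs(tt - (0.01 + lat + 42.5e-3)))
  expect_equal(pt, tr$current[mid], tolerance = 5e-3)

  expect_error(nmdaAmplitude(tr, ampaPeakLatency = 0.2), "beyond")
})

test_that("the AMPA/NMDA ratio follows its definition and rejects degenerate input", {
  expect_equal(ampaNmdaRatio(100, 100), 1)
  expect_equal(ampaNmdaRatio(150, 50), 3)
  expect_error(ampaNmdaRatio(100, 0), "UndefinedRatio")
})

test_that("series-resistance drift above 25% is flagged, boundary exclusive", {
  expect_false(qcSeriesResistance(rsRecording(rep(10, 12))))
  expect_true(qcSeriesResistance(rsRecording(seq(10, 12.6, length.out = 12))))
  expect_false(qcSeriesResistance(rsRecording(seq(10, 12.5, length.out = 12))))
  expect_warning(got <- qcSeriesResistance(rsRecording(rep(NA_real_, 12))),
                 "missing")
  expect_false(got)
})

test_that("the AMPA/NMDA ratio is invariant to common trace scaling", {
  pop <- SynapsePopulation(4, 2, pRelease = 0.4, noiseSd = 1)
  sim <- simulateCell(pop, nStimuli = 40, seed = 5)
  feat1 <- epscFeatures(sim$recording)
  scaled <- sim$recording
  scaleSweeps <- function(sweeps, c) lapply(sweeps, function(s) {
    s@current <- s@current * c
    s
  })
  scaled@sweepsMinus90 <- scaleSweeps(scaled@sweepsMinus90, 2.5)
  scaled@sweepsPlus50 <- scaleSweeps(scaled@sweepsPlus50, 2.5)
  feat2 <- epscFeatures(scaled)
  expect_equal(feat2$ampa_nmda_ratio, feat1$ampa_nmda_ratio, tolerance = 1e-12)
})

test_that("averaging commutes with baseline subtraction", {
  set.seed(8)
  sweeps <- lapply(0:9, function(i) {
    Sweep("c1", i, -90, 2e-4, 0.01, rnorm(300, mean = i), 10)
  })
  a <- subtractBaseline(averageSweeps(sweeps))
  b <- averageSweeps(lapply(sweeps, function(s) subtractBaseline(s)))
  expect_equal(a$current, b$current, tolerance = 1e-12)
})

test_that("with zero noise the extracted amplitudes equal ground truth on the grid", {
  pop <- SynapsePopulation(2, 3, pRelease = 0.3, qAmpa = 10, qNmda = 8,
                           noiseSd = 0)
  sim <- simulateCell(pop, idealKinetics(), nStimuli = 100, seed = 2)
  tr <- sim$truth
  avg90 <- subtractBaseline(averageSweeps(sim$recording@sweepsMinus90))
  res <- ampaPeak(avg90, noiseSd = 0)
  meanRel <- mean(tr$n_released_active[tr$holding_potential == -90])
  tt <- traceTimes(avg90) - avg90$stimulusOnset
  gridPeak <- max(synapticWaveform(tt[tt >= 1e-3 & tt <= 20e-3],
                                   0.5e-3, 3e-3))
  expect_equal(res$amplitude, meanRel * 10 * gridPeak, tolerance = 1e-9)
})
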