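---
title: "Quantal silent-synapse analysis and the cell-type DEG census: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal silent-synapse analysis and the cell-type DEG census: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synphen)
```

# The scientific problem

Cortical glutamatergic synapses come in two functional flavours. *Active*
synapses (As) carry both AMPA and NMDA receptors and respond at resting or
hyperpolarized potentials. *Silent* synapses (Ss) carry NMDA receptors only:
at −90 mV their NMDA conductance is blocked by Mg²⁺, so they produce no
current, but at +50 mV the block is relieved and they respond. The balance
between the two populations indexes the plastic potential of a circuit —
silent synapses are the substrate that LTP converts into active ones.

`synphen` implements two measurements of this balance from whole-cell
voltage-clamp recordings of layer 2/3 pyramidal neurons under three sleep
conditions (control sleep CS, sleep deprivation SD, recovery sleep RS),
plus the transcriptomic census that accompanies them:

1. the **AMPA/NMDA EPSC ratio** from averaged evoked responses, and
2. the **silent/active ratio Ss/As** from matched failure rates under
   minimal stimulation,
3. a **cell-type census of differentially expressed genes** (DEGs) from
   single-nucleus count data, with conditional DEG probabilities and
   curated gene-set enrichment.

# The binomial failure-rate model

Minimal stimulation recruits a small, fixed set of presynaptic terminals.
The model assumes (i) every stimulus activates the same terminals, (ii)
each terminal releases independently with a constant probability
$p_{\mathrm{release}}$, and (iii) a failure occurs when no activated
terminal releases. Then

$$\mathrm{FR}_{-90} = (1-p)^{A_s}, \qquad
  \mathrm{FR}_{+50} = (1-p)^{A_s+S_s},$$

so that

$$\frac{\ln \mathrm{FR}_{+50}}{\ln \mathrm{FR}_{-90}}
  = \frac{A_s+S_s}{A_s} = 1 + \frac{S_s}{A_s}.$$

`silentFraction()` evaluates this estimator; it is exact on the grid of
closed-form failure probabilities (the test suite verifies all
$A_s \in 1..4$, $S_s \in 0..6$, $p \in \{0.1, 0.3, 0.5\}$ to $10^{-12}$).
The estimator is undefined when either failure rate is 0 or 1 (the log
diverges); such cells are flagged `DEGENERATE_FR` and excluded rather than
imputed.

**The 1.3 correction.** Under the model the failure-rate ratio
$\mathrm{FR}_{+50}/\mathrm{FR}_{-90}$ cannot exceed 1, yet uncorrected
sleep-deprived data sit near 1.3 — the +50 mV rate is overestimated,
plausibly because input resistance drops at depolarized potentials and
small successes are missed. `correctFrPlus50()` therefore divides the raw
+50 mV rate by 1.3 in *all* conditions. The simulator models the same
mechanism as a per-stimulus miss probability; `plus50InflationFor()`
computes the miss rate that inflates the expected raw rate by a chosen
factor, and a property test confirms that inflating by 1.3 and correcting
by 1.3 recovers the uninflated estimator.

**Aggregation order.** A condition-level Ss/As can be formed by averaging
per-cell estimates or by applying the estimator to condition-mean failure
rates. The source of the published condition values is not stated, so
`conditionSummary()` reports both (`mean_ss_over_as` and
`pooled_ss_over_as`); on simulated cohorts they agree within Monte-Carlo
error.

# EPSC feature extraction

At least 10 sweeps per potential are averaged (`averageSweeps()`; fewer is
an error). After baseline subtraction:

* the **AMPA amplitude** is the peak inward current at −90 mV within
  1–20 ms post-stimulus (the first millisecond is blanked as stimulus
  artifact); a peak smaller than 3 baseline-noise SDs is `NO_RESPONSE`;
* the **NMDA amplitude** is the mean outward current at +50 mV in a 5-ms
  window starting 40 ms after the same cell's AMPA peak latency. Whether
  the published measure is the window mean or its centre point is
  ambiguous; the mean is the default and `pointEstimate = TRUE` gives the
  alternative (for the slow NMDA waveform they differ by well under 1%);
* recordings whose series resistance changes by more than 25%
  (strictly; 25.0% exactly is retained) are flagged, as are
  **polysynaptic** responses — two or more inward events in the 1–25 ms
  epoch counted with hysteresis (an event opens below the prominence
  threshold and closes at half of it, so noise riding on one EPSC flank is
  not double-counted), separated by at least 5 ms. The default prominence
  is the largest of 5 noise SDs, 10% of the principal peak, and 2 pA; the
  relative term keeps the criterion invariant to overall trace scaling.

The AMPA/NMDA ratio is only reported for cells with positive amplitudes
and no QC flags.

# Success/failure classification

The classifier applies the field's standard threshold rule: a sweep is a
success when the extremum in a response window, in the direction expected
for the holding potential, exceeds $k = 3$ noise SDs. Three details matter
for keeping the false-success rate of a window-maximum statistic near
nominal, and all are defaults of `silentSynapseTable()` that can be
overridden:

* **noise pooling** — the decision noise is estimated from the smoothed
  baselines of *all* sweeps of a cell at one potential, plus the variance
  contributed by subtracting the per-sweep baseline mean. A per-sweep
  estimate is too variable and inflates the tail of the max statistic;
* **matched smoothing** — 1 ms boxcar at −90 mV, 4 ms at +50 mV, roughly
  matching the AMPA and NMDA kinetics so the threshold compares like with
  like;
* **latency-anchored window** — the measurement window is ±2 ms around the
  evoked-response latency of the cell's averaged trace (clipped to the
  broad 1–20 / 1–50 ms search ranges). Scanning the full range instead
  raises the false-success rate to several percent and biases failure
  rates low.

With these defaults the simulator's ground truth is recovered with a
false-success rate of about 0.3% and no misses at the default quantal
sizes; with zero noise the classification is exact.

# The release simulator

`simulateCell()` draws independent Bernoulli release per terminal per
stimulus and synthesizes sweeps with difference-of-exponential waveforms
(AMPA rise/decay 0.5/3 ms; NMDA 5/80 ms), residual cross-potential
components (Mg-blocked NMDA at −90 mV, factor 0.02; reduced AMPA driving
force at +50 mV, factor 0.1), Gaussian recording noise (2 pA SD), optional
quantal variability, and the +50 mV miss process described above. Sweeps
are sampled at 5 kHz for 120 ms with the stimulus at 20 ms, and manifests
record the 10-s stimulus cadence.

The default cohort (`defaultCohortDesign()`) encodes the study conditions:
6 cells per condition, 300 stimuli per potential, CS and RS with
$A_s = 5$, $S_s = 7$ (Ss/As = 1.4), SD with $S_s = 0$ and a larger quantal
AMPA amplitude (14 vs 10 pA, reflecting sleep-loss strengthening),
$p_{\mathrm{release}} = 0.15$ so both failure rates stay well inside
(0, 1), and the miss rate set for a 1.3-fold raw inflation.
`simulateCohortOutcomes()` runs the same release process without waveform
synthesis — the generator's own bookkeeping — for studies that only need
failure counts (e.g. the 400-replicate type-I-error check).

What the simulator does *not* emulate: latency jitter, short-term
plasticity over the 10-s inter-stimulus interval, multi-vesicular or
heterogeneous $p_{\mathrm{release}}$, space-clamp and series-resistance
errors, or drifting baselines. Passing tests therefore show that the
pipeline recovers the binomial model's truth under realistic noise, not
that real recordings satisfy the model.

# The statistical battery

* `twoWayMixedAnova()` — cells (or samples) as subjects, a matched
  within-subject factor (−90/+50 measurement, or cell type for the UMI
  comparison) and condition between subjects; classical balanced sums of
  squares via `aov()`, cross-checked against `car::Anova` in the tests.
  `ggCorrection = TRUE` applies the Greenhouse–Geisser epsilon (computed
  from the pooled within-group covariance) to the within-stratum degrees
  of freedom, yielding the fractional df familiar from repeated-measures
  software; for a two-level within factor epsilon is exactly 1.
* `kruskalWallis()`, `wilcoxonMatchedPairs()` (exact null up to n = 25,
  normal approximation beyond), `chiSquareYates()` — standard base-R
  implementations behind a uniform result type, verified against hand
  formulas.
* `sidakAdjust()` — $1-(1-p)^m$.
* `bkyTwoStage()` — the two-stage adaptive step-up: BH at
  $q' = q/(1+q)$, estimate $m_0$ as the non-rejections, then BH at
  $q'm/m_0$. Decisions are validated against an independently coded
  evaluation of the definition. Note a boundary subtlety: the rejection
  set always contains plain BH at level $q'$, but not always at level $q$
  (if stage 1 rejects nothing the procedure stops even when BH at $q$
  would fire, e.g. $p = (0.024, 0.9)$, $q = 0.05$).

# The DEG census

`pseudobulkAggregate()` sums counts over nuclei per cell type and sample
(samples nested in conditions). DEG status is a threshold rule on a
reported statistics table: `"deg"` uses $|\log_2 FC| \ge 0.1375$ (a 10%
change) and FDR $\le 0.05$, both boundaries inclusive; `"overlap"`, used
for curated-set work, uses $|\log_2 FC| > \log_2 1.23$ and FDR $< 0.05$.
Both presets ship because both definitions are in active use. The
negative-binomial differential fit itself is out of scope — the census
consumes per-gene statistics tables.

The "probability of DEG occurrence given expression" is formalized as
$P(\mathrm{DEG}\mid \mathrm{expressed\ in\ type}) =
n_{\mathrm{DEG}}(t)/n_{\mathrm{expressed}}(t)$; a Bayes-rule form
$P(t\mid \mathrm{DEG})P(\mathrm{DEG})/P(t)$ with $P(t)$ proportional to
expressed genes reduces to the same ratio up to a global constant. Class
probabilities pool numerators and denominators within a class, and each
class is compared with the best of the others (`ratio_to_best_other`).
This quantity is invariant to duplicating a type's counts, which the tests
assert.

Gene-set enrichment uses the 2×2 Yates chi-square plus the hypergeometric
tail; `multisetIntersectionP()` generalizes the latter to k sets by
chaining hypergeometric kernels (the intersection of the first $j$ sets,
of size $s$, meets an independent uniform set of size $n$ as
Hypergeometric($N$, $s$, $n$)). For $k = 2$ this reduces exactly to the
hypergeometric tail; the tests verify the reduction by enumeration on all
universes up to 20 and check $k = 3$ against exhaustive enumeration on a
universe of 6.

# The synthetic transcriptome

`generateTranscriptome()` draws negative-binomial counts (dispersion
size 10) for 17 cortical types in four classes (ExIT by layer, other
excitatory projection classes, interneuron subclasses, non-neuronal), with
long-tailed per-gene rates, per-class expressed-gene budgets (33–75% of a
12,000-gene annotation, mirroring the observed 4,000–9,000 spread), and
per-class median UMIs per nucleus (2,000–6,000). Sleep deprivation scales
library sizes by 1.15. DEGs are planted per class share — 0.69 ExIT,
0.17 IN, 0.05 ExCT, 0.09 non-neuronal — with $|\log_2 FC|$ of
$0.2 + \mathrm{Exp}(4)$ and random sign; the reported table adds Gaussian
estimation noise (SD 0.02) to the fold changes and carries per-type
BH-adjusted p-values (tiny for planted DEGs, uniform for nulls), so it is
internally consistent and, at zero noise, recovers the planted set
exactly. It emulates the *structure* the census consumes — not reads,
barcodes, ambient RNA, doublets, or gene–gene correlation.

# Problem sizes and tolerances used in testing

The test suite runs the full study-size cohort (6 cells × 3 conditions ×
300 stimuli × 2 potentials) once with a 95% confidence check against the
planted values and across 100 seeds for the condition ordering; type-I
error uses 400 release-level null cohorts against a binomial 99% CI of the
nominal 0.05. The full 17-type, 12,000-gene transcriptome design is
generated once for the share-recovery check (±0.03); the 100-replicate
UMI-inflation check uses an 800-gene design with the same cells-per-type
and sample layout so the per-type UMI summaries keep their sampling
precision. Floating-point identities are asserted at $10^{-12}$,
reference-implementation agreement at $10^{-8}$.

# Known limitations

* Ss/As is a ratio estimator of two log failure rates; at 300 stimuli it
  carries a small positive Jensen-type bias (≈ +0.05 near Ss/As = 0)
  that vanishes as the stimulus count grows.
* The binomial model's assumptions (fixed recruited set, uniform constant
  $p_{\mathrm{release}}$, equal p at both potentials) are untestable from
  two failure rates alone; the package deliberately does not attempt to
  estimate $A_s$, $S_s$ or $p$ separately.
* The 1.3 correction is a single multiplicative constant applied to all
  conditions; if the underlying miss process varies across cells or
  conditions, condition differences in Ss/As are attenuated accordingly.
* The census consumes reported per-gene statistics; it inherits whatever
  biases the upstream differential fit had.
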