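Package: synphen
Title: Sleep-Dependent Glutamate Synaptic Phenotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantal analysis of the sleep-need-dependent glutamate synaptic
    phenotype in cortical pyramidal neurons. Extracts AMPA and NMDA EPSC
    amplitudes and their ratio from stimulus-locked voltage-clamp sweeps,
    classifies successes and failures under minimal stimulation, and
    estimates the silent/active synapse ratio from matched failure rates at
    -90 mV and +50 mV with a binomial release model. Includes the matched
    two-way ANOVA, Kruskal-Wallis, Sidak, Benjamini-Krieger-Yekutieli
    two-stage FDR and Yates chi-square battery used for sleep-condition
    comparisons; a pseudobulk cell-type census of differentially expressed
    genes with conditional DEG probabilities and curated gene-set enrichment
    (including an exact k-set intersection test); and seeded simulators for
    minimal-stimulation electrophysiology and single-nucleus count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
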