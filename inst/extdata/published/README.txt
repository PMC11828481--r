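Place the downloaded source-data tables here to enable the published-data
reproduction tests (see README, "Reproducing the results"):
  fig1_failure_rates.tsv  fig1_amplitudes.tsv
  fig3_census.tsv         fig3_degs.tsv
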