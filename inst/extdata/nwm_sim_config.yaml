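# Neutral ORF-decay simulation, New World monkey parameter set:
# night-monkey substitution rate with mouse-like 1-bp indel rates and a
# 1-year generation time.
preset: nwm-like
horizon_years: 5.0e+7
census_interval_years: 5.0e+4
n_replicates: 10000
seed: 1
require_start_codon: true
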