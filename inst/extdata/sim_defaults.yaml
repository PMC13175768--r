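# Default generator operating point: a typical targeted single-cell DNA
# run (99 human + 11 vector amplicons at 58x median per-amplicon
# coverage) with amplicon-to-amplicon efficiency spread, log-linear depth
# dependence, NB overdispersion decreasing with amplicon depth, and
# residual inter-amplicon correlation.
coverage_median: 58
n_human_amplicons: 99
n_vector_amplicons: 11
total_cv: 0.5
efficiency_sd: 0.4
x1_range: [0.85, 1.05]
alpha_base: 0.05
alpha_slope: -0.7
alpha_jitter_sd: 0.15
alpha_range: [0.005, 0.25]
residual_corr: 0.03
cn0_background: 0.05
doublet_rate: 0.0
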