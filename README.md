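# scvcn — single-cell vector copy number from targeted amplicon sequencing

Gene- and cell-therapy products (CAR T cells in particular) are made by
lentiviral transduction, and two quality attributes must be measured:
the **transduction efficiency** (what fraction of cells carry at least one
integrated vector) and the **vector copy number** (VCN) per cell. Bulk
assays (qPCR/ddPCR) return only a population average; two products with
identical average VCN can have drastically different per-cell copy-number
distributions, and hence different efficacy and insertional-mutagenesis
risk. `scvcn` implements a caller for per-cell VCN from targeted
single-cell amplicon DNA sequencing read counts (a cells × amplicons
integer matrix with both human genomic control amplicons and
vector-targeting amplicons), for analysts characterising transduced cell
products at single-cell resolution.

## The model

Each vector amplicon is modelled by a three-parameter negative-binomial
distribution anchored on control cells of known copy number
(`control_cn`):

- mean: `log(mean) = const + x1 · log(total reads of the cell)`, scaled
  linearly by copy number, `mean_cn = mean · cn / control_cn`
  (`cn = 0` uses a small ambient background floor);
- variance: `variance = mean + alpha · mean²`, where `alpha` is the
  amplicon's cell-to-cell overdispersion; for copy-number states other
  than the control state, `alpha` is extrapolated from the cross-amplicon
  trend of dispersion against mean read depth and scaled inversely with
  copy number.

For each cell, per-amplicon NB log-likelihoods are summed over all vector
amplicons for every state on a copy-number grid (0–9 by default); the
call is the argmax, and the call quality is the log-likelihood gap to the
runner-up state. Transduction status is simply `cn > 0`.

Raw per-cell calls leak a few percent of mass into neighbouring states
("fall-off clones"). The **weighted mixture method** (WMM) corrects the
population proportions: reads are simulated per copy-number state from
the fitted models — with the empirically observed inter-amplicon residual
correlation injected through a Gaussian copula (Cholesky factor of the
repaired correlation matrix) — the caller is run on these simulations,
and simplex weights over states are fitted so that the weight-mixed
expected call distributions minimise the sum of absolute differences
(SAD) against the observed call distribution.

Companion modules cover germline-variant demultiplexing of mixed cell
lines, antibody-tag (protein) normalisation with marker-rule lineage
assignment and an exhaustion-like phenotype Fisher test, summary
statistics (average VCN per transduced cell, linearity, Poisson
concordance of the copy-number distribution, control-anchor robustness,
outlier diagnostics, VAF by copy number), and a calibrated synthetic-data
generator so the whole pipeline can be exercised and tested without
sequencing data.

## Worked example

Simulate a transduced product (10% untransduced, average VCN ≈ 1.45) and
a CN-4 control run from one shared panel, then fit, call and correct:

```r
library(scvcn)

cfg <- simulation_config(n_cells = 4000,
                         composition = c("0" = 0.10, "1" = 0.55, "2" = 0.20,
                                         "3" = 0.10, "4" = 0.05),
                         seed = 7, run_id = "demo")
panel   <- simulate_panel(cfg)
control <- simulate_control_run(cfg, control_cn = 4, panel = panel, seed = 8)
test    <- simulate_run(cfg, panel = panel)

result <- vcn_pipeline(test$run, control$run, control_cn = 4, seed = 9)
result$mixture
#> mixture_estimate (weighted mixture method)
#>   SAD 3.5e-05 after 73 iteration(s), converged: TRUE
#>   weights: CN0=0.104, CN1=0.545, CN2=0.200, CN3=0.100, CN4=0.051
result$summary
#> transduced: 89.6%  avg VCN: 1.448  avg VCN/transduced: 1.617

sensitivity_specificity(result$calls$transduced, test$truth$transduced)
#> sensitivity 100%, specificity 100%
```

The corrected weights recover the simulated composition to within half a
percent per state; the sample average VCN (1.448) matches the simulated
truth (1.447), and `avg VCN/transduced` is the average restricted to
vector-positive cells — the quantity release assays report relative to
the CAR-positive fraction.

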