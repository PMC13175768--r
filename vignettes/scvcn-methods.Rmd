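---
title: "Methods: the scvcn copy-number model, mixture correction and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the scvcn copy-number model, mixture correction and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scvcn)
```

# The measurement problem

Targeted single-cell amplicon DNA sequencing reports, for every cell, an
integer read count per amplicon. The panel mixes *human* amplicons
(endogenous genomic controls, two copies per cell) with *vector*
amplicons whose counts scale with the number of integrated lentiviral
vector copies (VCN). Counts vary for three reasons that must be
separated from copy number: amplicons have different PCR efficiencies,
cells have different total read depths, and identical cells at equal
depth still scatter beyond Poisson noise. `scvcn` estimates per-cell VCN
by modelling each vector amplicon explicitly against control cells of
known copy number.

# The per-amplicon negative-binomial model

For one vector amplicon, the count $y$ of a cell with total read depth
$T$ at copy number $c$ is negative binomial with

$$\log \mu = \mathrm{const} + x_1 \log T, \qquad
  \mu_c = \mu \cdot \frac{\max(c,\ \texttt{cn0\_floor})}{c_{\mathrm{ctrl}}}, \qquad
  \mathrm{Var} = \mu_c + \alpha_c\, \mu_c^2 .$$

* `const` absorbs the amplicon's efficiency (low-yield amplicons get a
  lower intercept).
* `x1` measures how strongly the amplicon tracks the cell's total
  depth; values near 1 mean proportional scaling.
* `alpha` is the cell-to-cell overdispersion; it controls how much the
  count distributions of adjacent copy numbers overlap and therefore how
  informative the amplicon is.

**Total read depth.** $T$ is computed over *human* amplicons only
(configurable to the whole panel). A whole-panel total contains the
vector counts themselves and is therefore copy-number dependent, which
would bias the depth covariate for exactly the cells whose copy number is
in question; the human-only total is copy-number free. The same choice
propagates to the outlier diagnostics (`outlier_read_comparison`), where
it keeps the human-read comparison unconfounded.

**The CN-0 state.** A zero-copy cell still yields occasional vector
reads (ambient molecules, barcode hopping), so copy number 0 is modelled
as a small fraction `cn0_floor` (default 0.05) of the per-copy mean
rather than an impossible zero-mean distribution. The default is the
package's own choice of a realistic ambient level; it is configurable
and is mirrored by the simulator's `cn0_background` so that synthetic
untransduced cells obey the same law.

**Fitting.** Parameters are estimated by profile maximum likelihood on
the control cells: at fixed $\alpha$, $(\mathrm{const}, x_1)$ solve the
log-link estimating equations by iteratively reweighted least squares
(weights $\mu/(1+\alpha\mu)$, the inverse variance on the link scale);
$\alpha$ is then maximised by bounded one-dimensional search of the
profile log-likelihood on $[10^{-8}, 10]$ (log scale), seeded from a
method-of-moments estimate. Because the Poisson model is the
$\alpha \to 0$ boundary of the family, the fitted log-likelihood is
never below the Poisson fit; a final guard enforces this against line
search quirks. Cells with zero total reads are excluded from fitting and
are returned as uncallable (`cn = NA`, quality 0) by the caller.

**Dispersion at other copy numbers.** The control run pins $\alpha$ only
at the control state. For other states the package follows the trend
that deeper amplicons are less overdispersed: a least-squares polynomial
(degree 1 by default; degree is configurable) of $\log\alpha$ on
$\log(\text{mean control depth})$ across all retained vector amplicons,
evaluated at the amplicon's own mean depth and scaled by
$c_{\mathrm{ctrl}} / \max(c, \texttt{cn0\_floor})$, clipped below at
$10^{-8}$. The inverse-in-$c$ scaling makes the coefficient of variation
shrink for higher copy numbers, the direction consistent with a
per-copy averaging of integration noise; at the control state the
amplicon's own fitted $\alpha$ is used directly. With fewer than three
amplicons no trend can be fitted and each amplicon falls back to its own
constant $\alpha$, with a warning.

**Depth filter.** Vector amplicons with mean control depth at or below
5 reads (`min_mean`, boundary inclusive on the exclusion side) are
excluded before fitting; human amplicons are never filtered.

# Calling cells

For each cell the per-amplicon log NB masses are summed over all
retained vector amplicons for every state $c \in \{0, \dots,
\texttt{max\_cn}\}$ (default grid top 9, matching the reporting bins;
calls at the top of the grid are flagged `saturated`). The call is the
argmax and the *quality* is the gap between the best and second-best
summed log-likelihood. Exact ties resolve to the **lower** copy number
with quality 0 — conservative with respect to insertional-load claims.
No quality filtering is applied by default (`min_quality = 0`).
Per-amplicon calls are available for diagnostics
(`caller_config(per_amplicon = TRUE)`) but the cell-level call is
authoritative. Log-pmf underflow is floored at a large negative finite
value so sums never produce `NaN`.

# The weighted mixture correction

Even a clonal population leaks a few percent of calls into neighbouring
states. To correct the *population* proportions, reference call
distributions are built per state by simulating reads from the fitted
models at totals resampled from the control run and running the caller
on them; the observed call histogram is then explained as a weighted
mixture of these references by minimising the sum of absolute
differences (SAD) over copy-number bins.

* **Correlated simulation.** Standardised residuals
  $(y - \mu)/\sigma$ on the control run give a pairwise Pearson
  correlation matrix across vector amplicons (closely tiled amplicons
  co-vary, e.g. through polymerase run-on). The matrix is repaired to
  positive semi-definiteness by clipping eigenvalues at $10^{-6}$ and
  renormalising the diagonal, and its Cholesky factor mixes independent
  normal scores which are mapped through each amplicon's NB quantile
  function (a Gaussian copula). The copula preserves the NB marginals
  exactly — a back-transform through residual standardisation would not.
  A constant residual column gets zero correlation with a warning.
* **Weight optimisation.** SAD is piecewise linear and convex on the
  simplex. The fit starts from the single vertex with smallest SAD
  (ties to the lowest state) and performs deterministic pairwise
  descent: each iteration evaluates moving the current step of mass
  between every ordered pair of states and accepts the best strict
  improvement; when none improves the step is halved (from 0.5 down to
  $10^{-8}$). Iteration stops after 1,000 rounds or when
  $\mathrm{SAD} \le 1/(10\,n_{\mathrm{cells}})$. SAD is non-increasing
  across accepted iterations, the result is deterministic, and on
  degenerate inputs (duplicate reference states) the lowest-index state
  receives the mass. The implementation is validated in the tests
  against exhaustive simplex grid search at 0.01 resolution.
* **Reference size.** 10 simulated cells per observed cell per state by
  default (`sim_factor`), seeded for reproducibility.
* **Binning.** SAD is computed over bins $0..\texttt{max\_cn}$ with
  everything at or above the top bin merged into it.

# Phenotyping modules

* **Genotyping/demultiplexing** (plumbing around the caller): genotypes
  from allele fractions (0/0 below 0.2, 1/1 above 0.8, else
  heterozygous; sites under depth 5 missing), then each cell is assigned
  to the reference line with the highest fraction of matching genotypes
  if that fraction is strictly greater than 0.60; ties and sub-threshold
  matches stay unassigned. Thresholds are configurable defaults.
* **Protein normalisation.** The vendor's noise-corrected scaled protein
  protocol is proprietary; the package ships a documented surrogate:
  $x = \log(1 + 10^4\,\mathrm{count}/\mathrm{cell\ total})$, minus the
  mode of the pooled isotype-control distribution, clipped at 0. Its
  contract is only that it is monotone in count, compositional per cell,
  and comparable to the 0.7 positivity threshold after background
  centering. Passing phenotype tests on this scale does not certify the
  vendor scale.
* **Lineage rules.** Markers binarise at a strict threshold
  (`value > 0.7`); ordered rules (sticky isotype-positive cells first,
  then CD4+/CD8+ T) with first match winning; unmatched cells are
  `"other"`. Strict boundaries follow the source conventions
  ("greater than") throughout.
* **Exhaustion-like phenotype.** CD45RO+, CD62L−, CD69+, HLA-DR+ cells,
  compared between transduced and untransduced cells by Fisher's exact
  test (two-sided, via `stats::fisher.test`) with the sample odds ratio
  under Haldane correction when a cell is zero; a zero margin returns
  $p = 1$ with the odds ratio flagged undefined.

# Summary statistics

`summarize_transduction` enforces the identity
$\mathrm{avg\ VCN} = \mathrm{avg\ VCN\ per\ transduced} \times
\mathrm{transduced\ fraction}$. Poisson concordance folds the upper tail
of the PMF into the top bin before computing the squared Pearson
correlation. Linearity uses plain unweighted least squares with the
slope's t-based 95% CI, residual-versus-fitted correlation, and the
p-value of a quadratic term in a degree-2 refit. The coefficient of
variation uses the population (divisor $n$) standard deviation by
default, with a flag for the sample version — with triplicate
measurements the two differ noticeably, so the choice is documented.
Group comparisons of copy-number distributions use a permutation test on
the total variation distance between normalised histograms
(chi-square distance behind a flag), with the add-one p-value estimator.
Outlier diagnostics use one-tailed Welch t-tests (group sizes and
variances differ) on depth- and median-normalised reads.

# The synthetic-data generator

`simulate_run` produces runs with the statistical structure the model
assumes: lognormal per-cell total depth (median = coverage × panel
size; CV 0.5 by default — the depth law is the package's own choice, as
only a median coverage is meaningful to target), per-amplicon efficiency
weights (lognormal), depth slopes $x_1 \sim U(0.85, 1.05)$, NB counts
with dispersion coupled to amplicon depth (deeper amplicons less
overdispersed) and anchored at the diploid level, vector means
proportional to true copy number with an ambient background for CN 0,
exchangeable inter-amplicon residual correlation injected by the same
Gaussian copula as the mixture machinery, and optional doublets formed
by summing two independently drawn cells (truth records both parents and
the arithmetic-mean copy number). Optional companions simulate germline
allele depths for demultiplexing and antibody-tag matrices for
phenotyping.

**Calibration.** The numeric defaults live in
`inst/extdata/sim_defaults.yaml` and were chosen once so that a default
run reproduces the assay's published operating point at 58× coverage —
at least 93% of cells in a single-CN run called exactly and about 2%
called above the true state: coverage_median 58, 99 human + 11 vector
amplicons, `alpha_base` 0.05 at the diploid anchor (range
[0.005, 0.25] across amplicons), residual correlation 0.03, ambient
CN-0 background 0.05. Doublets default to 0 because the qualification
scenarios inject them explicitly where needed.

**What the generator does not emulate.** Amplicon dropout bursts,
ambient contamination gradients, GC/primer-sequence effects, batch
effects across runs, and read-level errors are absent. Passing tests on
synthetic data therefore demonstrates the estimator's correctness under
its assumed model and its calibrated noise level — not robustness to
every artifact of real sequencing runs.

# Problem sizes and numerical conventions used by the test suite

The acceptance suite runs the qualification surrogates at 20,000 cells
(transduction mixture), twelve 4,000-cell single-CN runs, seven
2,000-cell compositions for linearity, and an 8,000-cell Poisson
product with the full mixture correction — sizes chosen to hold the
binomial uncertainty of each measured rate comfortably inside the bound
it is checked against. All stochastic stages take explicit seeds and are
bit-reproducible; seeded helpers restore the caller's RNG state.

# Known limitations

* The control run must contain at least 30 usable cells; the model
  cannot be anchored on a zero-copy control.
* Copy numbers above the grid top are truncated into the `saturated`
  bin; the grid must be grown for high-VCN material.
* The dispersion extrapolation across copy-number states is an
  assumption (inverse-in-CN scaling of a cross-amplicon trend), not a
  fitted quantity, because a single-state control run carries no
  information about other states' dispersions.
* The protein normalisation is a surrogate scale (see above).
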