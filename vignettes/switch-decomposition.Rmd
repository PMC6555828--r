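---
title: "Models and methods: decomposing switch-like NFAT activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: decomposing switch-like NFAT activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caswitch)
```

## The scientific question

Local Ca²⁺ entry through CRAC channel puncta couples to gene expression
along at least two routes with different single-cell statistics. NFAT1
activation is switch-like: a stimulated population splits into cells that
look maximally activated and cells that look like resting cells, with the
*fraction* of responders — not the per-cell amplitude — tracking stimulus
strength. c-fos induction, in contrast, grades with dose in every cell.
`caswitch` implements the statistical models that make this distinction
quantitative: a binomial activating-unit model for nuclear translocation, a
two-component log-normal mixture for reporter-gene flow cytometry, Hill
dose-response fits, and rate-of-rise estimators for fura-2 traces, plus a
seeded synthetic-data layer that emulates each data type.

## Nuclear proportion and the binomial activating-unit model

Per-cell nuclear and cytosolic NFAT1 intensities are summarized as the
nuclear proportion

$$x = \frac{\mathrm{nuclear}}{\mathrm{nuclear} + \mathrm{cytosolic}}
    = \frac{\rho}{1+\rho}, \qquad \rho = \text{nuclear:cytosolic ratio},$$

a bounded quantity in $[0, 1)$. The ratio itself is awkward: some unimodal
ratio histograms look normal and others log-normal, whereas the proportion
admits one consistent model. We treat each cell as carrying $n$ independent
*activating units* — candidate identities include individual puncta,
regional clusters of puncta, or a downstream AKAP79/calcineurin bottleneck
— each of which switches on with probability $p$, so the number of active
units is $k \sim \mathrm{Binomial}(n, p)$ and the observed proportion is
$k/n$. Under stimulation, $p$ rises; across conditions $n$ is shared.

Fitting works on discretized counts $k_i = \mathrm{round}(n x_i)$
(half-integers round up — the simplest consistent mapping; the choice only
matters at bin edges and its sensitivity can be probed through the
configurable $n$ grid). For fixed $n$ the MLE is the closed form
$\hat p = \sum_i k_i / (N n)$.

**Choosing $n$.** No published value of $n$ exists for this system, so
`profile_n()` profiles it over an integer grid (default 1–50). Two regimes
are distinguished. When candidate lattices $\{0, 1/n, \dots, 1\}$ contain
every observation exactly, the observed values have genuine probabilities
under those candidates and they are compared by summed log-likelihood
directly (noiseless data then recover the generating $n$; all-zero or
all-one data tie every candidate and the tie-break picks the smallest).
Otherwise raw log-likelihoods are incomparable across $n$ — a coarser
lattice always concentrates more mass after rounding — so candidates are
scored on the continuous-density scale, dividing each bin's probability by
its width $1/n$: $\mathrm{score}(n) = \ell(n) + N\log n$. Point-mass fits
($\hat p \in \{0,1\}$) contribute no width correction.

**Responder/non-responder mixtures.** Partial stimulation produces bimodal
proportion histograms: a non-responding subpopulation near rest plus
responders near the maximal distribution. `fit_binomial_mixture()` fits
$w\,\mathrm{Bin}(n, p_1) + (1-w)\,\mathrm{Bin}(n, p_2)$ by EM with
deterministic multi-start (population splits at the 20th/80th percentiles
and the median), a log-likelihood tolerance of $10^{-8}$ and at most 500
iterations; monotonicity of the EM objective is asserted at every step. The
smaller-$p$ component is always labelled the non-responder. Boundary
solutions (a vanishing weight, or $p_1 \approx p_2$) are flagged
`degenerate` rather than raised as errors. `classify_modality()` compares
the one- and two-component fits by BIC (penalties 1 and 3 parameters); an
optional parametric-bootstrap likelihood-ratio test is available because
mixture LRTs violate the usual chi-squared asymptotics. Per-cell responder
posteriors come from Bayes' rule under the fitted mixture; on the fitting
data their mean reproduces the fitted responder weight (an EM stationarity
identity).

## Log-normal mixture decomposition of flow cytometry

Reporter fluorescence $H$ is modelled on the $\log_{10}$ scale. A resting
population is a single normal, $\log_{10} H \sim N(\mu, \sigma)$; a
stimulated population is the two-component mixture

$$\log_{10} H \sim \alpha\, N(\mu_n, \sigma_n) +
  (1-\alpha)\, N(\mu_r, \sigma_r),$$

with $\alpha$ the non-responder fraction and the smaller-mean component
labelled non-responder. Estimation is maximum likelihood: the
single-component fit uses the sample mean and the *population* (divisor-N)
SD of the $\log_{10}$ values, consistent with the likelihood the EM
maximizes; the mixture is fitted by EM with deterministic starts (20/80 and
35/65 quantile splits plus a 2-means-style split on the log values),
tolerance $10^{-8}$, 500 iterations maximum, best log-likelihood winning
and ties going to the smaller $\alpha$. Nonpositive events (possible in
compensated FCS exports) must be excluded up front; `drop_nonpositive()`
does so and reports the count.

Summaries on the raw fluorescence scale follow from the fitted model. The
mixture mean has the closed form
$\sum_i w_i\, 10^{\mu_i} e^{(\sigma_i \ln 10)^2/2}$; the median is the
numeric root of $F(x) = 1/2$, bracketed and solved to relative tolerance
$10^{-10}$ (exactly $10^\mu$ for a single component). The mean always
exceeds the median when any $\sigma > 0$ — the skew that makes raw-scale
FACS means look inflated. Tail fractions use the inclusive convention
(value ≥ threshold) in both empirical and model modes. Two rules derive
thresholds from controls: twice the largest blank intensity (sensitive to
blank outliers by construction — inspect the blank), and the
reporter-positivity call `value > mean(blank) + 3·SD(blank)`. The latter
reads the "3×SD above autofluorescence" convention as mean-plus-3SD; a
plausible alternative reading (3·SD above zero) is rejected because it
ignores the autofluorescence location. Quadrant statistics for two-reporter
scatters use strict exceedance with y = NFAT reporter and x = c-fos
reporter: Q1 high-y only, Q2 high-both, Q3 high-x only, Q4 neither;
percentages sum to 100 identically.

Whether the original decompositions were obtained by ML or by least squares
on binned histograms is not documented; per-cell maximum likelihood is
implemented because it is the statistically efficient choice and requires
no binning decisions. Histogram binning is for display only.

## Hill dose-response fits

Dose-response curves use
$r(d) = r_{\max}\, d^{n_H} / (d^{n_H} + \mathrm{EC}_{50}^{n_H})$, with
$\mathrm{EC}_{50}$ also reported as an apparent $K_D$ for SERCA-inhibitor
titrations. Fitting minimizes the weighted SSE over per-dose mean responses
(weights = cells per dose; per-dose means are the default because the
original fits were to dose means), parameterized as
$(\log_{10} \mathrm{EC}_{50}, \log n_H)$ to enforce positivity, with
`nlminb` from three deterministic starts across the positive dose range.
$r_{\max}$ is either fixed (100% for normalized reporter curves) or
profiled out in closed form — given the shape parameters the optimal
$r_{\max}$ is a weighted regression coefficient, which removes one
dimension from the search and is what makes noiseless recovery exact to
$10^{-6}$. Zero doses contribute to the loss but never to log transforms.
Flat series are flagged `degenerate`; an EC₅₀ outside the positive dose
range is flagged `extrapolated`. Uncertainty comes from case-resampling
bootstrap within dose (percentile 95% intervals); `compare_ec50()`
bootstraps the ratio of two curves' EC₅₀s and declares separation when the
interval excludes 1.

## Rates from fura-2 traces

All three trace-derived scalars — Ca²⁺-entry rate after readmission, the
ionomycin-transient initial rate (a proxy for store Ca²⁺ content), and
Ba²⁺-entry rate — use one estimator: an OLS slope over a post-onset window
minus the OLS slope of the pre-event basal window. Onset is the first
post-event sample exceeding the basal mean by 3 basal SDs (if never
crossed, the event time is used and the estimate flagged). Defaults are a
20 s analysis window and a 30 s basal window; no published values exist for
either, so both are arguments. Slopes stay in ratio units per second — no
calibration to nM Ca²⁺ is attempted. The synthetic trace generator lets the
basal drift continue through the event with the event slope added on top,
so that basal subtraction recovers the event-induced slope exactly on
noiseless input and the corrected estimate is invariant to basal drift —
the pair of properties that define the estimator.

## The synthetic-data layer

Because the raw single-cell measurements are not publicly deposited, the
generators in `synthgen` stand in for them, reproducing exactly the
distributional assumptions above: scaled-binomial lattices for nuclear
proportions, base-10 log-normal mixtures for fluorescence (component
membership sampled per cell, matching the probabilistic-responder
interpretation), Hill curves with multiplicative Gaussian noise truncated
at zero (rates are nonnegative), and piecewise-linear traces with additive
noise. Every generator takes an explicit seed (package default 20190607)
and restores the caller's RNG state.

The bundled reference parameters are the published fitted values: resting
fluorescence $\mu = 2.06$, $\sigma = 0.21$; the low-dose (30 nM
thapsigargin) mixture $\alpha = 0.38$, $(\mu_n, \sigma_n) = (2.37, 0.17)$,
$(\mu_r, \sigma_r) = (3.61, 0.75)$; the depolarised high-K⁺ mixture
$\alpha = 0.31$, $(2.29, 0.17)$, $(4.07, 0.67)$; Ca²⁺-entry Hill parameters
$K_D = 0.025\ \mu M$, $n_H = 0.8$ (thapsigargin) and
$\mathrm{EC}_{50} = 10$ nM, $n_H = 1$ (LTC₄); and reporter-activation
EC₅₀s of 1 nM (NFAT) and 9.8 nM (c-fos). Three generator settings are
conventions rather than published values and are fixed once here: the
reporter-activation curves use $n_H = 1$ (the value measured for the same
agonist's Ca²⁺-entry curve; no coefficient is published for the reporter
curves); the maximal entry rate behind the $K_D$ simulation is
$r_{\max} = 0.03$ R/s, a realistic fura-2 ratio rate (EC₅₀ recovery is
invariant to it under multiplicative noise); and the binomial default
$n = 13$ units echoes the 13 regulatory phosphorylation sites of NFAT1
discussed in this system — a convention, not an estimate.

What the generators deliberately do **not** emulate: instrument-specific
FACS artefacts (compensation spillover, boundary events), spatial Ca²⁺
microdomains, oscillatory trace dynamics, or any mechanistic STIM1–Orai1
gating. Passing recovery tests on synthetic data therefore demonstrates
estimator correctness under the stated models, not robustness to
instrument artefacts.

## Problem sizes and reproducibility

The recovery checks mirror the study's scales and were chosen once: 15,000
cells per FACS condition; 1,000–2,000 cells for binomial-mixture recovery
(50-replicate mean absolute error of the mixture weight below 0.03); 15–20
cells per dose at 5% multiplicative noise for Hill refits, matching the
11–30 cells per point of the underlying experiments; bootstrap sizes of
199 in tests and 999 by default. `run_scenario()` hashes its configuration
into every report, and all randomness flows through explicit seeds, so any
report or acceptance run is reproducible bit for bit.

```{r example}
rep <- run_scenario(reference_scenario(seed = 20190607, n_cells_facs = 5000))
c(alpha_30nM = rep$facs$tg30nM$alpha, alpha_highK = rep$facs$highK$alpha,
  KD_uM = rep$hill$thapsigargin_entry$ec50)
```

## Known limitations

- The binomial discretization is a modelling convenience; for data far off
  any lattice the profiled $n$ should be read as an effective granularity,
  not a count of physical units, and neither $n$ nor $p$ for the published
  translocation histograms can be checked numerically (they were not
  reported).
- EM mixture fits can hit boundary optima on near-unimodal data; such fits
  are flagged, and the BIC-based modality call (not the raw fit) is the
  supported decision rule.
- `fraction_above()` in model mode extrapolates the fitted tails; empirical
  tail fractions are data summaries and the two agree only as well as the
  mixture fits the tail.
- The blank-doubling threshold rule propagates blank outliers by design.
- Printed empirical means and medians of real FACS groups are data
  summaries; fitted-model summaries can only approximate them (the resting
  model median reproduces the empirical one within ~1%).
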