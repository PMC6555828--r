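# caswitch

Statistical decomposition of switch-like transcription-factor activation in
single cells.

Store-operated Ca²⁺ entry through CRAC (Orai1/STIM1) channels can drive two
very different transcriptional readouts from the same bulk Ca²⁺ rise: NFAT1
activation behaves like an all-or-none switch at the single-cell level —
cells either translocate NFAT1 to the nucleus and express an NFAT-driven
reporter, or they look like resting cells — whereas c-fos expression grades
with stimulus strength. `caswitch` packages the statistical machinery needed
to demonstrate and quantify that distinction from single-cell measurements:

- **Nuclear translocation** (`transloc`): transforms per-cell
  nuclear:cytosolic intensity ratios to the nuclear proportion
  `p = ratio / (1 + ratio) ∈ [0, 1)` and fits a binomial "activating-unit"
  model, `k ~ Binomial(n, p)` with nuclear proportion `k/n` — the idea that
  `n` discrete units (puncta, regional clusters, or a downstream
  calcineurin bottleneck) each make a probabilistic decision to admit NFAT1
  to the nucleus. Includes profiling of a shared `n` across conditions,
  two-component (responder/non-responder) mixture fitting by EM,
  BIC/bootstrap modality classification and per-cell responder posteriors.
- **Flow cytometry** (`flowmix`): base-10 log-normal fits to reporter
  fluorescence, `log10(H) ~ α·N(μₙ, σₙ) + (1−α)·N(μᵣ, σᵣ)` where `α` is the
  non-responder fraction; closed-form mixture means, numeric medians,
  threshold fractions, quadrant statistics for two-reporter scatters, and
  mean+3SD reporter-positivity calls against a blank.
- **Dose-response** (`doseresp`): Hill fits
  `r = r_max·d^n / (d^n + EC₅₀^n)` by weighted nonlinear least squares with
  free or fixed maximum, case-bootstrap confidence intervals, and EC₅₀
  comparison between curves (e.g. the left shift of NFAT-reporter
  activation relative to c-fos).
- **Ca²⁺ traces** (`catrace`): basal-corrected initial rates of rise of the
  fura-2 356/380 ratio after Ca²⁺ readmission, ionomycin challenge
  (store-content proxy) or Ba²⁺ addition.
- **Synthetic data** (`synthgen`): seeded generators that reproduce the
  statistical structure each stage assumes (binomial lattices, log-normal
  mixtures, noisy Hill curves, piecewise-linear traces), so the whole
  pipeline is testable without access to raw measurements.
- **Orchestration**: `run_scenario()` executes a declarative YAML/JSON or
  list config (generate → fit → report) and `check_acceptance()` compares a
  report against declared targets.

## Worked example

Decompose a simulated flow-cytometry population (15,000 cells, 38%
non-responders) and refit a thapsigargin Ca²⁺-entry dose-response curve:

```r
library(caswitch)

spec <- lognormal_population_spec(
  list(c(weight = 0.38, mu = 2.37, sigma = 0.17),   # non-responders
       c(weight = 0.62, mu = 3.61, sigma = 0.75)),  # responders
  n_cells = 15000, seed = 20190607)
fit <- fit_lognormal_mixture(gen_fluorescence(spec))
fit
#> Two-component base-10 log-normal mixture (n = 15000 )
#>   non-responders: alpha = 0.372, mu = 2.370, sigma = 0.169
#>   responders:     1-alpha = 0.628, mu = 3.594, sigma = 0.754
#>   log-likelihood: -15667.41

mixture_median(fit)   # 933 a.u.   -- far below the
mixture_mean(fit)     # 11209 a.u. -- heavily skewed raw-scale mean

tg <- hill_curve_spec(ec50 = 0.025, hill_n = 0.8, r_max = 0.03,
                      doses = 10^seq(log10(0.003), log10(2), length.out = 8),
                      cells_per_dose = 15, noise_cv = 0.05,
                      dose_unit = "uM", seed = 20190607)
fit_hill(gen_dose_response(tg), "free")
#> Hill fit: 120 cells at 8 doses
#>   EC50 (apparent K_D): 0.02546 uM
#>   Hill coefficient:    0.784
#>   maximal response:    0.03009 (free)
```

The mixture fit recovers the generating non-responder fraction (37.2% vs
38%) and component locations; the Hill refit recovers the apparent K_D and
coefficient from 15 noisy cells per dose. The gap between the mixture
median (~930 a.u.) and mean (~11,200 a.u.) is the log-normal skew that
makes raw-scale FACS means misleading.

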