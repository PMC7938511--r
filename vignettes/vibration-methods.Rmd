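---
title: "Methods: quantifying model, sampling and measurement vibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying model, sampling and measurement vibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

An epidemiological association — say, between a biomarker and all-cause
mortality — is usually reported as a single hazard ratio with a confidence
interval. That interval reflects sampling uncertainty only. Two further
sources of instability are rarely quantified: the analyst's freedom in
choosing adjustment variables, and measurement error in the covariates.
`voe` treats all three symmetrically. Each one is turned into a *set* of
refits of the same association, and the spread of that set is reported on
a common scale.

# The estimand and the fitting engine

Throughout, the target is the coefficient of one exposure in a Cox
proportional-hazards model for a time-to-event outcome. Fits are delegated
to `survival::coxph` with:

* **Efron approximation** for tied event times — the default of the
  reference survival ecosystem, and accurate for the moderate tie rates
  produced by continuous event times;
* **robust (sandwich) variance** always, so that P-values remain valid
  when sampling weights or cluster structure are present; without a
  design the sandwich and model-based variances agree closely on
  well-specified data (this is tested);
* survey design columns, when the cohort schema declares them: weights
  enter the partial likelihood, strata enter as baseline-hazard strata,
  and the sandwich variance is clustered on the primary sampling units.
  Full survey linearization beyond cluster-robust variance is out of
  scope.

P-values are two-sided Wald tests using the normal approximation,
`p = 2 * pnorm(-|beta| / se)`.

A continuous exposure is standardized to mean 0, SD 1 once at load time,
so hazard ratios read "per standard deviation" and are comparable across
vibration types. Under measurement vibration the corrupted exposure is
re-standardized after error injection, before refitting: injected error
inflates the variance, and without re-standardization the per-SD scale of
the hazard ratio would silently change across iterations. Ordinal
covariates enter the linear predictor as integer scores $1..L$; this is a
deliberate single-degree-of-freedom coding that keeps the $2^k$ model
universe interpretable.

**Convergence policy.** Degenerate fits (constant exposure, zero events in
a subsample, non-finite coefficients, optimizer warnings) yield a
non-converged estimate rather than an error. Non-converged fits are kept
in the long-format output, flagged, and excluded from all summary
statistics — excluding them avoids biasing percentiles with sentinel
values, keeping them in the CSV preserves transparency. If more than 5% of
fits in a run fail, the run aborts: at that rate the cohort is
structurally degenerate and percentile summaries would be misleading.

# The three vibration engines

**Model vibration.** With $k$ optional adjustment variables and a fixed
baseline set (age and sex in the canonical layout), all $2^k$ subsets are
enumerated in binary-counter order (bit $i$ = inclusion of the $i$-th
optional variable), so `model_id` is stable across runs and machines. The
enumeration is capped at $k = 20$ by default (an override exists) because
$2^k$ Cox fits must stay desk-scale.

**Sampling vibration.** $B$ subsets of size
$\lfloor \text{fraction} \cdot n \rfloor$ are drawn by simple random
sampling *without replacement* (defaults $B = 1000$, fraction $0.5$) and
the favourite model — by default the all-adjustments specification — is
refit on each. Subsets are drawn ignoring survey strata and clusters
(each subset is a plain row sample), but every refit still uses the design
columns; a design-aware subsampler would answer a different question
(variability across replicate *surveys* rather than across subsamples of
this one).

**Measurement vibration.** Per iteration, one parameter triple
$(\rho, \text{sens}, \text{spec})$ is drawn uniformly from its ranges and
applied to *all* error-prone variables of the targeted scenario
(exposure only, adjustments only, or both); the noise streams of different
variables are independent, i.e. measurement errors are uncorrelated across
variables. Error-free variables (the age/sex/race-ethnicity analogues in
the bundled spec), the outcome and the design columns are never touched —
outcome error is a documented non-goal.

The per-variable error generators:

* *Continuous:* classical additive error $Z = X + U$, with the recorded
  values taken as truth and
  $\mathrm{Var}(U) = \mathrm{Var}(X)/\rho^2 - \mathrm{Var}(X)$ computed
  from the sample variance ($n-1$ denominator; the choice is immaterial at
  cohort scale). This gives $\mathrm{cor}(X, Z) = \rho$ and
  $\mathrm{Var}(Z) = \mathrm{Var}(X)/\rho^2$ in expectation, and implies
  the classical regression-dilution slope attenuation by $\rho^2$ for a
  single error-prone covariate — both are tested against Monte-Carlo
  oracles.
* *Binary:* each true 1 stays 1 with probability equal to the
  sensitivity, each true 0 becomes 1 with probability one minus the
  specificity, independently per row.
* *Ordinal:* a latent-normal analogue of the continuous scheme.
  Thresholds are set from the empirical cumulative level frequencies via
  $\Phi^{-1}$; each row's latent value is drawn from the standard normal
  truncated to its level's slice (inverse-CDF sampling); noise with
  variance $1/\rho^2 - 1$ is added; the noisy latent value is rescaled by
  $\rho$ — restoring unit variance without changing the latent
  correlation, since correlation is scale-free — and re-discretized with
  the same thresholds. Without the rescaling step the noisy latent
  variance $1/\rho^2$ would systematically inflate the outer categories;
  with it, level marginals are preserved in expectation, which is the
  behavior a measurement-error model (as opposed to a distribution-shift
  model) should have.

**Reproducibility.** A master seed spawns one deterministic substream per
iteration index (an affine map into the 32-bit seed space), so runs are
bit-reproducible, iterations are order-independent, and changing $B$ does
not change the first $b$ iterations.

# Summary statistics

Over the converged estimates of one run: the relative hazard ratio
$\mathrm{RHR} = q_{99}(\mathrm{HR}) / q_{1}(\mathrm{HR})$, the relative
P-value $\mathrm{RP} = q_{99}(-\log_{10} p) - q_{1}(-\log_{10} p)$,
significance counts at $\alpha = 0.05$, and the Janus flag (significant
estimates on both sides of $\mathrm{HR} = 1$). Percentiles use linear
interpolation between order statistics (R's default type 7); the
convention is fixed and documented because with $B = 1000$ draws the 1st
and 99th percentiles sit between order statistics and different
conventions would give visibly different RHRs. The 1/99 band (rather than
min/max) makes the summaries robust to single outlier fits. A log-HR of
exactly 0 is classified non-significant regardless of its P-value, as it
carries no direction. No multiplicity correction is applied across the
model universe: the framework's purpose is to *report* multiplicity, not
to correct it.

# The synthetic cohort generator

`generate_cohort` draws latent rows from a multivariate normal with a
given correlation matrix (Gaussian copula); continuous covariates are the
latent values, binary/ordinal covariates are thresholded latents. Event
times are exponential with rate
$\lambda_0 \exp(\sum_j \beta_j x_j)$ and censoring is independent
exponential. The exponential choice is deliberate: it admits closed-form
oracles (a two-group rate ratio equals the hazard ratio; parameter
recovery is exact in expectation), which the test suite exploits. The
generator emulates the features that drive vibration — correlated
mixed-type covariates, confounding through shared correlation, realistic
event fractions — and deliberately does *not* emulate non-proportional
hazards, time-varying covariates, informative censoring, or the weighting
structure of a real complex survey, so passing tests speak to the
engines' statistical behavior, not to any specific cohort.

`spec_from_cohort` inverts the generator: thresholds from observed
category frequencies; effect sizes from the all-adjustments Cox fit;
baseline and censoring rates moment-matched from the event fraction and
total follow-up; and the latent correlation matrix from per-pair
estimators — Pearson for continuous–continuous pairs, a closed-form
moment-based polyserial estimator
($\hat\rho = \mathrm{cov}(x_{std}, y) / \sum_k \phi(\tau_k)$) when one
margin is discretized, and a numerically solved polychoric estimator
(matching the observed score covariance to its bivariate-normal
expectation) when both are. Rank-correlation mappings (Kendall/Spearman
sine transforms) were rejected: they are noticeably biased under the
heavy ties of binary margins and missed the recovery accuracy the
round-trip tests demand. If the assembled matrix is not positive
definite it is repaired by eigenvalue clipping followed by rescaling to
unit diagonal, with a message.

The bundled `synthetic_nhanes_like.yaml` (the `synthetic` in the name is
deliberate — it is a constructed stand-in, not derived from any real
extract) defines 16 covariates: one continuous exposure with true hazard
ratio 1.30 per SD, two error-free baseline adjustments (age, sex), one
error-free ordinal adjustment (race/ethnicity analogue), and 12 error-prone
adjustments of mixed type. Correlations decay as $0.35^{|i-j|}$ — moderate,
everywhere-positive dependence of the kind adjacent health variables show;
effect sizes span $|\beta| \le 0.6$; baseline rate 0.05 and censoring rate
0.15 give roughly 25–30% events, a typical mortality-cohort fraction.
These defaults are the package's fixed study conditions, not tuning knobs.

# Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `B` | 1000 | iterations for sampling/measurement vibration |
| `fraction` | 0.5 | subsample size as a share of `n` |
| `rho` range | 0.73–0.9 | true–observed correlation (continuous/ordinal) |
| sensitivity range | 0.56–0.85 | P(observed 1 \| true 1), binary |
| specificity range | 0.73–0.98 | P(observed 0 \| true 0), binary |
| `alpha` | 0.05 | significance threshold |
| percentiles | 1 / 99 | band for RHR and RP |
| `max_k` | 20 | cap on optional adjustments ($2^k$ fits) |

The error-parameter defaults are literature-representative averages for
commonly used self-reported and examination-based variables; they are
broad on purpose, and a study with validation data should replace them
with study-specific ranges via `me_ranges()`.

# Test-suite problem sizes

The suite verifies Monte-Carlo calibration at the sizes where the checks
are sharp but still desk-scale: error-generator calibration at
$n = 2 \times 10^5$ (correlation within $\pm 0.005$) and $10^5$
(misclassification rates within $\pm 0.01$); regression-dilution at
$1.5 \times 10^5$; generator round-trips at $5 \times 10^4$; full model
universes at $k = 8$ on $n = 2000$; sampling-vibration behavior with
$B$ between 50 and 1000 on cohorts of 500–5000. These sizes are the
package's own verification design.

# Known limitations

* Only classical additive, non-differential error is modeled; systematic,
  multiplicative, heteroscedastic and outcome error are out of scope, as
  are error correlations across variables.
* The model universe is the full power set of the declared optional
  adjustments; no plausibility filtering of adjustment sets is applied,
  and no interaction or spline terms are generated.
* Measurement vibration quantifies *variability*, not bias: the reference
  fit is the error-free model, and a systematic shift of the cloud away
  from it (attenuation, or inflation under adjusted-variable error) is
  visible in the volcano plot but deliberately not folded into the RHR.
* Vibration engines assume a loaded, complete-case cohort; missing data
  handling beyond complete-case deletion at load (chosen so that every
  engine sees identical rows) is the user's responsibility.
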