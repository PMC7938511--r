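# voe — vibration of effects for survival analyses

Observational associations between an exposure and a time-to-event outcome
are famously unstable: the estimated hazard ratio depends on which
adjustment variables the analyst includes, on which subjects happened to be
sampled, and on how precisely the covariates were measured. `voe`
quantifies all three sources of instability — **model**, **sampling** and
**measurement** uncertainty — in one common framework, for a single
exposure–mortality association fitted with Cox proportional-hazards
regression.

## What it computes

For one association of interest the package generates a *set* of effect
estimates instead of a single one:

- **Model vibration** — refit the Cox model under every subset of the `k`
  optional adjustment variables (baseline adjustments such as age and sex
  stay in every model), giving `2^k` fits; the canonical layout with 13
  optional adjustments yields `2^13 = 8192` models.
- **Sampling vibration** — refit one favourite model (by default the
  all-adjustments specification) on `B = 1000` random subsets of size
  `0.5 n`, drawn without replacement.
- **Measurement vibration** — `B = 1000` times, draw error parameters
  uniformly from representative ranges (true–observed correlation
  `ρ ∈ [0.73, 0.9]` for continuous and ordinal variables, sensitivity
  `∈ [0.56, 0.85]` and specificity `∈ [0.73, 0.98]` for binary ones),
  inject error into the exposure, the adjustment variables, or both, and
  refit the favourite model. Continuous variables receive classical
  additive error `Z = X + U`, `U ~ N(0, Var(U))` with
  `Var(U) = Var(X)/ρ² − Var(X)`; binary variables are misclassified via
  sensitivity/specificity; ordinal variables go through a latent-normal
  analogue of the continuous scheme.

Each set of fits is summarized on a common scale:

- **RHR** (relative hazard ratio): ratio of the 99th to the 1st percentile
  of the hazard ratios; 1 means no vibration.
- **RP** (relative P-value): difference between the 99th and 1st percentile
  of `−log10(p)`.
- **Significance classes**: counts of negative-significant,
  non-significant and positive-significant estimates at `α = 0.05`.
- **Janus pattern**: flagged when significant estimates occur in *both*
  directions (HR > 1 and HR < 1) within one vibration set.

Results are displayed as volcano plots (HR on a log axis vs `−log10(p)`,
with a black cross at the error-free reference fit) and, for simulation
sweeps, RHR-versus-`n` trajectories with stacked significance bars.

Cox fits use `survival::coxph` with Efron ties and a robust sandwich
variance; survey weights, strata and clusters (e.g. pseudostrata and
pseudosampling units of a complex survey) enter the fit and the variance
when the cohort schema declares them. Continuous exposures are
standardized so hazard ratios are per standard deviation.

A Gaussian-copula cohort generator (`generate_cohort` /
`spec_from_cohort`) produces synthetic cohorts with correlated mixed-type
covariates and exponential Cox event times, and powers sample-size sweep
studies; a ready-made 16-covariate synthetic specification ships in
`inst/extdata/synthetic_nhanes_like.yaml`.

## Worked example

```r
library(voe)

gs <- read_generator_spec(system.file("extdata",
        "synthetic_nhanes_like.yaml", package = "voe"))
set.seed(2026)
cohort <- generate_cohort(gs, n = 2000)

# reference: favourite (all-adjustments) model on the clean cohort
fit_cox_effect(cohort, favourite_model(cohort))
#>   provenance_id    log_hr       hr         se      p_value converged
#> 1            NA 0.2894975 1.335756 0.04385773 4.088569e-11      TRUE

mv <- model_vibration(cohort,
        optional_vars = c("bmi", "sbp", "hdl_chol", "crp", "smoker",
                          "diabetes", "heart_disease", "education"),
        baseline_vars = c("age", "sex"))
summary(mv)
#> <voe_summary>
#>   RHR 1.0284  RP 1.7927  Janus FALSE
#>   significance at alpha = 0.05: 0 neg / 0 nonsig / 256 pos (0 failed)

sv <- sampling_vibration(cohort, B = 200, seed = 2026)
summary(sv)
#> <voe_summary>
#>   RHR 1.2023  RP 6.5626  Janus FALSE

me <- measurement_vibration(cohort, scenario = "both", B = 200, seed = 2026)
summary(me)
#> <voe_summary>
#>   RHR 1.1688  RP 8.0753  Janus FALSE
```

The exposure's true hazard ratio in this synthetic cohort is 1.30 per SD.
Across the 256 adjustment sets the estimate moves by less than 3%
(RHR 1.03), while half-sample subsampling moves it by 20% (RHR 1.20) and
measurement error in exposure plus adjustments by 17% (RHR 1.17) — at this
sample size the association stays significant throughout (no Janus
pattern), but the P-value swings over 6–8 orders of magnitude.

`write_results(sv, "out/")` writes a long-format `estimates.csv` (one row
per fit with provenance) and a `summary.json` with the statistics above
plus settings and seed; `render_volcano(volcano_data(sv), "volcano.png")`
draws the corresponding volcano plot.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "voe.R", package = "voe"))')" \
  measurement --gspec path/to/gspec.yaml --n 2000 --B 1000 --seed 7 --out run1
```

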