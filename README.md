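# maskmix

Mixture-model analysis of visual masking and temporal crowding in
continuous-report (orientation reproduction) experiments.

When a target stimulus is flanked in time by two distractors at the same
spatial location, its perception is impaired in two regimes: *visual
masking* at short stimulus-onset asynchronies (SOAs of tens of
milliseconds) and *temporal crowding* at SOAs of several hundred
milliseconds. In a continuous-report task the observer reproduces the
target's orientation on a circle, and the distribution of signed report
errors separates distinct failure modes: loss of precision, random
guessing, and *substitution* — reporting a distractor's orientation
instead of the target's.

`maskmix` implements the full analysis pipeline for such experiments:

* **Preprocessing** — signed circular errors relative to the target and
  to each distractor; trial exclusion (saccades, missing responses);
  participant screening by the overall-performance score
  `1 − mean|error|/180` (0.5 is the guessing floor; participants below
  0.55 are excluded).
* **Mixture models** — the error distribution is modelled as a mixture of
  a target-centred von Mises component, a uniform guessing component, and
  distractor-centred von Mises components. The *two-misreport* model

  ```
  p(θ) = (1 − g − β₁ − β₂) φ_sd(θ) + g/2π + β₁ φ_sd(θ₁*) + β₂ φ_sd(θ₂*)
  ```

  separates the substitution rates of the preceding (β₁) and succeeding
  (β₂) distractor; nested alternatives are the *swap* model (one shared
  rate β) and the *standard* model (no distractor components), plus bias
  variants with a free mean μ on the target component. All components
  share one circular sd. Fitting is maximum a posteriori (multi-start
  quasi-Newton on transformed coordinates, weak priors); models are
  compared by AICc.
* **Inference** — one-way repeated-measures ANOVAs of each parameter over
  SOA, two-way mixed ANOVAs (SOA × target-distractor similarity), partial
  η², paired *t* with Cohen's *d*, and noncentral-F power analysis for
  the repeated-measures design.
* **Segmented regression** — piecewise-linear fits of parameter estimates
  against SOA pooled across the masking and crowding ranges, with
  breakpoints found by residual-sum-of-squares profiling on a 1-ms grid,
  slope CIs, slope-difference F tests and overall model F tests. The
  breakpoint between regimes estimates the temporal limit of masking.
* **Synthetic experiments** — a generator that emulates the designs
  (5 SOAs × 100 trials + 100 unmasked baseline trials per participant,
  distinct orientations within a trial, SOA-dependent true parameters,
  between-participant heterogeneity, trial-exclusion flags), so the whole
  pipeline is testable by parameter recovery without any raw data.

## Worked example

Simulate one participant of the masking design and fit the candidate
models to the shortest-SOA cell (true parameters at 40 ms:
g = 0.05, β₁ = 0.02, β₂ = 0.25, sd = 17°):

```r
library(maskmix)

cfg <- generator_config(builtin_profiles("masking_similar"),
                        n_participants = 1, trials_per_soa = 500,
                        between_participant_sd = 0,
                        trial_exclusion_rate = 0, seed = 42)
sim <- generate_experiment(cfg)
err <- compute_errors(exclude_trials(sim$trials)$kept)
cell <- err[err$condition == "40", ]

map_fit("two_misreport", cell, seed = 1)
#> MAP fit: two_misreport  (n = 500 trials)
#>   g = 0.069  beta1 = 0.012  beta2 = 0.246  sd = 16.5 deg
#>   logLik = -440.96  AICc = 890.00

compare_models(cell, n_starts = 10, seed = 2)[, c("model", "k", "aicc", "delta_aicc")]
#>                model k   aicc delta_aicc
#> 1      two_misreport 4 890.00     0.0000
#> 2               swap 3 959.20    69.2029
#> 3          swap_bias 4 958.97    68.9774
#> 4 two_misreport_bias 5 888.93    -1.0679
```

The fitted parameters recover the generating values: most errors cluster
on the target (high target report rate 1 − g − β₁ − β₂ ≈ 0.67), a quarter
of reports substitute the succeeding distractor (β₂ ≈ 0.25), and guessing
is rare. The swap model, which forces β₁ = β₂, loses ~69 AICc points
because the two substitution rates differ strongly; the bias variant's
small gain does not survive in replicate comparisons.

## The analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic
experiments and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the masking, crowding and similarity-control experiments |
| `02_fit_models.R` | exclusion, per-cell MAP fits, per-parameter SOA ANOVAs |
| `03_model_comparison.R` | AICc comparison of all candidate models per cell |
| `04_piecewise.R` | segmented SOA regressions pooled across masking + crowding |
| `05_power_and_similarity.R` | power analysis, baseline t-test, similarity mixed ANOVAs |

Run them in order from the repository root with `Rscript analysis/01_simulate.R`
and so on.

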