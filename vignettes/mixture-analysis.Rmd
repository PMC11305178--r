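---
title: "Mixture-model analysis of masking and temporal crowding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model analysis of masking and temporal crowding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model implemented by `maskmix`,
its assumptions, the numerical choices made in the implementation, and
the design decisions that a user should know before trusting the output.
It is a methods document: it states what the code computes and why,
not empirical findings.

## The experimental setting

An observer views a target orientation flanked in time by two distractor
orientations at the same location — one preceding, one succeeding the
target by the stimulus-onset asynchrony (SOA) — and then reproduces the
target orientation by rotating a probe. The data unit is a trial with
four angles in degrees on the full circle (period 360): the preceding
distractor `d1_ori`, the target `target_ori`, the succeeding distractor
`d2_ori`, and the response `response_ori`. Preprocessing reduces each
trial to three signed circular deviations of the response, wrapped to
(−180, 180]:

* `theta` — response minus target,
* `theta1` — response minus preceding distractor,
* `theta2` — response minus succeeding distractor.

## The mixture models

The signed target error θ is modelled as a finite mixture. The fullest
model in the candidate set, the **two-misreport** model, has density
(per radian; the package accepts and reports degrees and converts
internally)

$$
p(\theta) \;=\; (1 - g - \beta_1 - \beta_2)\,\varphi_\sigma(\theta)
\;+\; \frac{g}{2\pi}
\;+\; \beta_1\,\varphi_\sigma(\theta_1^\ast)
\;+\; \beta_2\,\varphi_\sigma(\theta_2^\ast),
$$

where $\varphi_\sigma$ is a von Mises density centred at zero whose
concentration κ corresponds to circular standard deviation σ, $g$ is the
probability of a uniform random guess, and $\beta_1, \beta_2$ are the
probabilities of reporting the preceding and succeeding distractor
(evaluated at the response's deviation from that distractor,
$\theta_j^\ast$). The complement $1 - g - \beta_1 - \beta_2$ is the
**target report rate**, the package's primary performance measure.

The candidate set, in increasing order of free parameters:

| model | free parameters | k |
|---|---|---|
| `standard` | g, σ | 2 |
| `swap` | g, β, σ (β split equally over the two distractors) | 3 |
| `standard_bias` | g, σ, μ | 3 |
| `swap_bias` | g, β, σ, μ | 4 |
| `two_misreport` | g, β₁, β₂, σ | 4 |
| `two_misreport_bias` | g, β₁, β₂, σ, μ | 5 |

Assumptions shared by all models:

* one common circular sd σ for all von Mises components — target and
  distractor reports are assumed equally precise;
* mixture weights constant within a participant × condition cell;
* trials independent given the cell's parameters;
* in the `_bias` variants the shift μ applies to the **target component
  only**. A systematic attraction/repulsion of the report toward a
  distractor shows up as a shift relative to the target, not relative to
  the distractor the observer (mistakenly but veridically) reproduces.
  This is a design decision; a model with shifted distractor components
  would not be identifiable from the same data without extra structure.

## Fitting: maximum a posteriori

Parameters are estimated per participant × condition cell by maximising
the log posterior with weak priors:

* mixture weights: uniform on the simplex;
* σ: Jeffreys-type 1/σ, truncated to [0.25°, 100°];
* μ: uniform on (−180°, 180°].

The priors act only as mild regularisers; with typical cell sizes
(≥ 100 trials) the MAP estimate is essentially the MLE. The optimum is
reported in the original parameterisation (no Jacobian correction), i.e.
it is the mode of the posterior in (g, β, σ, μ) coordinates.

Numerically, the posterior is maximised by BFGS (`stats::optim`) on
unconstrained coordinates: a softmax over mixture weights anchored on
the target component, a scaled logit for σ in [0.25, 100], and a scaled
logit for μ in (−180, 180). Multi-start is essential — the likelihood
has well-separated local optima (e.g. a "label-switched" mode in which
the target component absorbs a distractor). The package uses one
deterministic start (small non-target weights, σ = 15°, μ = 0) plus
random starts with Dirichlet(1) weights and log-uniform σ, which
together cover both the interior and the corners of the simplex
(including g → 1 for pure guessers). `n_starts = 20` (the default) is
conservative for 100-trial cells; comparisons across many cells remain
stable down to about 5 starts.

### Numerical choices

* **Density floor.** Component densities are floored at 10⁻³⁰⁰ before
  taking logs, so a single outlying trial cannot produce −Inf and kill a
  whole optimisation path.
* **σ ↔ κ conversion.** σ_rad = √(−2 ln(I₁(κ)/I₀(κ))), computed with
  exponentially scaled Bessel functions to avoid overflow at large κ,
  and inverted by `uniroot` on log κ over [10⁻⁶, 10⁴]. σ is capped at
  100° (beyond which the von Mises is visually indistinguishable from
  uniform and κ underflows); κ = 0 is a sentinel for "uniform".
* **σ lower bound 0.25°.** Below this the likelihood of a discrete-grid
  response variable degenerates; the bound is far below any plausible
  perceptual noise.

## Model comparison

Models are compared by AICc,
$\mathrm{AICc} = -2\ln L + 2k + 2k(k+1)/(n-k-1)$,
using the *likelihood* at the MAP (the prior is a regulariser, not part
of the model's evidence). `compare_models()` reports
ΔAICc anchored on the two-misreport model: positive values mean
two-misreport is preferred over that row's model. Two properties of
AICc worth knowing when reading these tables:

* For nested models differing by one parameter, the richer model wins
  whenever twice the log-likelihood gain exceeds ≈ 2.03 (for n ≈ 100),
  which happens by chance with probability ≈ 15% under the smaller
  model (χ²₁). A minority of cells "preferring" a bias variant is
  therefore expected even when there is no bias.
* When the true substitution rates are equal (β₁ = β₂), the swap model
  is the correct, cheaper description and *should* win; the
  two-misreport model earns its keep only when the rates differ.

## Inference across participants

Per-parameter estimates are analysed with standard linear-model
machinery, bought from `stats`:

* one-way repeated-measures ANOVA over SOA
  (`aov(value ~ level + Error(participant/level))`);
* two-way mixed ANOVA with a between-participant factor
  (`aov(value ~ between*within + Error(participant/within))`);
* partial η² = F·df₁ / (F·df₁ + df₂);
* paired t-tests with Cohen's d = mean(diff)/sd(diff);
* a-priori power for the repeated-measures design via the noncentral F
  distribution with λ = f²·(u + v + 1), u = df₁, v = df₁(N − 1),
  f² = η²ₚ/(1 − η²ₚ). `min_sample_size()` searches N upward until the
  target power is reached.

Degenerate inputs are handled explicitly: a parameter that is constant
across all cells yields F = 0, p = 1 rather than an `aov` error, and a
paired t on identical vectors yields t = 0, d = 0, p = 1.

## Segmented (piecewise-linear) regression

Parameter estimates pooled across the masking and crowding SOA ranges
are regressed on SOA with a continuous piecewise-linear ("hinge") model
with 1 or 2 breakpoints. Choices:

* **Breakpoint search**: exhaustive residual-sum-of-squares profiling on
  a 1-ms grid between the observed SOA extremes, with a minimum gap of
  10 ms between breakpoints and from the boundaries. The grid matches
  the measurement resolution of SOA; ties are broken toward the earliest
  breakpoint.
* **Residual df**: n − (2 + 2·n_break) — the breakpoints are counted as
  estimated parameters.
* **Slope standard errors**: delta method on the full nonlinear
  least-squares Jacobian, including the breakpoint columns
  (∂/∂c of the hinge term is −b·1[x > c]). Conditioning on the estimated
  breakpoint — the common shortcut — ignores breakpoint uncertainty and
  undercovers noticeably in simulation (≈ 81% for a nominal 95% CI in
  this package's test scenarios); the delta-method CIs restore ≈ 93–96%
  coverage. The Jacobian cross-product is inverted via an SVD
  pseudo-inverse so that a vanishing hinge coefficient (which makes its
  breakpoint column zero) degrades gracefully to the conditional SE.
* **Tests**: `slope_difference_test()` compares the segmented fit to a
  single straight line (F with df₁ = n_break extra slope parameters, not
  counting breakpoints); `overall_model_test()` compares it to an
  intercept-only model (df₁ = 2·n_break + 1).

These SEs and tests treat the pooled per-participant estimates as
independent observations; they ignore the repeated-measures structure
(each participant contributes several SOAs) and the first-stage
estimation error in the parameter estimates themselves.

## The synthetic-experiment generator

Because the package ships no raw data, correctness is established by
parameter recovery on synthetic experiments that emulate the real
designs:

* 5 SOAs × `trials_per_soa` masked trials plus `baseline_trials`
  unmasked trials per participant, shuffled within participant;
* target and distractor orientations drawn as *distinct* integers in
  0–359 within each trial;
* responses drawn from the generating mixture by explicit component
  sampling (guess / target / distractor-1 / distractor-2), with von
  Mises noise generated by the Best–Fisher rejection sampler;
* SOA-dependent true parameters from named profiles
  (`builtin_profiles()`): a masking profile whose guessing and
  substitution rates peak or cross within 40–120 ms, and crowding
  profiles whose precision and substitution rates relax over
  175–475 ms;
* between-participant heterogeneity by jittering each participant's
  parameters on logit/log scales (`between_participant_sd`), with the
  non-target weight simplex rescaled if it exceeds 0.95 and σ clamped to
  [1, 100]°;
* a fraction of trials (`trial_exclusion_rate`) flagged for exclusion,
  split between saccade flags and missing responses (missing responses
  have `NA` in the response column).

What the generator does *not* emulate: sequential effects across trials,
response-grid discretisation beyond integer stimulus orientations,
lapses correlated with SOA, or any perceptual mechanism — it samples
from the analysis model itself (plus heterogeneity). It is therefore a
tool for verifying the *pipeline*, not for adjudicating between
psychological theories: recovery success shows the estimator works when
the model is true, and the built-in profile shapes are illustrative
choices of this package, not measurements.

The problem sizes used by the `analysis/` scripts (15–16 participants,
100 trials per cell, the specific SOA grids and profiles) are likewise
this package's own choices for a realistic demonstration.

## Exclusion rules

* Trials flagged as saccade-contaminated or lacking a response are
  dropped before any fitting.
* Participants are screened by the overall-performance score
  $1 - \overline{|\theta|}/180$, which is 0.5 in expectation for a
  uniform guesser and 1 for a perfect responder. Participants scoring
  below 0.55 (strict inequality: exactly 0.55 is kept) are excluded.

## Limitations

* The shared-σ assumption is substantive; if distractor reports are
  noisier than target reports, β estimates absorb the mismatch.
* AICc-based selection with ~100 trials per cell has limited power to
  detect small bias terms and a known ~15% false-preference rate for
  one-extra-parameter variants.
* Segmented-regression inference ignores participant clustering and
  first-stage uncertainty (see above); its p-values are descriptive for
  pooled estimates, not a substitute for the repeated-measures ANOVAs.
* The power analysis assumes sphericity and the stated effect size; it
  inherits all the usual caveats of noncentral-F power calculations.
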