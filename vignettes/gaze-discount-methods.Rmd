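---
title: "Measuring the gaze discount: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the gaze discount: models, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeddm)
```

## The scientific question

In binary value-based choice, people tend to choose the option they
look at longer, and sequential-sampling models explain this with a
gaze-dependent drift rate: while an option is fixated, the value of
the *other* option is multiplied by a discount weight `θ ∈ [0, 1]`.
Because the discount acts multiplicatively on item values, its
behavioral footprint scales with the overall value (OV) of the items
on screen: with high-value pairs, shifts of gaze swing the drift rate
strongly (fast decisions, strong coupling of choice to dwell time),
while with low-value pairs gaze barely matters. An intervention that
weakens the gaze discount (raises `θ`) should therefore show up most
clearly as a reduced *OV × dwell-time-advantage* interaction on
choice, and as a change in the fitted `θ` itself. This package
implements both sides of that argument: the generative simulator and
the estimation/analysis machinery.

## The generative model

The simulator (`simulate_trial()`) accumulates a relative decision
value in 1-ms Euler steps. During left fixations the mean increment
is `d (r_left − θ r_right)`; during right fixations it is
`d (θ r_left − r_right)`; Gaussian noise of SD `σ` is added once per
millisecond. The trial ends at the first step at or beyond `±1`
(left at the upper boundary); the final dwell is truncated at the
crossing. There is no sub-millisecond interpolation — the discrete
update rule is taken literally.

**Scale conventions.** The boundary magnitude and starting value are
not separately identified from `d` and `σ`, so they are fixed at 1
and 0 (a symmetric-start offset is configurable for bias
simulations). Defaults `d = 2e-4 ms⁻¹` and `σ = 0.02 ms⁻¹ᐟ²`-scale
noise give human-plausible 1–3 s decision times on a 0–10 rating
scale; both are configurable everywhere.

A trial that has not crossed by 20 s (configurable) raises an error:
with valid parameters this happens only in the far tail of the
driftless case, and the experiment generator re-draws such trials
(up to 10 times) the way degenerate trials are excluded in practice.

## Estimation: collapsing gaze to per-trial fractions

Fitting a time-inhomogeneous drift is deliberately avoided. Instead,
gaze is summarized per trial by the fractions `g_left, g_right`
(normalized over item-directed dwell time; whether non-item gaze
should enter the denominator is not decidable in general, so the
item-only normalization is the default and the alternative remains a
caller-side choice when building the gaze summaries). The trial's
drift is modeled as

`v = β0 + β1(r_L g_L − r_R g_R) + β2(r_L g_R − r_R g_L) + β3(g_L − g_R)`

and the likelihood is the analytic Wiener first-passage density
(diffusion coefficient 1, parameters `a`, `z`, `Ter`), mixed with a
5% uniform contaminant over the observed RT range. `β1 = β2` is the
special case of no multiplicative gaze effect; in the amplification
regime the discount is the ratio `θ = β2/β1` (`compute_theta()`
refuses the ratio when `β1 ≤ 1e-6`).

The density uses the standard small-time/large-time series with the
term counts chosen from truncation error bounds (target accuracy
`1e-10` by default) and switches to whichever representation needs
fewer terms; evaluation is in log space so extreme parameters
degrade to `-Inf` rather than to invalid values. Unit tests verify
normalization to `1e-5` by quadrature, the reflection identity, the
closed-form mean decision time, and agreement of the implied choice
probabilities with a corrected Euler simulation.

**Attenuation is expected.** Because the generative drift switches
within a trial while the fitted drift is constant, the recovered `θ̂`
is a compressed version of the generating `θ`; the recovery tests
assert the bands `θ̂ ∈ [0.10, 0.34], [0.34, 0.58], [0.73, 0.98]` for
generating values `0.3, 0.6, 0.9`, frozen from independent
large-sample reference fits. Ordering and group contrasts are
preserved — which is what the scientific argument rests on — but
absolute values of `θ̂` should not be read as unbiased estimates of
the simulator's `θ`.

## Subject-level maximum likelihood

`fit_subject_mle()` maximizes the mixture likelihood over
`(a, z, Ter, β0..β3)` with `L-BFGS-B` from three documented starting
points, bounds keeping `a ∈ [0.3, 8]`, `z ∈ [0.05, 0.95]` and `Ter`
below the subject's minimum RT, and the outlier weight fixed at
0.05. Standard errors come from the numerical Hessian at the
optimum. Non-convergence from every start is reported explicitly
(`converged = FALSE` with the best incumbent), never silently.

## Hierarchical Bayesian fit

`fit_hierarchical()` places subject parameters under group-level
normals (location–scale). Priors are weakly informative: group means
normal with wide scales centered at `a = 2`, `z = 0.5`,
`Ter = 0.4 s`, `β = 0`, restricted to the valid region; group SDs
half-normal. The sampler is Metropolis-within-Gibbs:

* subject parameters: adaptive random-walk Metropolis, one parameter
  at a time, plus a joint `(β1 + e, β2 − e)` proposal — the gaze
  regressors make `β1 + β2` well constrained but `β1 − β2` diffuse,
  and without the joint move that direction (and hence `θ`) mixes
  slowly;
* group means: conjugate Gibbs draws;
* group SDs: Metropolis on the log scale.

Proposal scales adapt toward ~44% acceptance during burn-in only, so
the retained chains are a valid fixed-kernel sampler. The default
configuration is 3 chains × 10,000 iterations with 5,000 burn-in;
recovery checks on synthetic data use 3 × 6,000 with 3,000 burn-in,
which is where the Gelman–Rubin statistics of all 14 group-level
parameters drop below 1.1 on the reference problem (20 subjects ×
200 trials). Convergence is flagged only when every r-hat is below
1.1; otherwise the result carries a warning and
`converged = FALSE`.

Group comparisons report (i) `P(A < B)` by randomly pairing draws
from the two independent group posteriors (10,000 pairs, seeded) and
(ii) Welch t-tests (unequal variances, Welch–Satterthwaite df) on
subject-level posterior means.

## Behavioral statistics

All regressions are GLMs with cluster-robust (CR1) sandwich standard
errors clustered on subjects, the estimator used as the robustness
check when crossed-random-effects models fail to converge; full
GLMMs are out of scope by design. Implemented analyses: first
fixation (left-first and best-first, `~ OV × group`), log dwell
durations per ordinal class (`~ group × position × OV × VD`), the
choice model (`~ VD + group × OV × dwell-advantage`, with
VD-interaction, trial-number and gaze-bias-split robustness
variants), log-RT (`~ |VD| + group × OV`) with per-subject median
paired t-tests, pooled two-sample K-S comparisons of RT
distributions, and subject-level dwell-advantage quintile curves
(labels −2..+2, midpoint-rank tie-break). OV enters as a low = 0 /
high = 1 dummy by default. No multiple-testing correction is applied;
p-values are reported raw.

## The synthetic experiment generator

`generate_dataset()` emulates the study design the analyses assume:
45 subjects split 23/22 between a stimulation ("fef") and control
("vertex") group with gaze discounts 0.902 and 0.744; 180 trials per
subject among 148 items rated 0–10 in two value pools (low 1–4, high
7–10) so both OV conditions are populated and the value difference
is constrained to {−1, 0, +1}; fixation streams that start left with
probability 0.693 and strictly alternate; gamma dwell durations
(first dwells mean 400 ms, middle 650 ms, shape 3 — the ordinal
facts, first-shorter-than-middle, are what matters; no duration
distributions are on record, so the gamma family and these means are
the package's own calibration); subject non-decision times normal
(0.68 s ± 0.08, truncated at 0.2 s), anchored to typical fitted
group values. `generate_ddm_dataset()` is the estimation-side
counterpart that draws subject parameters from known group normals
and simulates from the fitted model itself (Euler with the
0.5826·√dt boundary continuity correction, which removes the
discretization's overshoot bias) — used for self-consistency
recovery.

**What the generator does not emulate:** rating noise and menu
effects, non-item (elsewhere) gaze, within-subject drift of
parameters over the session, saccade dynamics, and any direct effect
of the manipulation on fixation durations. Passing recovery tests on
these data therefore shows the estimation machinery is correct and
the design is sensitive, not that real data meet the model's
assumptions.

## Problem sizes used in the checks

The shipped test suite runs recovery at sizes chosen to make the
checks sharp but routine on a laptop: 10⁶ Euler paths for the
likelihood cross-check; 5,000-trial single-subject fits at
`θ ∈ {0.3, 0.6, 0.9}` over 10 seeds; one 20-subject × 200-trial
hierarchical recovery; ten full 45-subject × 180-trial end-to-end
replicates. The tolerance bands for `θ̂` were frozen from independent
10,000-trial reference fits before the suite was assembled.

## Known limitations

* `θ̂` is attenuated relative to the simulator's `θ` (see above);
  only ordering and contrasts are interpreted.
* The Welch t-test on subject-level `θ̂` treats the per-subject
  estimates as data, ignoring their estimation error.
* The K-S tests pool trials and ignore the repeated-measures
  structure — they are reported, as is conventional, with that
  caveat.
* The hierarchical sampler is a general-purpose random-walk scheme;
  for much larger designs a gradient-based sampler would be the
  natural upgrade.
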