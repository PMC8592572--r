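# gazeddm

Simulation and estimation tools for the **attentional drift diffusion
model (aDDM)** of binary value-based choice, together with the
behavioral and hierarchical-Bayesian analyses used to test whether an
experimental manipulation (e.g. inhibitory brain stimulation over a
control region vs. an attention-controlling region) changes the
multiplicative effect of gaze on choice.

The package is aimed at decision-modelling researchers who want a
self-contained, tested pipeline: simulate two-condition eye-tracking
choice experiments, fit the gaze-weighted diffusion model by maximum
likelihood or MCMC, and run the standard fixation/choice/RT analyses —
all on tidy trial and fixation tables.

## The model

While the left item is fixated, the relative decision value follows

    V_t = V_{t-1} + d (r_left − θ r_right) + ξ,   ξ ~ N(0, σ²)

and during right fixations

    V_t = V_{t-1} + d (θ r_left − r_right) + ξ,

with one update per millisecond; the left item is chosen when `V`
reaches `+1`, the right item at `−1`. The gaze discount `θ ∈ [0, 1]`
scales down the unfixated item's value: `θ = 1` is a standard DDM,
lower `θ` means gaze amplifies the fixated value more.

At fitting time, gaze is collapsed to per-trial fractions
`g_left, g_right` and the trial-wise drift is regressed as

    v = β0 + β1 (r_L g_L − r_R g_R) + β2 (r_L g_R − r_R g_L) + β3 (g_L − g_R)

inside a Wiener first-passage-time likelihood (boundary separation
`a`, relative start `z`, non-decision time `Ter`, 5% uniform outlier
mixture). When `β1 > β2`, gaze amplifies value and the discount is
recovered as **`θ = β2 / β1`**.

## Worked example

```r
library(gazeddm)

# a two-group synthetic experiment: 23 "fef" subjects at theta = 0.902,
# 22 "vertex" subjects at theta = 0.744, 180 trials each
ds <- generate_dataset(experiment_config(seed = 301))

# subject-level maximum-likelihood fits, then group means of theta
fits <- fit_subjects_mle(ds)
tapply(fits$theta, fits$group, mean)
#>       fef    vertex
#> 0.8926591 0.6322296

# choice model: group x overall-value x dwell-advantage interaction
f <- analyze_choice(ds)
f$coefficients["fef:ov:dwell_adv"]; f$p["fef:ov:dwell_adv"]
#> -0.5591052
#> 0.0004820646
```

The fitted gaze discounts preserve the generative ordering (the
control group, simulated with the stronger discount, recovers the
lower `θ̂`; both estimates are attenuated relative to the generating
values because the fit collapses the time-varying gaze drift to
per-trial fractions). The negative triple interaction is the model's
behavioral signature: the gaze-on-choice effect grows less from low-
to high-value trials in the group with the weaker discount
manipulation.

## Command-line interface

A thin CLI over the same functions is installed at
`inst/cli/gazeddm`:

```sh
Rscript inst/cli/gazeddm simulate --out data/ --seed 7
Rscript inst/cli/gazeddm fit --trials data/trials.csv \
    --fixations data/fixations.csv --out fits/ --hierarchical --fast
Rscript inst/cli/gazeddm analyze --trials data/trials.csv \
    --fixations data/fixations.csv --out report/
```

See `vignettes/gaze-discount-methods.Rmd` for the full methods
account: model assumptions, priors, sampler design, generator
calibration, and known limitations.
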