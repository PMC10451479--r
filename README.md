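# rbdprt

Reward Behavior Disengagement (RBD) analysis for the Probabilistic
Reward Task (PRT), for clinical researchers studying reward impairment
in depression: an economic, ideal-observer scoring of PRT behavior, an
objective engaged/disengaged cutoff derived against healthy controls,
and a longitudinal test of whether that classification moderates
antidepressant response.

## What it computes

The PRT rewards correct identifications of an ambiguous stimulus on an
asymmetric 3:1 schedule (rich vs lean stimulus, 20¢ per reward), which
pulls an engaged participant's decision criterion toward the rich
response. Behavior in a block is modelled as equal-variance Gaussian
signal detection (sensitivity *d′*, criterion *c*). The expected
earnings of a criterion are

EV(c) = P(rich)·Φ(d′/2 − c)·V_r + P(lean)·Φ(c + d′/2)·V_l,

maximized at c\* = ln β\*/d′ with
β\* = [P(lean)·V_l]/[P(rich)·V_r]. RBD is the per-trial earnings a
participant forgoes relative to that ideal observer,

RBD = EV(c\*(d̂′)) − EV(ĉ)  (cents/trial),

estimated from each block's zero-cell-corrected hit and false-alarm
rates. The classical PRT measures log *b* (response bias) and log *d*
(discriminability) are computed alongside. A univariate quadratic
discriminant fit of block-2 RBD (depressed vs controls) yields a single
upper cutoff; scores at or above it classify a subject as *reward task
disengaged*. Subgroups are profiled with uncorrected Pearson chi-square
tests and Cochran–Cox unequal-variance t-tests, and the clinical payoff
is tested in a repeated-measures linear mixed model of HAMD-17 on
baseline + treatment × engagement × log(week), with a subject random
intercept and spatial-power (continuous-time AR(1)) residual
correlation — the moderation hypothesis being the 3-way interaction.

A parametric simulator generates the full study design (195 depressed +
40 control subjects, 200 trials in 2 blocks, 70/30 engaged/disengaged
mixture, HAMD-17 visits at weeks 0–8 under sertraline vs placebo with a
disengaged-only drug effect) for power, calibration and recovery
studies.

## Worked example

```r
library(rbdprt)

report <- run_pipeline(pipeline_config(cohort = cohort_config(seed = 11L)))
print(report)
#> PRT disengagement pipeline report
#>   seed 11, 195 MDD + 40 HC subjects (hash c79e6018)
#>   QDA cutoff on block-2 RBD: 0.2899
#>   MDD classification: 111 engaged, 84 disengaged
#>   moderation (3-way) estimate -2.402, Wald z = -4.336, p = 1.452e-05
```

The cutoff (0.29 cents/trial of forgone earnings) is where the
depressed posterior overtakes the healthy-control posterior: depressed
subjects at or above it are labelled disengaged — 84 of 195 here, of
whom 73 are truly disengaged under this seed's phenotype draw (93.3%
of labels match the generating phenotype). The negative 3-way
coefficient says the sertraline–placebo difference in log-week slope
is ~2.4 HAMD-17 points steeper among disengaged than engaged subjects
(generating value −3), and the Wald test rejects the no-moderation
null.

Individual stages are available as plain functions:
`simulate_session()`, `tabulate_blocks()`, `response_bias()`,
`compute_rbd()`, `fit_qda_1d()`, `classify()`, `compare_groups()`,
`fit_moderation_model()`, `fitted_trajectories()`. A thin command-line
front end with `simulate` / `score` / `classify` / `outcomes` /
`report` subcommands lives at `exec/rbdprt`. See
`vignettes/rbd-methodology.Rmd` for the model, assumptions, parameter
defaults and limitations.

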