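---
title: "Reward Behavior Disengagement: model, cutoff, and moderation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward Behavior Disengagement: model, cutoff, and moderation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the measurement problem

The probabilistic reward task (PRT) presents, over two blocks of 100
trials, an ambiguous stimulus that must be identified as one of two
alternatives ("rich" vs "lean"). Correct identifications are rewarded
(20 cents) on a deliberately asymmetric schedule: correct responses to
the rich stimulus are rewarded three times as often as correct responses
to the lean one. Healthy participants exploit the asymmetry, drifting
their decision criterion toward the rich response over the session. The
classical summary of that drift is the signal-detection response bias

$$\log b = \tfrac{1}{2}\log_{10}
  \frac{\mathrm{Rich_{correct}}\cdot\mathrm{Lean_{incorrect}}}
       {\mathrm{Rich_{incorrect}}\cdot\mathrm{Lean_{correct}}},$$

with discriminability
$\log d = \tfrac12\log_{10}
  \frac{\mathrm{Rich_{correct}}\cdot\mathrm{Lean_{correct}}}
       {\mathrm{Rich_{incorrect}}\cdot\mathrm{Lean_{incorrect}}}$
as its accuracy counterpart. Both use base-10 logarithms, and both
receive the conventional all-or-none correction — 0.5 added to every
cell whenever any cell is zero — so they stay finite
(`response_bias()`, `discriminability()`).

Response bias describes *how much* a participant shifted, but not *how
much the shift was worth*. This package's central quantity, Reward
Behavior Disengagement (RBD), asks the economic question instead: given
the task's payoff structure, how far short of the reward-maximizing
policy did the participant's behavior fall?

## The ideal observer and the EV-shortfall score

Behavior in a block is modelled as equal-variance Gaussian signal
detection: trial evidence is drawn from $N(+d'/2, 1)$ on rich trials and
$N(-d'/2, 1)$ on lean trials, and the participant responds "rich"
whenever evidence exceeds a criterion $c$ (positive $c$ therefore favors
"lean" responses). The expected earnings of a criterion are exact
Gaussian-tail arithmetic (`expected_value()`):

$$EV(c) = P(\mathrm{rich})\,\Phi(d'/2 - c)\,V_r
        + P(\mathrm{lean})\,\Phi(c + d'/2)\,V_l - \text{effort},$$

where $V_s$ is reward magnitude times the probability a correct response
to stimulus $s$ is rewarded (12 and 4 cents under the default 3:1
schedule). Setting $EV'(c) = 0$ gives the reward-maximizing criterion

$$c^* = \frac{\ln \beta^*}{d'}, \qquad
  \beta^* = \frac{P(\mathrm{lean})\,V_l}{P(\mathrm{rich})\,V_r},$$

which under the default schedule is negative: the ideal observer
over-calls "rich" (`optimal_criterion()`).

The default RBD form, registered under the method tag `ev_shortfall`, is
the per-trial expected value forgone:

$$\mathrm{RBD} = EV\!\big(c^*(d̂')\big) - EV(\hat c),$$

with $\hat d'$ and $\hat c$ estimated from the block's
zero-cell-corrected hit and false-alarm rates by the usual z-transform.
Because that estimate reproduces the observed rates exactly, the
subtrahend equals the expected earnings implied by the empirical rates
themselves; when a reference sensitivity is imposed (for instance to
score a chance-level responder), the observed side remains the empirical
value, so a uniform random responder under the default payoff scores
$EV(c^*) - 4$ cents per trial. The score is zero exactly at the optimum,
grows strictly as the criterion moves away on either side, and is
invariant to relabeling the two stimuli together with the payoff.

Two numerical choices matter here. First, a sensitivity floor
(`d_floor = 0.05`): at $d' \le 0$ the $EV$ curve is flat and the optimal
criterion is undefined, so near-zero empirical sensitivities are floored
and produce near-zero shortfalls — a participant who cannot discriminate
forgoes almost nothing by not shifting, which is the honest answer of an
earnings-based score, though arguably not of a clinical one. Second,
units are cents per trial; the flat effort-cost parameter is retained in
the payoff object but cancels from the shortfall difference.

The functional form sits behind a registry (`rbd_methods()`,
`register_rbd_method()`): every downstream stage consumes one scalar per
block, so alternative disengagement forms can be swapped in without
touching the classifier or the outcome model. A log-compressed variant
was evaluated during development and rejected: spreading the near-zero
engaged scores over a long left tail degrades the downstream Gaussian
classification rather than helping it.

## The objective cutoff

Depressed participants are classified from their block-2 RBD — the block
in which the reinforcement asymmetry has been experienced and can be
exploited. A univariate quadratic discriminant model (`fit_qda_1d()`)
fits a Gaussian to each group's block-2 scores (unbiased variances, the
healthy-control sample being small) and solves

$$\log\big[\pi_1\,\phi(x;\mu_1,\sigma_1)\big] =
  \log\big[\pi_2\,\phi(x;\mu_2,\sigma_2)\big],$$

a quadratic with two roots when the variances differ. The operative
cutoff is the root above the control mean beyond which the depressed
posterior dominates for all larger values; scores at or above it label
the subject *disengaged* (ties go to disengaged). The lower root is
reported but never used for labeling — the clinical rule is a single
upper threshold on disengagement.

Priors are configurable. `fit_qda_1d()` defaults to empirical class
frequencies, but the pipeline passes equal priors, for a geometric
reason worth stating plainly: with a roughly 5:1 depressed:control
imbalance and the larger mixture variance of the depressed group, the
empirical-prior posterior for depression can dominate the entire real
line — the discriminant has no real roots and no cutoff exists. Equal
priors ask the question the cutoff is actually meant to answer — where
does this score leave the healthy range? — and reproduce the expected
geometry of a threshold sitting above both group means.

The engaged/disengaged split is then profiled against baseline features
(`compare_groups()`): categorical features by the uncorrected Pearson
chi-square (`chisq_independence()`), continuous scales by the
unequal-variance t-statistic assessed primarily with the Cochran–Cox
weighted-critical-value approximation, with the Welch–Satterthwaite
result reported alongside (`cochran_cox_ttest()`). The Cochran–Cox
p-value is obtained by inverting the weighted critical value in the
level; it is never smaller than the Welch p-value, making it the
conservative of the two. Sensitivity and specificity of the flag for
group membership come with Wilson score intervals by default
(Clopper–Pearson behind a flag).

## The moderation model

Whether disengagement moderates drug response is tested on HAMD-17
trajectories with a repeated-measures linear mixed model
(`fit_moderation_model()`): response at weeks 1, 2, 3, 4, 6, 8; fixed
effects baseline HAMD-17 (the week-0 score, entered as a covariate and
excluded from the response), treatment, engagement label, log-week, and
all interactions; a random intercept per subject; and spatial-power
residual correlation $\rho^{|\Delta\text{week}|}$, i.e. continuous-time
first-order autoregression over the real week axis, which handles the
unequal 4→6→8 spacing exactly (nlme's `corCAR1`). Natural log is used
for the time transform; the base only rescales slope coefficients.
Baseline never enters the log (week 0 is not a response visit), so
$\log 0$ never arises.

The moderation hypothesis is the three-way treatment × label × log-week
coefficient. The primary test is a large-sample Wald z on that
coefficient; the fit's own conditional t (with nlme's inner–outer
degrees of freedom) is reported alongside, since small-sample
denominator-degrees-of-freedom conventions differ across software and
none is canonical here. Estimation is REML with the autocorrelation
profiled from three starting values (0.2, 0.5, 0.8), keeping the best
restricted likelihood among converged fits; fixing $\rho = 0$ reduces
the model to independent residuals (used by the reduction tests).
Missing visits are handled by likelihood under
missing-at-random; no imputation.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the study conditions end to end: 195
depressed and 40 control participants, 200 trials each in two blocks,
30 rich + 10 lean rewards scheduled per 100-trial block (the 3:1
asymmetry at 20 cents, equiprobable stimuli), and a 70/30
engaged/disengaged mixture within the depressed group. Rewards are
delivered by a controlled scheduler: scheduled rewards whose trial is
answered incorrectly stay pending until the next correct response to the
owed stimulus, so delivered rewards never exceed targets and are only
ever attached to correct responses.

Each subject is a signal-detection agent whose block-2 criterion has
moved a fraction *engagement* of the way from its block-1 starting point
(default 0, neutral) toward $c^*$. Learning is expressed as this single
block-to-block shift — all statistics in the analysis are block-level,
so trial-by-trial criterion dynamics are deliberately out of scope. The
phenotype distributions are the package's definition of well-separated
phenotypes: engaged subjects and controls share
$d' \sim N(1.0, 0.15)$, engagement $\sim N(0.85, 0.05)$ and a 2% lapse
rate, while disengaged subjects barely adjust (engagement
$\sim N(0.05, 0.03)$) and lapse into stimulus-independent responding on
20% of trials — haphazard responding being part of the disengagement
construct, not an extraneous nuisance. Under these conditions the
end-to-end pipeline recovers true phenotype labels with accuracy above
0.9, a property exercised directly by the test suite.

Two honest limitations follow from the same arithmetic. With 100 trials
per block, the criterion estimate carries a standard error near 0.16,
which is the dominant source of label error — no classifier can undo
it. And because any valid disengagement score is minimized at $c^*$ and
rises on both sides, engaged subjects whose estimated criterion
overshoots the optimum fold back to elevated scores; the within-class
score distributions are therefore right-skewed, and the Gaussian
assumption of the discriminant is an approximation, not a theorem. The
simulator also does not emulate: practice-phase effects, reaction-time
structure beyond optional Gaussian noise, site effects, dropout that
depends on outcome, or evidence-accumulation dynamics. Passing tests on
this cohort demonstrate that the pipeline's statistics do what they
claim under the generating model; they cannot certify the generating
model as a portrait of any real clinical sample.

HAMD-17 trajectories (`simulate_outcomes()`) mirror the fitted model:
latent baseline $N(22, 4)$, per-cell slopes on log-week (defaults −3.0
for both engaged arms, −1.5 for disengaged-placebo, −4.5 for
disengaged-sertraline, so the drug–placebo separation exists only among
the disengaged and the generating three-way coefficient is −3.0),
random intercept sd 3, residual sd 3 with $\rho = 0.5$ per week, scores
rounded then clamped to 0–52 after noise, and 5% of post-baseline visits
missing completely at random. With these defaults the moderation test's
power comfortably exceeds one half while its size stays near the nominal
5% under the null — both checked by simulation in the test suite at 200
replicates.

## Problem sizes and reproducibility

The test and acceptance suites use the study-sized cohort (235 subjects,
47,000 trials) for single end-to-end runs, 200 replicates for the
cutoff-recovery and mixed-model calibration checks, and reduced cohorts
(60–160 depressed subjects) for structural unit tests — sizes chosen so
the full suite completes in minutes while keeping Monte Carlo error
small relative to the margins being tested. Every simulation consumes an
explicit integer seed, and the pipeline report is a pure function of its
configuration; the run log records seed, group sizes and a parameter
hash so two reports can be compared at a glance.

```{r, eval = FALSE}
library(rbdprt)
report <- run_pipeline(pipeline_config(cohort = cohort_config(seed = 1L)))
print(report)
plot_trajectories(report$moderation_fit)
```
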