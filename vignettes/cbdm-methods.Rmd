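---
title: "Modelling cost-benefit decision-making under drug manipulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cost-benefit decision-making under drug manipulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

`cbdm` models binary cost-benefit choices from within-subject
pharmacological crossover experiments. On every trial a participant
chooses between a high-reward/high-cost option and a
low-reward/low-cost option. Two cost domains are covered:

* **Effort**: rewards of 2-16 "apples" against grip forces of 0-80% of
  the participant's maximum voluntary contraction (MVC), 125 trials in
  5 blocks per session, both options varying on both dimensions.
* **Delay**: a fixed, immediately available 20 EUR option against
  hypothetical rewards of 20.20-260 EUR delayed by 1-60 days; the
  15 x 7 reward-by-delay grid gives 105 unique high-cost offers, each
  appearing once per block over 2 blocks (210 trials).

Each participant completes both tasks under three conditions: placebo
(PLC), a dopamine D2-receptor antagonist (haloperidol, HAL), and a
muscarinic M1-receptor antagonist (biperiden, BIP). The package
provides the full analysis chain for such designs — task generation,
cohort simulation, hierarchical Bayesian model estimation, model
comparison, validation, and regression — exercised end-to-end on
synthetic cohorts.

## The discounting model

The subjective value (SV) of an option is its reward devalued by its
cost. Four single-parameter forms are implemented; the conventional
winners in the two domains are:

* parabolic effort discounting, applied to both options:
  $SV = R - \kappa E^2$;
* hyperbolic delay discounting of the varying option, with the
  immediate option held at face value:
  $SV = R / (1 + e^{\kappa} D)$.

For the delay task the discount rate is parameterized as
$e^{\kappa}$ — i.e. $\kappa$ lives in log space — because raw delay
discounting rates are skewed towards zero across subjects. For
uniformity, *all four* delay forms use the $e^{\kappa}$ rate, so the
additive drug-shift machinery below applies identically whichever form
is selected. The linear and exponential forms use their standard
textbook definitions.

Drug effects enter as additive shifts on the placebo parameters:

$$\kappa = \kappa_{PLC} + I_{HAL}\, s\kappa_{HAL} + I_{BIP}\, s\kappa_{BIP},$$

and likewise for the softmax inverse temperature $\beta$. Choices are
Bernoulli draws from the two-option softmax
$P(HC) = \text{logistic}(\beta\,(SV_{HC} - SV_{LC}))$, computed in the
overflow-safe logistic form. A positive $s\kappa$ means the drug
steepens discounting; a positive $s\beta$ means more deterministic
choices.

### Effort units

Published group-level estimates near $\kappa \approx 0.1$ are only
dimensionally consistent with the 2-16 reward range if effort enters
the parabolic model on a compressed scale. `cbdm` therefore codes
effort in *deciles of MVC* by default (0, 2, 4, 6, 8 for 0-80%): at
the maximum effort of 8 coded units, $\kappa = 0.102$ removes
$0.102 \times 64 \approx 6.5$ apples — a discount commensurate with
the reward range. The coding is configurable (`percent`, `fraction`,
`level`) via `effort_code()`; simulation and fitting always share one
coding, so parameter recovery is coding-invariant.

### Numerical guards

* Condition-resolved $\beta$ is floored at $10^{-6}$ (with a validity
  flag): the additive shift model does not itself prevent a large
  negative shift from crossing zero.
* Choice probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$
  before logs, so likelihoods are always finite.
* The effort-hyperbolic denominator $1 + \kappa E$ is floored at
  $10^{-3}$, so negative $\kappa$ values explored during sampling
  cannot flip its sign.

## Synthetic cohorts

Trial-level data from such pharmacological studies are generally not
publicly deposited, so the package ships a first-class generator.
Its defaults define the reference study conditions: 62 subjects, three
within-subject conditions, both tasks, with population means set to
the published group-level posterior means of the winning models
(effort: $\kappa = 0.102$, $\beta = 0.667$, shifts
$s\kappa_{HAL} = 0.013$, $s\kappa_{BIP} = -0.012$,
$s\beta_{HAL} = -0.089$, $s\beta_{BIP} = 0.127$; delay:
$\kappa = -4.621$, $\beta = 0.356$, $s\kappa_{HAL} = -0.630$,
$s\kappa_{BIP} = -0.125$, $s\beta_{HAL} = -0.055$,
$s\beta_{BIP} = -0.043$). Those means are *estimates from one study*,
used as a realistic operating point, not ground truth.

Between-subject SDs are not published anywhere, so they are the
package's own choices, fixed once: effort $\kappa$ 0.05 and $\beta$
0.25, delay log-$\kappa$ 1.0 and $\beta$ 0.15 — spreads typical of
healthy-adult discounting cohorts — and each shift SD equal to half
its mean magnitude (mild, subject-specific drug sensitivity).
Parameters are drawn as independent normals; no covariance structure
is modelled because none is reported for this class of task.

What the generator deliberately does **not** emulate: fatigue drift
across trials, session-order effects, decision times, lapses or
attention failures, and any mood or physiological covariates. Passing
tests on synthetic cohorts therefore demonstrate that the estimation
machinery is correct and well calibrated *under the model's own
assumptions* — they cannot certify how real participants deviate from
those assumptions.

```{r}
library(cbdm)
study <- simulate_study(seed = 1)    # 62 subjects, both tasks
head(study$effort$trials)
```

## Hierarchical estimation

`fit_hierarchical()` estimates all six parameters per subject with
separate group-level mean/SD distributions, by MCMC in JAGS. Two
implementation choices matter:

* **Binomial cell aggregation.** Identical option pairs within a
  subject-condition are collapsed to binomial counts. The Bernoulli
  likelihood factorizes over trials, so this is exact, and roughly
  halves the effort-task graph (the delay task collapses its two
  blocks).
* **Hybrid parameterization.** Subject-level $\kappa$ and $\beta$ are
  centered on their group distributions (they are strongly identified
  by the placebo data, and centering keeps the hyperparameter updates
  conjugate). The four drug shifts use the non-centered
  parameterization ($s = \mu + \sigma z$, $z \sim N(0,1)$): their
  heterogeneity is small, and the centered form funnels badly under
  Gibbs sampling — in side-by-side runs the shift-group means mixed an
  order of magnitude faster non-centered, while $\kappa/\beta$ mixed
  best centered.

Priors (configurable through `prior_spec()`) are weakly informative
and anchored to each parameter's scale: group means
$N(0.05, 0.1)$ for effort $\kappa$, $N(-4, 2)$ for delay log-$\kappa$,
$N(0.5, 0.5)$ for $\beta$, $N(0, 0.5)$ for all shifts; every group SD
is half-normal with scale equal to half the corresponding mean-prior
scale.

Sampler presets (`fit_settings()`):

| preset | chains | adaptation | burn-in | retained draws |
|--------|--------|-----------|---------|----------------|
| `full` | 4 | 1000 | 2000 | 4000 |
| `standard` | 4 | 300 | 500 | 1600 |
| `fast` | 2 | 150 | 200 | 300 |

`full` mirrors the published estimation procedure (4 chains, 3,000
warmup iterations, 4,000 retained). `standard` is the profile used
for convergence reporting on 20-subject synthetic cohorts, and `fast`
is the documented reduced profile for tests and repeated recovery
experiments; with the aggregated, hybrid-parameterized model the
group-level split r-hat on standard synthetic fits sits at or below
the conventional 1.01 threshold already at the `standard` size.
Convergence is always computed (split-chain r-hat per group
parameter, `hdi()` for intervals) and a fit is flagged, not rejected,
when `max rhat > 1.01`. One master seed fans out deterministically to
per-chain RNG seeds, so fits reproduce exactly.

When only placebo data are supplied — the convention for form
comparison — the shift parameters are dropped and the model reduces to
two parameters per subject.

## Model comparison

`compare_forms()` fits each candidate form to the placebo subset and
ranks them by trial-based LOOIC. The pointwise log-likelihood is
evaluated in R from the retained subject-level draws; PSIS smoothing
(generalized Pareto fit to the importance-ratio tail by the
Zhang-Stephens profile posterior, expected-order-statistic
replacement, truncation at the raw maximum) is implemented in the
package and verified in the tests against an analytic conjugate
Beta-Bernoulli leave-one-out oracle. Pareto-k diagnostics are
reported per trial; "trial-based" means pointwise per trial, not per
subject.

## Validation and recovery

`posterior_predictive_datasets()` simulates 500 datasets per subject
from the subject-level posterior and selects 10 per subject for
refitting, mirroring the standard validation procedure;
`recover_group()` checks that refit group-level means fall inside the
reference fit's 95% HDIs, and `recover_subjects()` correlates
reference subject-level posterior means with refit means averaged
across the selected datasets (per-dataset correlations are retained
as an attribute). Recovery is judged against the reference
*posterior* by default — the procedure a study without ground truth
can run — and against the simulation ground truth in the package's own
calibration tests, which is the stronger check.

`bayesian_correlation()` (bivariate-normal MCMC with a uniform prior
on $r$, on standardized inputs) serves the across-task question:
whether subjects who discount effort steeply also discount delay
steeply. Inputs are the per-subject posterior-mean placebo $\kappa$
values from the two tasks.

## Choice regression

`build_design()` + `fit_glmm()` implement the model-agnostic
complement: a hierarchical Bernoulli-logit regression of high-cost
choice on drug (two indicators, placebo reference), reward, cost, and
all interactions, with a subject-level random slope for every fixed
effect. Following the common effect-size-friendly convention,
non-binary predictors are centered and scaled to SD 0.5 (binary drug
indicators are left unscaled); interactions are formed *after*
scaling the mains, and the effort task uses high-minus-low difference
terms while the delay task uses the absolute levels of the varying
option. Optional `trial_number` and `session` covariates (each with
drug interactions) reproduce the fatigue/order control analyses as a
strict superset of the core design.

Priors are $N(0, 2.5)$ on fixed effects and half-normal(1) on
random-effect SDs. Random-effect *correlations* are not modelled:
JAGS has no LKJ prior, and with independent SDs the random slopes can
be centered on the fixed effects, which keeps the fixed-effect
conditionals conjugate and the Gibbs sampler fast. This sacrifices
slope-correlation estimates, which are not an inferential target
here. An effect is called credible when its 95% HDI excludes zero.

## Problem sizes used in the shipped checks

The package's own acceptance checks run, per task, a 20-subject
cohort at the full trial counts (the scaled-down analogue of the
62-subject study): a reference fit, ten posterior-predictive refits
(single-chain fast profile — only posterior means are consumed), and
subject-level recovery correlations, requiring r > 0.8 for $\kappa$
and $\beta$; plus a `standard`-preset convergence fit, 20-replicate
coverage calibration on reduced 2-block effort designs, 10-replicate
form-identification runs at 6 subjects, and directional/null
calibration of the GLMM. These sizes were chosen as the smallest at
which the statistical properties are stable; all are configurable
upward.

## Known limitations

* The JAGS backend samples by adaptive Gibbs/slice updates, not
  Hamiltonian Monte Carlo; equivalent posteriors need more iterations
  than an HMC implementation, which the presets reflect.
* The generator's between-subject SDs are assumptions (see above);
  absolute coverage statements depend on them only weakly, but effect
  sizes in simulated drug contrasts scale with the shift means.
* Single-parameter discounting forms only: no two-parameter
  (magnitude-sensitive) discounting, no lapse mixtures, no
  decision-time modelling.
* `rhat()` requires at least two chains and errors on one — by
  design, single-chain refits report `NA` diagnostics rather than a
  false reassurance.
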