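# cbdm — cost–benefit decision modelling under drug manipulation

`cbdm` is an R package for analysing binary cost–benefit choices from
within-subject pharmacological crossover studies, and for simulating
such studies when trial-level data are unavailable. It targets the
two classic cost domains: **effort discounting** (grip-force for
"apples") and **delay discounting** (money now versus more money
later), each measured under placebo, a dopamine D2 antagonist
(haloperidol) and a muscarinic M1 antagonist (biperiden).

## The model

On each trial the subjective value (SV) of an option is its reward
devalued by its cost. The package implements four single-parameter
discounting forms (linear, parabolic, hyperbolic, exponential); the
conventional winners are

- effort (parabolic, both options): SV = R − κE²
- delay (hyperbolic, varying option only; κ in log space):
  SV = R / (1 + e^κ D)

Drug conditions shift the placebo parameters additively
(κ = κ_PLC + I_HAL·sκ_HAL + I_BIP·sκ_BIP, and likewise β), and
choices follow a softmax with inverse temperature β:
P(high-cost) = logistic(β(SV_HC − SV_LC)). All six parameters
(κ, β and four shifts) are estimated per subject under separate
group-level mean/SD distributions by MCMC (JAGS), with split-chain
r-hat diagnostics, 95% highest-density intervals, PSIS-LOO model
comparison, posterior-predictive validation and parameter recovery,
a hierarchical Bayesian logistic regression of choice on drug ×
reward × cost, and a Bayesian across-task correlation of κ.

See `vignettes/cbdm-methods.Rmd` for the full account of the model,
priors, sampler parameterization and design decisions.

## Worked example

```r
library(cbdm)

# simulate a small effort-task cohort from the default population
co <- simulate_cohort(group_truth("effort", n_subjects = 6), seed = 2)
nrow(co$trials)
#> [1] 2250                      # 6 subjects x 3 conditions x 125 trials

fit <- fit_hierarchical(co$trials, form = "parabolic",
                        settings = fit_settings("fast", seed = 2))
summarize_fit(fit)
#>     parameter    mean     sd    lower  upper rhat p_gt_0
#> 1       kappa  0.0613 0.0197  0.01829 0.0958 1.03 0.9967
#> 2        beta  0.4753 0.0775  0.32540 0.6273 1.06 1.0000
#> 3 s_kappa_hal  0.0159 0.0124 -0.00791 0.0409 1.10 0.9100
#> 4 s_kappa_bip -0.0230 0.0218 -0.06523 0.0195 1.02 0.1433
#> 5  s_beta_hal -0.0926 0.0729 -0.20579 0.0474 1.17 0.0717
#> 6  s_beta_bip  0.1072 0.0713 -0.02097 0.2657 1.07 0.9383
```

Each row is a group-level posterior: the population mean of the
discounting rate `kappa` and inverse temperature `beta` under
placebo, and the four drug shifts (`s_kappa_hal` > 0 would mean
haloperidol steepens effort discounting). `lower`/`upper` bound the
95% HDI; a shift whose HDI excludes zero is a credible drug effect;
`p_gt_0` is the posterior sign probability. (Output from a 6-subject
fast-preset fit — intervals are wide and r-hat is rough at this size;
use the `standard` or `full` preset for reporting.)

Downstream stages follow the same pattern:

```r
compare_forms(co$trials)                    # LOOIC ranking, placebo data
pp  <- posterior_predictive_datasets(fit, co$trials, 500, 10, seed = 3)
ref <- lapply(pp, fit_hierarchical, form = "parabolic",
              settings = fit_settings("fast"))
recover_subjects(ref, fit)                  # per-parameter Pearson r
eff <- fit_glmm(build_design(co$trials, regression_spec("effort")))
credible_effects(eff)                       # drug x reward x cost terms
run_pipeline(run_config(seed = 1, n_subjects = 8, tasks = "effort"))
```

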