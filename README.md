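# sessm

Fitting the Simon-effect sequential sampling model (SE-SSM) and relating
its parameters and within-trial dynamics to BOLD activity.

## The problem

In a Simon task, subjects respond to a stimulus feature (color) while its
irrelevant spatial position primes the competing response. Conflict trials
are slower, less accurate, and — tellingly — show a *reduced* RT spread.
A standard drift-diffusion model cannot produce this pattern. The SE-SSM
extends it with two conflict-specific parameters:

* `x_b` — an automatic starting-point bias. The decision variable starts at
  `x0 = x_b (1 − 2c)`: toward the correct bound (`+x_th`) without conflict,
  toward the error bound with conflict (`c = 1`). It produces the slowing
  and the fast errors.
* `b` — conflict counteraction. The per-step update is
  `Δx = v (1 + c·b·d) Δt + s ξ₁ √Δt` with `d` the elapsed decision time,
  so on conflict trials the effective drift ramps up within the trial.
  It rescues slow trials and compresses the conflict RT distribution.

Observed RT adds an effective non-decision time `t_eff = t + ξ₂ s_t`
(uniform jitter of range `s_t`). The per-subject parameters are
`v, x_th, t, s_t, b, x_b`, with the diffusion scale `s = 1` fixed.

The package is for researchers who want to (i) fit this model — or its
nested variants — to choice/RT data by maximum likelihood, (ii) compare the
variants with AIC weights, and (iii) carry the model into fMRI analysis,
either through across-subject correlations between fitted parameters and
GLM maps (with TFCE + max-statistic permutation FWER correction) or through
response-locked expected-decision-variable regressors ("DV-GLM").

Because the SE-SSM's first-passage densities have no closed form, the
likelihood engine propagates a discretized decision-variable distribution
through Gaussian transition kernels with absorbing bounds (time-varying
under conflict), accumulating defective correct/error densities.

## Worked example

One synthetic subject with known parameters, fitted and compared across
the nested family M1 (basic), M2 (+`b`), M3 (+`x_b`), M4 (full):

```r
library(sessm)

truth <- se_params(v = 3, x_th = 0.6, t = 0.3, s_t = 0.1, b = 2.5, x_b = 0.15)
set.seed(1)
trials <- rbind(simulate_trials(truth, 0, 500),
                simulate_trials(truth, 1, 500))

behavioral_summary(trials)$by_condition
#>   condition   n   mean_rt      sd_rt accuracy
#> 1         0 500 0.4596838 0.12000625    0.998
#> 2         1 500 0.4864345 0.08939051    0.984

row <- compare_subject(trials, fit_config(n_restarts = 2, rng_seed = 7))
print(row)
#> Model comparison (winner: M4 )
#>   model      aic waic
#> 1    M1 -1728.24    0
#> 2    M2 -1731.66    0
#> 3    M3 -1796.56    0
#> 4    M4 -1841.78    1
print(row$fits$M4$params)
#> SE-SSM parameters
#>   v = 3.267  x_th = 0.6821  t = 0.2896  s_t = 0.09597
#>   b = 2.416  x_b = 0.1398  s = 1 (fixed in fitting)
```

The conflict condition is ~27 ms slower, less accurate, and has a *smaller*
RT spread — the Simon signature the `b` and `x_b` parameters encode — and
the full model recovers the generating values (true
`v = 3, x_th = 0.6, t = 0.3, s_t = 0.1, b = 2.5, x_b = 0.15`) with the
correct model winning decisively.

Downstream, `dv_pool()` + `expected_dv_traces()` + `extract_windows()`
turn a fitted subject into z-scored pre-response decision-variable
amplitudes, `build_design()`/`fit_glm()` assemble first-level GLMs with a
canonical double-gamma HRF, and `group_maps()` +
`max_stat_permutation()` run the across-subject TFCE permutation test.
`generate_cohort()` materializes a full 21-subject synthetic study
(2 sessions × 48 congruent/48 incongruent/24 null trials of 2.5 s,
TR 2 s, 151 volumes) for end-to-end testing; `read_events()` ingests
BIDS-style events TSVs for real data. Thin command-line front ends live in
`inst/cli/sessm.R`. See the vignette (`vignettes/se-ssm-methods.Rmd`) for
the model, the numerical choices, and the design decisions.

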