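---
title: "Modelling the Simon effect with a sequential sampling model and relating it to BOLD"
author: "sessm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Simon effect with a sequential sampling model and relating it to BOLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sessm)
```

## The model

In a Simon task, a lateralized stimulus signals a left- or right-hand
response through a non-spatial feature (its color). When the stimulus side
conflicts with the required response, subjects are slower and less
accurate, and the spread of conflict response times shrinks relative to
the congruent condition — the behavioral fingerprint the SE-SSM (Simon-effect
sequential sampling model) is built to capture.

The model is an accuracy-coded drift-diffusion accumulator. A decision
variable $x$ starts at

$$x_0 = x_b\,(1 - 2c),$$

where $c \in \{0, 1\}$ flags conflict and $x_b \ge 0$ is the automatic
response bias: toward the correct bound ($+x_{th}$) on congruent trials and
toward the error bound ($-x_{th}$) under conflict. Evidence then evolves in
steps of

$$\Delta x = v\,(1 + c\,b\,d)\,\Delta t + s\,\xi_1\sqrt{\Delta t},$$

with drift $v$, diffusion scale $s$ (fixed at 1, the scaling convention
that makes the remaining parameters identifiable), standard-normal
$\xi_1$, and the within-trial clock $d$ (seconds since accumulation
onset). The gain $b \ge 0$ is the conflict-counteraction term: on conflict
trials the effective drift ramps up linearly in time, which both rescues
accuracy after an adverse start and compresses the conflict RT
distribution — exactly the spread reduction the bias term alone cannot
produce. A response is emitted when $|x| \ge x_{th}$; the observed RT adds
an effective non-decision time

$$t^{\mathrm{eff}} = t + \xi_2\, s_t .$$

The parameters fitted per subject are $v, x_{th}, t, s_t, b, x_b$.

**Choices the equations leave open.** The distribution of $\xi_2$ is only
described as uniform with scale $s_t$; we take $\xi_2 \sim U(-\tfrac12,
\tfrac12)$, so `s_t` is the *range* of the jitter (the standard DDM
convention; the alternative, $U(0,1)$ scaling, would change the meaning of
fitted `s_t` by a factor of two and shift `t` by `s_t/2`). Accuracy coding
orients the upper bound to the correct response, and the bias points
toward correct on non-conflict trials. The clock `d` starts at the onset
of accumulation, not at stimulus onset: non-decision time is outside the
accumulation process.

## Likelihood by transition-matrix propagation

The SE-SSM has no closed-form first-passage density (the time-varying
drift on conflict trials breaks the standard series solutions), so
likelihoods are computed numerically. The decision variable is discretized
on a uniform grid of spacing `dx` spanning $\pm(x_{th} +
5\,s\sqrt{\Delta t})$ — wide enough that a single Gaussian step
essentially never leaves the grid. States at or beyond $\pm x_{th}$ are
absorbing: their transition-matrix columns are zero apart from a unit
diagonal. Interior states receive a Gaussian kernel with mean shift
$v(1 + c\,b\,d)\Delta t$ and standard deviation $s\sqrt{\Delta t}$,
renormalized over the grid so interior probability is conserved until it
is absorbed. The initial vector puts unit mass on the grid point nearest
$x_0$. Iterating the (fixed, or under conflict time-varying) matrix and
accumulating the mass absorbed above and below the bounds yields the
defective CDFs of correct and error responses; numerical differentiation
gives the defective densities, which are then shifted by `t` and convolved
with the uniform `s_t` kernel to reach the observed-RT domain.

Numerical choices, with reasons:

* `dt = 0.001` s keeps the one-step kernel several grid cells wide at both
  working resolutions (`dx = 0.01` coarse, `0.005` refinement), so the
  discrete kernel is well resolved.
* A grid spanning anything *less* than the bounds could not host the
  absorbing states that sit outside them, so the grid extends *beyond*
  $\pm x_{th}$ by the pad.
* Propagation stops early once interior mass falls below $10^{-9}$; the
  defective CDFs are flat afterwards. A leak above $10^{-3}$ at the
  horizon (`t_max`, default 5 s) warns that the horizon is too short.
* The log-likelihood floors densities at $10^{-10}$ so a stray RT cannot
  produce an infinite objective; RTs outside the representable support
  contribute the floor and a warning.
* Discrete-time boundary crossing (both here and in the trace simulator)
  slightly overestimates the absorption threshold — the classic
  $0.58\,s\sqrt{\Delta t}$ outward shift of discretely monitored barriers.
  Engine and simulator share the convention, so fitting simulated data is
  internally consistent; against the *continuous-time* closed form the
  absorption split is accurate to a few $10^{-3}$ at the default step and
  to better than $5\times10^{-3}$ at `dt = 1e-4`, which is what the
  engine-accuracy checks use.

## Fitting and model comparison

Per subject, the negative log-likelihood is minimized by a projected
generalized pattern search of the Hooke--Jeeves family: opportunistic
coordinate polling with step halving, plus pattern (extrapolation) moves
along the last successful displacement — without them the search stalls
on the curved $v$--$x_{th}$ ridge that near-ceiling-accuracy data
produce. It runs inside box bounds wide enough to enclose the
initialization distributions ($v \sim G(3,1)$, $x_{th} \sim G(0.6,0.15)$, $t \sim
G(0.3,0.075)$, $b \sim HN(2.5)$, $x_b \sim G(0.1,0.06)$, $s_t \sim
U(0,0.15)$; Gamma distributions are moment-matched from mean and sd). Two
constraints are joint and enforced by projection during the search:
$s_t \le 2t - 0.01$ (the effective non-decision time must stay positive)
and $x_b \le 0.95\,x_{th}$ (the start must stay inside the bounds). The
search runs `n_restarts` times from fresh random draws at `dx = 0.01`,
then refines the best solution once at `dx = 0.005` with reduced initial
steps. Both correct and error trials enter the likelihood; only the BOLD
analyses later restrict to correct trials.

The candidate family is nested: M1 (basic model, $b = x_b = 0$), M2 (adds
$b$), M3 (adds $x_b$), M4 (both). `compare_subject()` chains warm starts
along the nesting (M2/M3 also start from M1's optimum, M4 from M2's and
M3's), which guarantees the nesting inequality
$\mathrm{NLL}(M4) \le \min(\mathrm{NLL}(M2), \mathrm{NLL}(M3)) \le
\mathrm{NLL}(M1)$ up to the optimizer tolerance — a property independent
restarts alone cannot provide. Model evidence is summarized by AIC
($2k + 2\,\mathrm{NLL}$) and Akaike weights (softmax of
$-\Delta\mathrm{AIC}/2$, computed shift-invariantly); ties break toward
the simpler model.

## The expected decision variable and BOLD regressors

To relate within-trial dynamics to BOLD, the fitted model is simulated at
the trace level (Euler–Maruyama, crossing recorded at the first
suprathreshold sample). For each real trial, simulated trials with the
same choice and an RT within a 25 ms bin centered on the observed RT are
selected, aligned at their threshold crossing, and averaged backwards in
time wherever at least half of the matched traces have samples (the
50% rule avoids early-time artifacts carried only by the longest traces).
Trials with fewer than 10 matches are excluded rather than matched more
loosely, keeping the estimator's definition uniform. Window averages of
width 50 ms are taken stepping back from the response (centers -25, -75,
... ms), z-scored per window across trials (population sd), and missing
windows are imputed at 0 — the post-z-score mean — so every window's
regressor has the same event count. The default pool size is $7.5\times10^5$ traces; the package's tests use
$2$–$4\times10^4$, which keeps window amplitudes stable to well under
0.05 sd (doubling the pool moves them by less).

One genuinely open point is what the pre-response expected DV *means*:
computing the estimator on data simulated from known parameters shows that
its -25 ms window amplitude increases with RT rank (slow trials linger
near the bound; fast trials cross steeply, and their window also spans
more of the early rise). The estimator is therefore strongly
RT-informative, but the sign of that relationship is a property of the
response-locked conditioning, not a free choice.

In the GLM layer, stimulus events are 1 s boxcars, DV events are 100 ms
boxcars centered on their extraction time (onset $+\,$RT$\,+$ center $-$
50 ms), and all event regressors are convolved with a canonical
double-gamma hemodynamic response (peak 6 s, undershoot 16 s, ratio 1/6,
SPM-flavored parameters; other canonical variants of the kernel differ
only marginally) at 0.1 s microtime resolution, then sampled at the
volume times (TR 2 s, volume 0 at $t = 0$). High-pass filtering (0.01 Hz)
enters as discrete-cosine drift columns rather than pre-filtering the
data; motion confounds may be appended, never convolved. Correct-trial
events in the DV-GLM are given the 1 s stimulus duration, matching the
stimulus-event convention. Fitting is OLS with contrast t
statistics mapped to z through matched tail probabilities; session-level
combination is fixed-effects (inverse-variance), and the across-subject
level is a one-sample t-test with clusters reported at $|z| > 2.5$
(26-connectivity) — deliberately simpler than a full mixed-effects
neuroimaging stack, whose preprocessing and random-field corrections are
out of scope here.

## Across-subject inference

The across-subject test asks where a per-subject scalar (a fitted
parameter, mean RT, or the congruency RT difference) correlates with
first-level GLM weights. Per voxel inside the mask, Pearson correlation is
Fisher z-transformed ($|r|$ capped at $1-10^{-12}$), the signed map is
TFCE-enhanced ($E = 0.5$, $H = 2$, 26-connectivity, threshold step
$\max|z|/100$ as a midpoint Riemann sum — the midpoint rule is within
a fraction of a percent of the analytic $\sqrt{n}\,h^3/3$ on flat
clusters, where edge-aligned steps are off by 1.5%), and voxelwise
family-wise-error-corrected p-values come from the permutation
distribution of the image-wide maximum $|TFCE|$ under covariate
shuffling: $p = (1 + \#\{\text{null max} \ge \text{obs}\})/(1 + n_{perm})$,
the add-one form guaranteeing $p > 0$. When $n!$ does not exceed the
requested permutation count the test enumerates all permutations exactly.
The two-tailed map splits by the observed sign into positive- and
negative-tail maps with the complementary voxels set to 1. Permuting the
covariate rather than the maps is equivalent under exchangeability and
cheaper.

## What the synthetic data emulate — and what they do not

`generate_cohort()` reproduces the behavioral skeleton of the two-session
Simon-task dataset the package targets: 21 subjects, 2 sessions, and per
session 48 congruent + 48 incongruent + 24 null trials of 2.5 s on a
regular onset grid (TR 2 s, 151 volumes), with null-trial positions
uniformly random — the original randomization scheme is not documented.
Subject parameters are drawn once per subject from the fitting
initialization distributions, which makes cohort-level Simon signatures
(positive congruency RT effect, reduced conflict RT spread given $b > 0$,
fast errors concentrated in the lowest conflict RT-percentile bin)
emergent properties rather than assertions. Synthetic BOLD uses white
noise only: first-level inference is calibrated against the matched
generator, not against scanner noise with its autocorrelation, drift, and
motion structure. One consequence worth flagging: in the generator, a
subject's congruency RT difference derives *only* from the model
parameters plus sampling noise, so it correlates substantially with the
counteraction gain (r of about -0.4 across subjects). Real across-subject
RT differences carry many conflict-irrelevant sources of variance, which
is precisely why parameter-linked activation can be invisible to an RT
covariate in real data while remaining partially detectable in these
synthetic cohorts. Passing tests therefore demonstrate the correctness of
the estimators and the internal consistency of the pipeline — not
robustness to real-data artifacts, registration error, or physiological
confounds, all of which are assumed handled upstream.

Problem sizes used by the test-suite and acceptance script (engine checks
at $5\times10^4$–$10^5$ simulated trials; recovery at 2000
trials/condition with 2 restarts; model recovery across replicate
datasets at 1 restart plus warm-start chaining; permutation calibration
at 199 permutations over 100–200 null cohorts; DV pools of
$3\times10^4$) were chosen as the smallest sizes at which the Monte-Carlo
error is comfortably below each check's tolerance.

## Known limitations

* No within-step bridge correction in the trace simulator; engine and
  simulator share the discrete-crossing convention instead.
* The response-conditional estimator aligns windows at the observed
  response time, absorbing the motor part of the non-decision time into
  the alignment; a delta-function automatic-pathway onset is implied.
* No hierarchical (subject-pooling) estimation; each subject is fitted
  independently.
* No stimulus/response-laterality coding: the accuracy-coded form is
  mathematically equivalent for the data structure handled here but
  cannot expose lateralized activation patterns.
* Cluster reporting at $|z| > 2.5$ carries no cluster-level error
  control; the permutation-TFCE path is the inferential route.

## A worked micro-example

```{r example, eval = FALSE}
# one synthetic subject, coarse fit, model comparison
cohort <- generate_cohort(cohort_spec(n_subjects = 1, seed = 1))
sub <- cohort$subjects[[1]]
row <- compare_subject(sub$dataset, fit_config(n_restarts = 2, rng_seed = 1))
print(row)
print(sub$params)   # generating truth for comparison
```
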