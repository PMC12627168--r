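---
title: "Methods: the EZ Bayesian hierarchical drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the EZ Bayesian hierarchical drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezbhddm)
```

## The model

Two-choice response-time data are described by the three-parameter drift
diffusion model: evidence accumulates as a Wiener process with drift
$\nu$ (evidence per second) between absorbing boundaries a distance
$\alpha$ apart, starting midway between them, with diffusion coefficient
fixed at 1; the response time adds a nondecision time $\tau$ (seconds)
for encoding and motor execution. Under these assumptions the accuracy
rate and the mean and variance of the correct response times have closed
forms. With $q = e^{-\alpha\nu}$:

$$R = \frac{1}{q+1},\qquad
  M = \tau + \frac{\alpha}{2\nu}\cdot\frac{1-q}{1+q},\qquad
  V = \frac{\alpha}{2\nu^3}\cdot\frac{1 - 2\alpha\nu q - q^2}{(q+1)^2}.$$

This forward system is algebraically invertible
(`ez_forward()` / `ez_inverse()`); the inverse is the classical EZ
estimator of $(\nu, \alpha, \tau)$ from $(R^{ob}, M^{ob}, V^{ob})$. Note
that the drift estimator involves a *fourth* root,

$$\hat\nu = \operatorname{sgn}\!\left(R^{ob}-\tfrac12\right)
  \left[\frac{L\!\left({R^{ob}}^2 L - R^{ob} L + R^{ob} -
  \tfrac12\right)}{V^{ob}}\right]^{1/4},
  \qquad L = \operatorname{logit}(R^{ob}),$$

which is what makes `ez_inverse(ez_forward(...))` an exact round trip
(verified to $10^{-8}$ over a broad parameter grid in the test suite).

Instead of evaluating the Wiener first-passage-time density, the package
scores per-cell *summary statistics* against their sampling
distributions — a proxy likelihood in the spirit of indirect inference.
For a cell with $N$ trials, $T^{ob}$ of them correct:

* $T^{ob} \sim \mathrm{Binomial}(R, N)$,
* $M^{ob} \sim \mathrm{Normal}(M,\; V/N)$,
* $V^{ob} \sim \mathrm{Gamma}\!\big(\tfrac{N-1}{2},\;
  \mathrm{scale} = \tfrac{2V}{N-1}\big)$, the exact law for the sample
  variance of normal observations, or its large-sample normal
  approximation $\mathrm{Normal}(V,\; 2V^2/(N-1))$.

The normal approximation is the default (`likelihood_config()`); the
gamma law is retained as `"gamma_exact"` because it is exact for normal
samples and nearly indistinguishable at large $N$ (the suite checks
agreement to $10^{-2}$ nats at $N = 10^4$).

Two deliberate approximations are worth naming. First, the mean law
uses $V/N$ with $N$ the *total* trial count even though $M^{ob}$ is
computed from correct trials only; under the unbiased diffusion the
correct and error RT distributions coincide, and this matches the
formulation the proxy model is built from. Second, the RT moments use
correct trials only by default (`correct_only = TRUE`), with the
all-trials variant available.

### The maximum-likelihood identity

The inverse EZ estimates maximize the per-cell proxy likelihood — but
exactly only in the large-$N$ limit. At finite $N$ the
$-\tfrac12\log V(\theta)$ terms of the mean and variance laws displace
the maximizer by $O(1/N)$, and the raw gradient at the inverse estimates
is $O(1)$ regardless of $N$ (it is the curvature that grows with $N$).
The suite therefore checks the identity where its content lives: at
$N = 10^5$ the numerically maximized likelihood agrees with the closed
form to $10^{-4}$ per coordinate, and the Newton step $H^{-1}g$ (the
displacement of the maximizer, the natural 1/N-scaled stationarity
measure) is below $10^{-4}$.

## Hierarchical structure and priors

Individual parameters are draws from normal parents,
$\nu_p \sim \mathrm{N}(\mu_\nu + \beta x_p, \sigma_\nu^2)$ when drift is
the *criterion* parameter (and analogously for boundary or nondecision
time), $\alpha_p \sim \mathrm{N}(\mu_\alpha, \sigma_\alpha^2)$,
$\tau_p \sim \mathrm{N}(\mu_\tau, \sigma_\tau^2)$. Exactly one parameter
carries the metaregression weight $\beta$; the covariate $x$ is binary
(t-test designs) or in $[0,1]$ (regression design). In the
within-subjects design each participant contributes one summary cell
per condition, with an independent criterion draw per cell and shared
values of the other two parameters — the minimal structure consistent
with per-condition shifts.

Parents are left untruncated at the individual level; the two places
where positivity matters are handled in deliberately different ways.
The *simulator* rejection-resamples boundary draws below 0.01 and
nondecision times below 0 (counted and reported), because a generative
model must produce valid diffusion parameters. The *likelihood* instead
returns a $-\infty$ sentinel for any proposal with a non-positive
boundary, so the sampler simply rejects such moves.

Default priors (`prior_spec()`) are weakly informative over the ranges
typical for unit-diffusion-coefficient analyses of two-choice tasks:
$\mu_\nu \sim \mathrm{N}(0, 2^2)$;
$\mu_\alpha \sim \mathrm{N}(1.5, 1)$ truncated to $(0.1, 5)$;
$\mu_\tau \sim \mathrm{N}(0.3, 0.25^2)$ truncated to $(0, 1)$ seconds;
$\sigma_\nu, \sigma_\alpha, \sigma_\tau \sim \mathrm{U}(0.01, 3)$; and
$\beta \sim \mathrm{N}(0, 1)$, kept untruncated-normal so its density at
zero is analytic for the Savage–Dickey ratio. All components are
replaceable.

## The simulator

`simulate_trials()` integrates the diffusion by Euler–Maruyama with step
mean $\nu\,dt$ and step SD $\sqrt{dt}$ (default $dt = 10^{-4}$ s),
absorbing at the boundaries. Plain discrete monitoring overshoots:
crossings between grid points are missed, biasing absorption times and
accuracy by $O(\sqrt{dt})$ — measurably so, since each barrier behaves
as if displaced outward by $0.5826\sqrt{dt}$. The simulator therefore
applies the standard continuity correction, pulling each barrier inward
by $0.5826\sqrt{dt}$ (`boundary_correction = TRUE`), which removes the
leading-order bias; the residual is $O(dt)$. At $dt = 10^{-4}$ and
$(\nu, \alpha, \tau) = (1, 1, 0.3)$, $10^5$ simulated trials match the
closed-form accuracy, mean and variance within three Monte-Carlo
standard errors plus a small documented residual allowance (20% of one
overshoot length propagated through the forward system) — this is an
acceptance check. Set `boundary_correction = FALSE` for the uncorrected
walk. The rare trial unabsorbed at the 20 s horizon is resolved by the
sign of its current position and triggers a warning.

`simulate_hierarchical()` composes parent draws, per-cell trial
simulation, and summary computation, returning both the summaries and
the generating individual parameters for recovery scoring. A cell with
fewer than two correct trials cannot provide an RT variance and is
re-simulated (counted); at the default study conditions this is
vanishingly rare.

### Generator defaults

The generator's defaults describe a typical two-choice experiment:
$\mu_\nu = 1$, $\sigma_\nu = 0.5$ (clear but imperfect discrimination,
accuracy mostly 0.75–0.95 at the default boundary),
$\mu_\alpha = 1.5$, $\sigma_\alpha = 0.2$ (moderate caution),
$\mu_\tau = 0.4$ s, $\sigma_\tau = 0.06$ s (typical encoding-plus-motor
times), $\beta = 0$ unless a study sets it. Regression covariates are
evenly spaced on $[0,1]$ (a fixed design matrix across replicates);
t-test designs use a balanced 0/1 split.

## Sampling

The posterior over population parameters and all individual parameters
is explored by Metropolis-within-Gibbs with Gaussian random-walk
proposals, target acceptance 0.44 per scalar block, and
stochastic-approximation adaptation of the proposal SDs during warmup
only (frozen afterwards, preserving detailed balance). Population SDs
are sampled on the log scale with the Jacobian correction. Individual
parameters are conditionally independent across participants given the
population, so `fit_ezbhddm()` carries out their scalar updates as
vectorized blocks — one likelihood evaluation per block per sweep —
while `run_mcmc()` exposes the same algorithm for arbitrary closures
(used for the conjugate-target validation in the suite). Chains are
initialized from the edge-corrected inverse EZ estimates
(`init_from_ez()`), with prior medians as the fallback for degenerate
(e.g. chance-level) cells, and are bit-reproducible given a seed.

Convergence is monitored by split R-hat and autocorrelation-based
effective sample size for every parameter; fits flag any parameter with
R-hat above 1.05. Defaults are 4 chains, 2000 warmup, 5000 draws
(`sampler_config()`); the recovery harnesses default to a desk-scale 2
chains × (500 + 1000), which keeps a full replicate
(simulate + fit, $P = T = 80$) around three seconds while holding
R-hat < 1.05 for essentially all parameters.

## The study harnesses

`run_recovery_cell()` repeats simulate–fit cycles at one scenario
(criterion × design × $P$ × $T$ × $\beta$), recording per replicate the
posterior mean and central 95% credible interval of $\beta$ and the
population means; aggregates report bias, empirical SD and CI coverage.
Replicate seeds derive deterministically from (base seed, cell hash,
replicate index); sampler failures are recorded rows, never silent
drops. `run_grid()` crosses factors and caches finished cells by a
content hash so interrupted grids resume. Desk-scale defaults use
reps in the tens to low hundreds per cell; the full
150-condition × 1000-replicate program is expressible but is
cluster-scale work.

`savage_dickey()` estimates the posterior density of $\beta$ at zero
from the pooled draws by a Gaussian kernel density (Sheather–Jones
bandwidth, default bandwidth as fallback) and reports
$BF_{01} = p(\beta = 0 \mid y)/p(\beta = 0)$ together with a
moment-matched normal-approximation variant, flagging disagreement
beyond 10%. When the posterior places no mass near zero the kernel
estimate underflows; the moment-matched normal density then stands in
(tagged `moment_normal_fallback` in the result), so the Bayes factor
stays finite while still reporting an overwhelming magnitude.

## Numerical choices

* **Zero-drift singularity.** The mean and variance equations are
  $0/0$ at $\nu = 0$; for $|\alpha\nu| < 10^{-6}$ the analytic limits
  $M = \tau + \alpha^2/4$, $V = \alpha^4/24$ are used, with a series
  branch for $|\alpha\nu| < 10^{-3}$ where the closed-form numerator
  loses precision to cancellation. Continuity at the switch is tested.
* **Edge cells.** The logit diverges for cells with 0% or 100%
  accuracy; `edge_correct()` substitutes $1/(2N)$ and $1 - 1/(2N)$
  (configurable). A cell at exactly 50% leaves drift sign and boundary
  unidentified and is a hard error for `ez_inverse()`; inside the
  sampler such cells simply fall back to prior-median initials.
* **Variance denominator.** $V^{ob}$ uses the unbiased $N_c - 1$
  denominator, matching the $(N-1)$ in the gamma law.
* **Invalid proposals.** The likelihood returns $-\infty$ rather than
  raising, so Metropolis steps reject cleanly.

## What the tests do and do not show

The synthetic generator emulates a hierarchical three-parameter
diffusion: normal parents, one covariate, unbiased start, no
trial-to-trial parameter variability, no contaminant or outlier RTs,
stationary parameters across the session. Real datasets violate several
of these (response bias, fast guesses, fatigue); passing recovery tests
therefore demonstrates the estimator's behavior *under its own
generative assumptions* plus exact-simulator data, not robustness to
misspecification. Outlier screening is left to the user as a documented
pre-filter step before `summarize_trials()`.

## Known limitations

* Parameter recovery inherits the character of EZ estimation: the
  regression weight $\beta$ is the well-recovered quantity, while
  population means of boundary and nondecision time absorb small-sample
  distortions. In this implementation the per-cell nondecision-time
  estimates on diffusion data are systematically *high* at small trial
  counts — a fourth-root Jensen effect: the sampling variability of
  $V^{ob}$ on skewed, heavy-tailed diffusion RTs exceeds the proxy's
  normal-theory gamma law, inflating $\hat\nu$ and deflating the
  implied decision time. Consequently the hierarchical $\mu_\tau$
  posterior mean tends to sit *above* truth here (the acceptance script
  reports the measured direction as `mu_ndt_fraction_below_truth` /
  `mu_ndt_mean_bias`); accounts that report underestimation of
  $\mu_\tau$ rest on different (unpublished) prior settings. Either
  way the bias is systematic, and the covariate effect remains
  well estimated — which is the intended use.
* The proxy's mean law understates the sampling variance of $M^{ob}$
  by the factor $N_c/N$; at typical accuracies this is modest and is
  absorbed into the interval calibration checked by the coverage tests.
* The sampler is random-walk based: adequate for these
  low-dimensional-per-block targets, but not a gradient method; very
  large $P$ would benefit from something sharper.
* Out of scope by design: the seven-parameter diffusion with
  across-trial variabilities, response bias / biased starting points,
  multi-criterion regression, and latent-variable structures across
  parameters.
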