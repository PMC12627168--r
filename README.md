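# ezbhddm

Hierarchical Bayesian estimation of the drift diffusion model from
summary statistics — for cognitive psychometrics, where the question is
rarely "what is this participant's drift rate?" and usually "does this
covariate move drift rate (or caution, or nondecision time)?"

## The idea

The three-parameter drift diffusion model describes two-choice response
times as a Wiener process with drift ν drifting between absorbing
boundaries α apart (start at α/2, unit diffusion coefficient), plus a
nondecision time τ. Its first-passage-time likelihood is expensive;
hierarchical extensions multiply that cost.

This package replaces the trial-level likelihood with a *proxy
likelihood* over three per-cell summary statistics. With
q = exp(−αν), the model implies

    R = 1/(q+1)
    M = τ + (α/2ν) · (1−q)/(1+q)
    V = (α/2ν³) · (1 − 2ανq − q²)/(q+1)²

for the accuracy rate and the mean and variance of correct response
times, and the sampling distributions of their observed counterparts
are elementary:

    T_ob ~ Binomial(R, N)
    M_ob ~ Normal(M, V/N)
    V_ob ~ Gamma((N−1)/2, scale 2V/(N−1))   [≈ Normal(V, 2V²/(N−1))]

Those three lines *are* the likelihood. Around it the package provides
the closed-form forward/inverse EZ system, normal population
distributions for individual parameters with a metaregression weight β
linking one parameter (drift, boundary, or nondecision time) to an
external covariate, weakly informative priors, an adaptive
Metropolis-within-Gibbs sampler with split R-hat/ESS diagnostics, a
Savage–Dickey Bayes factor for β = 0, a continuity-corrected Euler
diffusion simulator for ground-truth data, and recovery-study
harnesses. Because only summary statistics are needed, the model also
fits cells taken straight from published tables (`read_summaries()`).

## Worked example

Simulate a study in which individual drift rates depend linearly on a
covariate x ∈ [0,1] with weight β = 0.5 (80 participants, 80 trials
each), then recover the weight and test it:

```r
library(ezbhddm)

design <- design_spec(P = 80, T_trials = 80, "regression", "drift")
sim <- simulate_hierarchical(design, population_params(beta = 0.5),
                             seed = 11)

fit <- fit_ezbhddm(sim$stats, criterion = "drift",
                   cfg = sampler_config(chains = 2, warmup = 500,
                                        draws = 1000, seed = 42))
print(fit)
#> EZ Bayesian hierarchical DDM fit
#>   criterion: drift | cells: 80 | chains: 2 x 1000 draws
#>   beta: mean 0.765, 95% CI [0.296, 1.145]
#>   split R-hat: max 1.044 (100% of parameters < 1.05)

summary(fit)[1:7, c("parameter", "mean", "sd")]
#>   parameter       mean          sd
#> 1  mu_drift 0.83070044 0.121923216
#> 2  sd_drift 0.46576895 0.042694479
#> 3  mu_bound 1.46455574 0.025535484
#> 4  sd_bound 0.21191919 0.018763310
#> 5    mu_ndt 0.42500090 0.007853131
#> 6    sd_ndt 0.05098922 0.007326547
#> 7      beta 0.76514923 0.211093750

savage_dickey(fit)
#> Savage-Dickey BF10 = 60.43 (BF01 = 0.01655), gaussian_kde_sj on 2000 draws
#>   note: normal-approximation BF01 = 0.006646 differs by >10%
```

The generating population had mean drift 1, boundary separation 1.5,
nondecision time 0.4 s and β = 0.5: the population means are recovered
closely, the weight's 95% interval covers the truth, and the Bayes
factor correctly reports strong evidence for a nonzero weight. (The
single-dataset β estimate scatters around the truth with SD ≈ 0.18 at
this design size; the recovery harness shows the estimator is unbiased
across replicates.)

Study-level harnesses:

```r
cell <- run_recovery_cell("drift", "regression", P = 80, T_trials = 80,
                          beta_true = 0.5, reps = 100, base_seed = 1)
cell$summary   # bias, empirical SD, 95% CI coverage across replicates
grid <- run_grid(P_values = c(40, 80), T_values = c(40, 80), reps = 50)
plot_recovery(grid)   # estimate-vs-truth panels (needs ggplot2)
```

A thin command-line interface covers the same workflows
(`inst/cli/ezbhddm simulate | summarize | fit | recover | bf`), reading
YAML/JSON configs and writing CSV/JSON outputs with a provenance
record.

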