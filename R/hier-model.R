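#' Default prior specification for the population parameters
#'
#' Weakly informative priors spanning the empirically plausible ranges of
#' diffusion parameters under the unit-diffusion-coefficient scaling:
#' \itemize{
#'   \item `mu_drift` ~ Normal(0, 2^2)
#'   \item `mu_bound` ~ Normal(1.5, 1^2) truncated to (0.1, 5)
#'   \item `mu_ndt`   ~ Normal(0.3, 0.25^2) truncated to (0, 1)
#'   \item `sd_drift`, `sd_bound`, `sd_ndt` ~ Uniform(0.01, 3)
#'   \item `beta`     ~ Normal(0, 1)
#' }
#' The regression-weight prior is kept analytic (untruncated normal) so
#' its density at zero is available exactly for Savage-Dickey Bayes
#' factors.  Every component is replaceable: pass a modified copy to the
#' fitting functions.
#'
#' @return A named list of class `ezbhddm_priors`; each element is a list
#'   with a `family` (`"normal"`, `"truncnorm"` or `"uniform"`) and its
#'   hyperparameters.
#' @export
prior_spec <- function() {
  structure(list(
    mu_drift = list(family = "normal", mean = 0, sd = 2),
    sd_drift = list(family = "uniform", min = 0.01, max = 3),
    mu_bound = list(family = "truncnorm", mean = 1.5, sd = 1,
                    lower = 0.1, upper = 5),
    sd_bound = list(family = "uniform", min = 0.01, max = 3),
    mu_ndt = list(family = "truncnorm", mean = 0.3, sd = 0.25,
                  lower = 0, upper = 1),
    sd_ndt = list(family = "uniform", min = 0.01, max = 3),
    beta = list(family = "normal", mean = 0, sd = 1)
  ), class = "ezbhddm_priors")
}

# Log density of one prior component at `value`; -Inf outside support.
prior_logdens <- function(spec, value) {
  if (!is.list(spec) || is.null(spec$family)) stop("malformed prior spec")
  switch(spec$family,
    normal = dnorm(value, spec$mean, spec$sd, log = TRUE),
    truncnorm = {
      if (value < spec$lower || value > spec$upper) return(-Inf)
      z <- pnorm(spec$upper, spec$mean, spec$sd) -
        pnorm(spec$lower, spec$mean, spec$sd)
      dnorm(value, spec$mean, spec$sd, log = TRUE) - log(z)
    },
    uniform = {
      if (value < spec$min || value > spec$max) return(-Inf)
      -log(spec$max - spec$min)
    },
    stop("unknown prior family: ", spec$family)
  )
}

# Median of one prior component (used as a degenerate-cell fallback).
prior_median <- function(spec) {
  switch(spec$family,
    normal = spec$mean,
    truncnorm = {
      lo <- pnorm(spec$lower, spec$mean, spec$sd)
      hi <- pnorm(spec$upper, spec$mean, spec$sd)
      qnorm((lo + hi) / 2, spec$mean, spec$sd)
    },
    uniform = (spec$min + spec$max) / 2
  )
}

#' Log prior density of the population parameters
#'
#' @param pop Named list or [population_params()] object with `mu_drift`,
#'   `sd_drift`, `mu_bound`, `sd_bound`, `mu_ndt`, `sd_ndt`, `beta`.
#' @param priors A [prior_spec()] (possibly modified).
#' @return Sum of component log densities; `-Inf` outside any component's
#'   support.
#' @export
log_prior <- function(pop, priors = prior_spec()) {
  lp <- 0
  for (nm in names(priors)) {
    if (is.null(pop[[nm]])) stop("pop is missing component: ", nm)
    lp <- lp + prior_logdens(priors[[nm]], pop[[nm]])
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Group-level log density of individual parameters
#'
#' Scores individual diffusion parameters against their normal parent
#' distributions.  The criterion parameter's mean is shifted by
#' `beta * x` per cell; the other two parameters are scored once per
#' participant against unshifted parents.
#'
#' @param indiv Data frame with one row per cell: `participant` and the
#'   columns `drift`, `boundary`, `ndt`.  In within-subject designs the
#'   criterion column varies across a participant's cells while the other
#'   two repeat; non-criterion parameters are counted once per
#'   participant.
#' @param pop Population parameters (named list).
#' @param x Covariate, one value per cell (row of `indiv`).
#' @param criterion Which parameter carries the regression weight.
#' @return The group-level log density; `-Inf` if any population SD is
#'   non-positive.
#' @export
log_group <- function(indiv, pop, x,
                      criterion = c("drift", "boundary", "ndt")) {
  criterion <- match.arg(criterion)
  if (length(x) != nrow(indiv)) stop("covariate length must match cells")
  sds <- c(drift = pop$sd_drift, boundary = pop$sd_bound,
           ndt = pop$sd_ndt)
  mus <- c(drift = pop$mu_drift, boundary = pop$mu_bound,
           ndt = pop$mu_ndt)
  if (any(sds <= 0)) return(-Inf)
  first <- !duplicated(indiv$participant)
  lg <- 0
  for (pname in c("drift", "boundary", "ndt")) {
    if (pname == criterion) {
      lg <- lg + sum(dnorm(indiv[[pname]], mus[[pname]] + pop$beta * x,
                           sds[[pname]], log = TRUE))
    } else {
      lg <- lg + sum(dnorm(indiv[[pname]][first], mus[[pname]],
                           sds[[pname]], log = TRUE))
    }
  }
  if (!is.finite(lg)) -Inf else lg
}

#' Joint log posterior of the hierarchical model
#'
#' The single target density the sampler explores: prior on population
#' parameters, plus the group-level density of individual parameters,
#' plus the proxy likelihood of the observed summaries.
#'
#' @inheritParams log_group
#' @param stats Per-cell summary statistics aligned with `indiv`.
#' @param priors A [prior_spec()].
#' @param lik A [likelihood_config()].
#' @return Log posterior density (up to a constant); `-Inf` outside the
#'   support (e.g. any individual boundary separation non-positive).
#' @export
log_posterior <- function(pop, indiv, stats, x, priors = prior_spec(),
                          criterion = c("drift", "boundary", "ndt"),
                          lik = likelihood_config()) {
  criterion <- match.arg(criterion)
  lp <- log_prior(pop, priors)
  if (!is.finite(lp)) return(-Inf)
  lg <- log_group(indiv, pop, x, criterion)
  if (!is.finite(lg)) return(-Inf)
  ll <- loglik_dataset(indiv, stats, lik)
  if (!is.finite(ll)) return(-Inf)
  lp + lg + ll
}
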