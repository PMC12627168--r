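default_pop <- function(...) {
  modifyList(list(mu_drift = 1, sd_drift = 0.5, mu_bound = 1.5,
                  sd_bound = 0.2, mu_ndt = 0.4, sd_ndt = 0.06,
                  beta = 0), list(...))
}

test_that("prior components evaluate their stated densities", {
  pr <- prior_spec()
  # standard-normal regression-weight prior at zero
  expect_equal(ezbhddm:::prior_logdens(pr$beta, 0), log(1 / sqrt(2 * pi)))
  # uniform components are flat inside their support
  expect_equal(ezbhddm:::prior_logdens(pr$sd_drift, 0.5),
               ezbhddm:::prior_logdens(pr$sd_drift, 2.5))
  # truncated components renormalize over the truncation window
  z <- pnorm(5, 1.5, 1) - pnorm(0.1, 1.5, 1)
  expect_equal(ezbhddm:::prior_logdens(pr$mu_bound, 1.5),
               dnorm(1.5, 1.5, 1, log = TRUE) - log(z))
})

test_that("the joint prior returns the sentinel outside any support", {
  pr <- prior_spec()
  expect_true(is.finite(log_prior(default_pop(), pr)))
  expect_identical(log_prior(default_pop(sd_drift = 5), pr), -Inf)
  expect_identical(log_prior(default_pop(mu_ndt = 1.2), pr), -Inf)
  expect_identical(log_prior(default_pop(mu_bound = 0.05), pr), -Inf)
  # flat components contribute no difference inside support
  expect_equal(log_prior(default_pop(sd_ndt = 0.5), pr),
               log_prior(default_pop(sd_ndt = 1.5), pr))
})

test_that("group density drops the covariate when beta is zero", {
  set.seed(5)
  indiv <- data.frame(participant = 1:20,
                      drift = rnorm(20, 1, 0.5),
                      boundary = rnorm(20, 1.5, 0.2),
                      ndt = rnorm(20, 0.4, 0.05))
  x <- rep(c(0, 1), 10)
  pop <- default_pop()
  expect_equal(log_group(indiv, pop, x, "drift"),
               log_group(indiv, pop, sample(x), "drift"))
})

test_that("group density attains its maximum at the parent means", {
  pop <- default_pop()
  at_means <- data.frame(participant = 1:5, drift = pop$mu_drift,
                         boundary = pop$mu_bound, ndt = pop$mu_ndt)
  x <- rep(0, 5)
  base <- log_group(at_means, pop, x, "drift")
  expect_equal(base,
               5 * sum(dnorm(0, 0, c(0.5, 0.2, 0.06), log = TRUE)))
  off <- at_means
  off$drift <- off$drift + 0.3
  expect_lt(log_group(off, pop, x, "drift"), base)
})

test_that("a location shift on the criterion is absorbed by beta", {
  set.seed(6)
  indiv <- data.frame(participant = 1:30,
                      drift = rnorm(30, 1, 0.5),
                      boundary = rnorm(30, 1.5, 0.2),
                      ndt = rnorm(30, 0.4, 0.05))
  x <- rep(c(0, 1), 15)
  with_beta <- default_pop(beta = 0.4)
  shifted <- indiv
  shifted$boundary <- shifted$boundary + 0.4 * x
  expect_equal(log_group(shifted, default_pop(beta = 0.4), x, "boundary"),
               log_group(indiv, default_pop(beta = 0), x, "boundary"))
})

test_that("the log posterior is the sum of its three components", {
  set.seed(7)
  sim <- simulate_hierarchical(design_spec(6, 20, "regression", "drift"),
                               population_params(), seed = 7, dt = 2e-3)
  indiv <- sim$truth[c("participant", "drift", "boundary", "ndt")]
  pop <- default_pop()
  x <- sim$stats$x
  lp <- log_posterior(pop, indiv, sim$stats, x, criterion = "drift")
  expect_equal(lp,
               log_prior(pop) + log_group(indiv, pop, x, "drift") +
                 loglik_dataset(indiv, sim$stats))
  # sentinel propagation: an invalid individual boundary
  bad <- indiv
  bad$boundary[2] <- -0.5
  expect_identical(
    log_posterior(pop, bad, sim$stats, x, criterion = "drift"), -Inf)
  # moving one cell's stats onto its own predictions improves the fit
  better <- sim$stats
  f <- ez_forward(indiv$drift[1], indiv$boundary[1], indiv$ndt[1])
  better$n_correct[1] <- round(better$N[1] * f$pred_acc)
  better$mean_rt[1] <- f$pred_mean
  better$var_rt[1] <- f$pred_var
  expect_gte(log_posterior(pop, indiv, better, x, criterion = "drift"), lp)
})

test_that("prior-predictive draws give finite posteriors", {
  # population from the priors, individuals from floored parent draws,
  # summaries from the proxy's own sampling laws
  set.seed(8)
  pr <- prior_spec()
  n_bad <- 0
  for (r in 1:200) {
    pop <- list(mu_drift = rnorm(1, 0, 2),
                sd_drift = runif(1, 0.01, 3),
                mu_bound = 0, sd_bound = runif(1, 0.01, 3),
                mu_ndt = 0, sd_ndt = runif(1, 0.01, 3),
                beta = rnorm(1))
    repeat {
      pop$mu_bound <- rnorm(1, 1.5, 1)
      if (pop$mu_bound > 0.1 && pop$mu_bound < 5) break
    }
    repeat {
      pop$mu_ndt <- rnorm(1, 0.3, 0.25)
      if (pop$mu_ndt > 0 && pop$mu_ndt < 1) break
    }
    P <- 5
    x <- runif(P)
    drift <- rnorm(P, pop$mu_drift + pop$beta * x, pop$sd_drift)
    boundary <- ndt <- numeric(P)
    for (p in 1:P) {
      repeat {
        boundary[p] <- rnorm(1, pop$mu_bound, pop$sd_bound)
        if (boundary[p] >= 0.01) break
      }
      repeat {
        ndt[p] <- rnorm(1, pop$mu_ndt, pop$sd_ndt)
        if (ndt[p] >= 0) break
      }
    }
    f <- ez_forward(drift, boundary, ndt)
    N <- 30L
    stats <- data.frame(
      participant = 1:P,
      N = N,
      n_correct = rbinom(P, N, f$pred_acc),
      mean_rt = rnorm(P, f$pred_mean, sqrt(f$pred_var / N)),
      var_rt = rgamma(P, shape = (N - 1) / 2,
                      scale = 2 * f$pred_var / (N - 1))
    )
    indiv <- data.frame(participant = 1:P, drift = drift,
                        boundary = boundary, ndt = ndt)
    lp <- log_posterior(pop, indiv, stats, x, pr, "drift")
    if (!is.finite(lp)) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})
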