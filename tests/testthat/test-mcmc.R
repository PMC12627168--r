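test_that("a constant target is accepted at every step", {
  post <- run_mcmc(function(th) 0, c(0, 0),
                   sampler_config(chains = 2, warmup = 50, draws = 200,
                                  seed = 1))
  expect_true(all(post$accept == 1))
})

test_that("the sampler recovers standard-normal moments", {
  post <- run_mcmc(function(th) dnorm(th, log = TRUE), 0,
                   sampler_config(chains = 4, warmup = 1000, draws = 5000,
                                  seed = 2), par_names = "z")
  z <- posterior_draws(post, "z")
  ess <- post$diagnostics$ess
  expect_lt(abs(mean(z)), 3 * sd(z) / sqrt(ess))
  expect_lt(abs(sd(z) - 1), 0.05)
  expect_lt(post$diagnostics$rhat, 1.02)
})

test_that("runs are bit-reproducible under identical configuration", {
  cfg <- sampler_config(chains = 2, warmup = 100, draws = 200, seed = 33)
  a <- run_mcmc(function(th) dnorm(th, log = TRUE), 0.5, cfg)
  b <- run_mcmc(function(th) dnorm(th, log = TRUE), 0.5, cfg)
  expect_identical(a$draws, b$draws)
})

test_that("the sampler refuses a non-finite starting point", {
  expect_error(run_mcmc(function(th) -Inf, 0, tiny_cfg()), "finite")
})

test_that("split R-hat is near 1 for well-mixed chains and flags drifts", {
  set.seed(4)
  good <- array(rnorm(2000 * 4), dim = c(2000, 4, 1),
                dimnames = list(NULL, NULL, "p"))
  expect_lt(split_rhat(good), 1.01)
  # chains centered 10 SD apart must be flagged
  offs <- good
  offs[, 3, 1] <- offs[, 3, 1] + 10
  expect_gt(split_rhat(offs), 1.1)
  post <- ezbhddm:::make_posterior(offs, matrix(1, 4, 1),
                                   sampler_config(chains = 4, draws = 2000,
                                                  warmup = 0))
  expect_warning(d <- diagnostics(post), "R-hat")
  expect_true(d$flagged)
})

test_that("independent draws have effective size close to nominal", {
  set.seed(5)
  iid <- array(rnorm(2000 * 4), dim = c(2000, 4, 1),
               dimnames = list(NULL, NULL, "p"))
  ess <- ess_draws(iid)
  expect_gt(ess, 0.8 * 8000)
  expect_lt(ess, 1.2 * 8000)
  # strongly autocorrelated draws have far smaller effective size
  ar <- array(0, dim = c(2000, 2, 1), dimnames = list(NULL, NULL, "p"))
  for (ch in 1:2) {
    z <- numeric(2000)
    for (i in 2:2000) z[i] <- 0.95 * z[i - 1] + rnorm(1)
    ar[, ch, 1] <- z
  }
  expect_lt(ess_draws(ar), 0.2 * 4000)
})

test_that("diagnostics require at least two chains", {
  one <- array(rnorm(500), dim = c(500, 1, 1),
               dimnames = list(NULL, NULL, "p"))
  post <- ezbhddm:::make_posterior(one, matrix(1, 1, 1),
                                   sampler_config(chains = 1, draws = 500,
                                                  warmup = 0))
  expect_error(diagnostics(post), "2 chains")
})

test_that("EZ initialization inverts noise-free summaries exactly", {
  truth <- data.frame(drift = c(0.8, 1.4, -0.6),
                      boundary = c(1.2, 1.8, 1.0),
                      ndt = c(0.25, 0.4, 0.3))
  f <- ez_forward(truth$drift, truth$boundary, truth$ndt)
  N <- 1e6L
  stats <- data.frame(participant = 1:3, N = N,
                      n_correct = round(N * f$pred_acc),
                      mean_rt = f$pred_mean, var_rt = f$pred_var)
  init <- init_from_ez(stats)
  expect_equal(init$indiv$drift, truth$drift, tolerance = 1e-3)
  expect_equal(init$indiv$boundary, truth$boundary, tolerance = 1e-3)
  expect_equal(init$indiv$ndt, truth$ndt, tolerance = 1e-3)
  expect_equal(init$pop$beta, 0)
})

test_that("chance-level cells fall back to prior medians", {
  stats <- data.frame(participant = 1:2, N = 40L,
                      n_correct = c(20L, 30L),
                      mean_rt = c(0.5, 0.52), var_rt = c(0.03, 0.031))
  init <- init_from_ez(stats)
  pr <- prior_spec()
  expect_equal(init$indiv$drift[1], 0)
  expect_equal(init$indiv$boundary[1],
               ezbhddm:::prior_median(pr$mu_bound))
  # the non-degenerate cell still gets its EZ estimate
  expect_gt(init$indiv$drift[2], 0)
})

test_that("the hierarchical fit runs, converges and is reproducible", {
  sim <- simulate_hierarchical(design_spec(8, 40, "regression", "drift"),
                               population_params(beta = 0.5), seed = 21,
                               dt = 1e-3)
  fit <- fit_ezbhddm(sim$stats, "drift", cfg = tiny_cfg(seed = 9))
  expect_s3_class(fit, "ezbhddm_fit")
  expect_equal(dim(fit$draws)[3], 7 + 3 * 8)
  expect_true(all(is.finite(fit$draws)))
  expect_false(any(is.na(fit$diagnostics$rhat)))
  expect_false(any(is.na(fit$diagnostics$ess)))
  sm <- summary(fit)
  expect_true(all(c("mean", "sd", "rhat", "ess") %in% names(sm)))
  # posterior mass in a sane region
  pm <- setNames(sm$mean, sm$parameter)
  expect_gt(pm[["mu_bound"]], 0.8)
  expect_lt(pm[["mu_bound"]], 2.5)
  expect_gt(pm[["mu_ndt"]], 0.2)
  expect_lt(pm[["mu_ndt"]], 0.6)

  fit2 <- fit_ezbhddm(sim$stats, "drift", cfg = tiny_cfg(seed = 9))
  expect_identical(fit$draws, fit2$draws)
})

test_that("the fit validates its inputs", {
  sim <- simulate_hierarchical(design_spec(4, 20, "regression", "drift"),
                               population_params(), seed = 22, dt = 2e-3)
  s <- sim$stats
  expect_error(fit_ezbhddm(s[setdiff(names(s), "x")], "drift"),
               "covariate")
  s_bad <- s
  s_bad$var_rt[1] <- 0
  expect_error(fit_ezbhddm(s_bad, "drift"), "var_rt")
  s_bad <- s
  s_bad$n_correct[1] <- 99L
  expect_error(fit_ezbhddm(s_bad, "drift"), "0..N")
})
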