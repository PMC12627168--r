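test_that("the likelihood decomposes into its three sampling laws", {
  # parameters chosen so the predicted accuracy is exactly 0.7
  p <- list(drift = qlogis(0.7), boundary = 1,
            ndt = 0.3)
  f <- ez_forward(p$drift, p$boundary, p$ndt)
  s <- data.frame(N = 10L, n_correct = 7L, mean_rt = f$pred_mean,
                  var_rt = f$pred_var * 1.1)
  ll <- loglik_cell(p, s, components = TRUE)
  comp <- attr(ll, "components")
  expect_equal(sum(comp), as.numeric(ll))
  # binomial term equals the exact pmf: C(10,7) 0.7^7 0.3^3 = 0.266828
  expect_equal(comp[["binomial"]], log(0.26682793), tolerance = 1e-7)
  # a mean observed exactly at its prediction attains the normal maximum
  expect_equal(comp[["mean"]],
               -0.5 * log(2 * pi * f$pred_var / s$N))
})

test_that("gamma and normal variance laws agree at large N", {
  f <- ez_forward(1, 1, 0.3)
  N <- 1e4L
  for (shift in c(0, -1, 1)) {
    v_ob <- f$pred_var * (1 + shift * sqrt(2 / (N - 1)))
    s <- data.frame(N = N, n_correct = as.integer(round(N * f$pred_acc)),
                    mean_rt = f$pred_mean, var_rt = v_ob)
    ln <- loglik_cell(ddm_params(1, 1, 0.3), s,
                      likelihood_config("normal_approx"))
    lg <- loglik_cell(ddm_params(1, 1, 0.3), s,
                      likelihood_config("gamma_exact"))
    expect_lt(abs(ln - lg), 1e-2)
  }
})

test_that("invalid proposals get the rejection sentinel, not an error", {
  s <- data.frame(N = 50L, n_correct = 40L, mean_rt = 0.5, var_rt = 0.03)
  expect_identical(
    ezbhddm:::loglik_cells(1, -1, 0.3, s$N, s$n_correct, s$mean_rt,
                           s$var_rt),
    -Inf)
  expect_identical(
    ezbhddm:::loglik_cells(NaN, 1, 0.3, s$N, s$n_correct, s$mean_rt,
                           s$var_rt),
    -Inf)
})

test_that("dataset likelihood is additive, exchangeable and aligned", {
  set.seed(31)
  stats <- random_interior_stats(4, N = 200)
  stats$participant <- 1:4
  params <- cbind(participant = 1:4,
                  ez_inverse(edge_correct(stats$n_correct, stats$N),
                             stats$mean_rt * 1.02, stats$var_rt))
  single <- loglik_dataset(params[1, ], stats[1, ])
  expect_equal(single, loglik_cell(params[1, ], stats[1, ]))

  full <- loglik_dataset(params, stats)
  perm <- sample(4)
  expect_equal(loglik_dataset(params[perm, ], stats[perm, ]), full)

  dup <- loglik_dataset(params[c(1:4, 2), ], stats[c(1:4, 2), ])
  expect_equal(dup - full, loglik_cell(params[2, ], stats[2, ]))

  expect_error(loglik_dataset(params[1:3, ], stats), "misaligned")
  bad <- params
  bad$participant <- c(1, 2, 4, 3)
  expect_error(loglik_dataset(bad, stats), "misaligned")
})

test_that("closed-form inverse estimates maximize the cell likelihood", {
  # the identity is exact up to O(1/N); tested at N = 1e5 against a
  # general-purpose numerical optimizer started off the solution
  set.seed(77)
  stats <- random_interior_stats(10, N = 1e5)
  for (i in seq_len(nrow(stats))) {
    s <- stats[i, , drop = FALSE]
    closed <- as.numeric(mle_cell(s))
    numeric <- numeric_mle(s)
    expect_lt(max(abs(closed - numeric)), 1e-4)
  }
})

test_that("the inverse estimates are a stationary point at scale 1/N", {
  set.seed(78)
  stats <- random_interior_stats(5, N = 1e5)
  for (i in seq_len(nrow(stats))) {
    s <- stats[i, , drop = FALSE]
    theta <- as.numeric(mle_cell(s))
    gh <- loglik_grad_hess(theta, s)
    newton_step <- solve(gh$hess, gh$grad)
    expect_lt(max(abs(newton_step)), 1e-4)
  }
})

test_that("mle_cell reproduces generating parameters from exact stats", {
  f <- ez_forward(1, 1, 0.3)
  s <- data.frame(N = 1000L, n_correct = 1000L * f$pred_acc,
                  mean_rt = f$pred_mean, var_rt = f$pred_var)
  est <- mle_cell(s, edge_rule = "none")
  expect_equal(as.numeric(est), c(1, 1, 0.3), tolerance = 1e-10)
})

test_that("sample variances of normal RTs follow the gamma law", {
  set.seed(91)
  N <- 50
  f <- ez_forward(1, 1, 0.3)
  vobs <- replicate(4000, var(rnorm(N, f$pred_mean, sqrt(f$pred_var))))
  ks <- suppressWarnings(
    ks.test(vobs, function(q) {
      pgamma(q, shape = (N - 1) / 2, scale = 2 * f$pred_var / (N - 1))
    }))
  expect_gt(ks$p.value, 0.01)
})

test_that("likelihood curvature scales estimator variance as 1/N", {
  # the inverse Fisher information in the drift direction should fall
  # like 1/N: slope about -1 on the log-log scale
  f <- ez_forward(1, 1.5, 0.4)
  info <- vapply(c(50, 200, 800), function(N) {
    s <- data.frame(N = as.integer(N),
                    n_correct = as.integer(round(N * f$pred_acc)),
                    mean_rt = f$pred_mean, var_rt = f$pred_var)
    theta <- as.numeric(mle_cell(s))
    gh <- loglik_grad_hess(theta, s)
    -gh$hess[1, 1]
  }, numeric(1))
  slope <- coef(lm(log(1 / info) ~ log(c(50, 200, 800))))[2]
  expect_lt(abs(slope + 1), 0.15)
})
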