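# Shared helpers for the test suite: tiny sampler settings, synthetic
# summary-statistic cells, and a numerical maximizer used as the
# independent oracle against the closed-form inverse estimators.

tiny_cfg <- function(seed = 1) {
  sampler_config(chains = 2, warmup = 150, draws = 300, seed = seed)
}

# Random interior summary-statistic cells: generated by pushing random
# diffusion parameters through the forward system at large N (so the
# observed accuracy is exactly representable as a count) and nudging the
# moments off their predictions.
random_interior_stats <- function(n_cells, N = 1e5, jitter = 0.02,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- runif(n_cells, 0.4, 2)
  a <- runif(n_cells, 0.8, 2)
  t0 <- runif(n_cells, 0.2, 0.5)
  f <- ez_forward(v, a, t0)
  n_correct <- as.integer(round(N * f$pred_acc))
  data.frame(
    N = as.integer(N),
    n_correct = n_correct,
    mean_rt = f$pred_mean * (1 + runif(n_cells, -jitter, jitter)),
    var_rt = f$pred_var * (1 + runif(n_cells, -jitter, jitter))
  )
}

# Independent oracle: general-purpose numerical maximization of the
# per-cell proxy log-likelihood (Nelder-Mead, polished by a restart).
numeric_mle <- function(stats, cfg = likelihood_config(),
                        start_factor = c(1.05, 0.95, 1.02)) {
  start <- as.numeric(mle_cell(stats)) * start_factor
  nll <- function(th) {
    ll <- loglik_cell(list(drift = th[1], boundary = th[2], ndt = th[3]),
                      stats, cfg)
    if (!is.finite(ll)) 1e12 else -ll
  }
  o <- optim(start, nll, control = list(reltol = 1e-15, maxit = 20000))
  o <- optim(o$par, nll, control = list(reltol = 1e-15, maxit = 20000))
  o$par
}

# Central finite-difference gradient and Hessian of the cell
# log-likelihood in (drift, boundary, ndt).
loglik_grad_hess <- function(theta, stats, cfg = likelihood_config(),
                             h = 1e-5) {
  f <- function(th) {
    loglik_cell(list(drift = th[1], boundary = th[2], ndt = th[3]),
                stats, cfg)
  }
  d <- length(theta)
  g <- numeric(d)
  H <- matrix(0, d, d)
  hs <- h * pmax(abs(theta), 1)
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- hs[i]
    g[i] <- (f(theta + e) - f(theta - e)) / (2 * hs[i])
  }
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- numeric(d); ei[i] <- hs[i]
      ej <- numeric(d); ej[j] <- hs[j]
      H[i, j] <- (f(theta + ei + ej) - f(theta + ei - ej) -
                    f(theta - ei + ej) + f(theta - ei - ej)) /
        (4 * hs[i] * hs[j])
      H[j, i] <- H[i, j]
    }
  }
  list(grad = g, hess = H)
}
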