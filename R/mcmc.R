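#' Configure the MCMC sampler
#'
#' @param chains Number of independent chains (at least 2 for
#'   diagnostics; default 4).
#' @param warmup Adaptation iterations per chain (discarded).
#' @param draws Post-warmup draws per chain (at least 1).
#' @param seed Integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @param target_accept Target acceptance rate for the scalar
#'   random-walk blocks (0.44, standard for one-dimensional walks).
#' @param init_step Initial random-walk proposal SD, adapted during
#'   warmup and frozen afterwards.
#' @return A list of class `ezbhddm_sampler`.
#' @export
sampler_config <- function(chains = 4L, warmup = 2000L, draws = 5000L,
                           seed = 1L, target_accept = 0.44,
                           init_step = 0.1) {
  chains <- as.integer(chains)
  warmup <- as.integer(warmup)
  draws <- as.integer(draws)
  if (chains < 1) stop("chains must be at least 1")
  if (draws < 1) stop("draws must be at least 1")
  if (warmup < 0) stop("warmup must be non-negative")
  if (target_accept <= 0 || target_accept >= 1) {
    stop("target_accept must lie in (0, 1)")
  }
  structure(list(chains = chains, warmup = warmup, draws = draws,
                 seed = as.integer(seed), target_accept = target_accept,
                 init_step = init_step),
            class = "ezbhddm_sampler")
}

# Robbins-Monro step size for proposal-SD adaptation at sweep t.
adapt_gamma <- function(t) min(0.5, 2 / sqrt(t))

#' Generic Metropolis-within-Gibbs sampler
#'
#' Samples from an arbitrary log target density by updating one scalar
#' coordinate at a time with a Gaussian random-walk Metropolis step.
#' Proposal SDs adapt toward `target_accept` during warmup (stochastic
#' approximation on the log scale) and are frozen afterwards, preserving
#' detailed balance in the sampling phase.  Chains are independent given
#' distinct sub-seeds and the run is bit-reproducible under a fixed
#' configuration.
#'
#' This closure-based sampler is intended for low-dimensional targets and
#' validation studies; [fit_ezbhddm()] applies the same update rules to
#' the hierarchical model with vectorized blocked updates.
#'
#' @param log_target Function mapping a numeric parameter vector to a log
#'   density (up to a constant); must be finite at `init`.
#' @param init Numeric vector of initial values (all chains start here).
#' @param cfg A [sampler_config()].
#' @param par_names Optional parameter names.
#' @return An object of class `ezbhddm_post`: draws array
#'   (iterations x chains x parameters), per-parameter split R-hat and
#'   effective sample size, and the per-block acceptance-rate log.
#' @examples
#' post <- run_mcmc(function(th) dnorm(th, log = TRUE), 0,
#'                  sampler_config(chains = 2, warmup = 200, draws = 500))
#' summary(post)
#' @export
run_mcmc <- function(log_target, init, cfg = sampler_config(),
                     par_names = NULL) {
  d <- length(init)
  if (is.null(par_names)) par_names <- paste0("theta[", seq_len(d), "]")
  lp0 <- log_target(init)
  if (!is.finite(lp0)) stop("log target is not finite at the initial values")
  draws <- array(NA_real_, dim = c(cfg$draws, cfg$chains, d),
                 dimnames = list(NULL, NULL, par_names))
  accept <- matrix(0, nrow = cfg$chains, ncol = d,
                   dimnames = list(NULL, par_names))
  for (ch in seq_len(cfg$chains)) {
    set.seed(cfg$seed + 1000L * (ch - 1L))
    state <- init
    lp <- lp0
    ls <- rep(log(cfg$init_step), d)
    acc_count <- numeric(d)
    for (t in seq_len(cfg$warmup + cfg$draws)) {
      in_warmup <- t <= cfg$warmup
      for (j in seq_len(d)) {
        prop <- state
        prop[j] <- state[j] + exp(ls[j]) * rnorm(1)
        lpp <- log_target(prop)
        a <- is.finite(lpp) && log(runif(1)) < (lpp - lp)
        if (a) {
          state <- prop
          lp <- lpp
        }
        if (in_warmup) {
          ls[j] <- ls[j] + adapt_gamma(t) * ((a * 1) - cfg$target_accept)
        } else {
          acc_count[j] <- acc_count[j] + a
        }
      }
      if (!in_warmup) draws[t - cfg$warmup, ch, ] <- state
    }
    accept[ch, ] <- acc_count / cfg$draws
  }
  make_posterior(draws, accept, cfg)
}

# Assemble a posterior object and compute diagnostics.
make_posterior <- function(draws, accept, cfg, extra = list()) {
  diag <- if (dim(draws)[2] >= 2) {
    data.frame(parameter = dimnames(draws)[[3]],
               rhat = split_rhat(draws),
               ess = ess_draws(draws),
               row.names = NULL)
  } else {
    data.frame(parameter = dimnames(draws)[[3]], rhat = NA_real_,
               ess = ess_draws(draws), row.names = NULL)
  }
  structure(c(list(draws = draws, diagnostics = diag, accept = accept,
                   config = cfg), extra),
            class = "ezbhddm_post")
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain drift inflates the statistic as between-chain
#' disagreement does.
#'
#' @param draws Iterations x chains x parameters array (or an
#'   iterations x chains matrix for one parameter).
#' @return Named vector of R-hat values, one per parameter.
#' @export
split_rhat <- function(draws) {
  if (length(dim(draws)) == 2) dim(draws) <- c(dim(draws), 1)
  n <- dim(draws)[1]
  half <- floor(n / 2)
  apply(draws, 3, function(x) {
    splits <- cbind(x[seq_len(half), , drop = FALSE],
                    x[(n - half + 1):n, , drop = FALSE])
    m <- ncol(splits)
    means <- colMeans(splits)
    vars <- apply(splits, 2, var)
    W <- mean(vars)
    B <- half * var(means)
    if (W == 0) return(1)
    vhat <- (half - 1) / half * W + B / half
    sqrt(vhat / W)
  })
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size: per-chain autocovariances
#' (via FFT) are combined across chains, converted to correlations
#' against the cross-chain variance estimate, summed over Geyer's initial
#' monotone sequence of paired lags, and inverted.
#'
#' @inheritParams split_rhat
#' @return Named vector of ESS values, one per parameter.
#' @export
ess_draws <- function(draws) {
  if (length(dim(draws)) == 2) dim(draws) <- c(dim(draws), 1)
  n <- dim(draws)[1]
  m <- dim(draws)[2]
  apply(draws, 3, function(x) {
    acovs <- vapply(seq_len(m), function(ch) autocov_fft(x[, ch]),
                    numeric(n))
    mean_acov <- rowMeans(acovs)
    W <- mean(apply(x, 2, var))
    if (W == 0) return(m * n)
    B_over_n <- if (m > 1) var(colMeans(x)) else 0
    vhat <- (n - 1) / n * W + B_over_n
    rho <- 1 - (W - mean_acov) / vhat
    # Geyer initial monotone sequence over paired lags
    max_pairs <- floor((n - 1) / 2)
    tau <- -1
    prev <- Inf
    for (k in 0:max_pairs) {
      p <- rho[2 * k + 1] + if (2 * k + 2 <= n) rho[2 * k + 2] else 0
      if (k > 0 && p < 0) break
      p <- min(p, prev)
      tau <- tau + 2 * p
      prev <- p
    }
    tau <- max(tau, 1 / (m * n))
    min(m * n / tau, m * n * 10)
  })
}

# Biased (1/n) autocovariance sequence via FFT.
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  nfft <- 2^ceiling(log2(2 * n))
  f <- fft(c(xc, rep(0, nfft - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
  ac / n
}

#' Convergence diagnostics of a posterior object
#'
#' @param post An `ezbhddm_post` (or `ezbhddm_fit`) object with at least
#'   two chains.
#' @param rhat_threshold Parameters with split R-hat above this value are
#'   flagged.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `flagged`.
#' @export
diagnostics <- function(post, rhat_threshold = 1.05) {
  stopifnot(inherits(post, "ezbhddm_post"))
  if (dim(post$draws)[2] < 2) {
    stop("diagnostics require at least 2 chains")
  }
  d <- data.frame(parameter = dimnames(post$draws)[[3]],
                  rhat = split_rhat(post$draws),
                  ess = ess_draws(post$draws), row.names = NULL)
  d$flagged <- d$rhat > rhat_threshold
  if (any(d$flagged)) {
    warning(sum(d$flagged), " parameter(s) with split R-hat > ",
            rhat_threshold)
  }
  d
}

#' Initialize individual and population parameters from inverse EZ
#'
#' Applies the edge-corrected inverse EZ estimators to every cell to get
#' individual initial values; population means and SDs are their sample
#' moments and the regression weight starts at 0.  A degenerate cell (for
#' example chance-level accuracy, where the inverse is undefined) falls
#' back to the prior medians so the run can proceed.
#'
#' @param stats Per-cell summary statistics (`participant`, optional
#'   `condition`, `N`, `n_correct`, `mean_rt`, `var_rt`).
#' @param priors A [prior_spec()] supplying fallback medians.
#' @return List with `indiv` (per-cell data frame of `drift`, `boundary`,
#'   `ndt`) and `pop` (named list of population initial values, SDs
#'   floored at 0.05 and clipped inside the prior support).
#' @export
init_from_ez <- function(stats, priors = prior_spec()) {
  fallback <- c(drift = prior_median(priors$mu_drift),
                boundary = prior_median(priors$mu_bound),
                ndt = prior_median(priors$mu_ndt))
  est <- lapply(seq_len(nrow(stats)), function(i) {
    tryCatch(mle_cell(stats[i, , drop = FALSE]),
             error = function(e) {
               data.frame(drift = fallback[["drift"]],
                          boundary = fallback[["boundary"]],
                          ndt = fallback[["ndt"]])
             })
  })
  indiv <- do.call(rbind, est)
  keep <- intersect(c("participant", "condition"), names(stats))
  indiv <- cbind(stats[keep], indiv)
  rownames(indiv) <- NULL
  clip <- function(v, lo, hi) min(max(v, lo), hi)
  pop <- list(
    mu_drift = mean(indiv$drift),
    sd_drift = clip(max(sd(indiv$drift), 0.05), 0.011, 2.99),
    mu_bound = clip(mean(indiv$boundary), 0.101, 4.99),
    sd_bound = clip(max(sd(indiv$boundary), 0.05), 0.011, 2.99),
    mu_ndt = clip(mean(indiv$ndt), 1e-3, 0.999),
    sd_ndt = clip(max(sd(indiv$ndt), 0.05), 0.011, 2.99),
    beta = 0
  )
  list(indiv = indiv, pop = pop)
}

#' @export
print.ezbhddm_post <- function(x, ...) {
  dm <- dim(x$draws)
  cat("ezbhddm posterior: ", dm[3], " parameter(s), ", dm[2],
      " chain(s) x ", dm[1], " draws\n", sep = "")
  if (!is.null(x$diagnostics)) {
    rh <- x$diagnostics$rhat
    if (all(is.na(rh))) {
      cat("  (single chain: split R-hat unavailable)\n")
    } else {
      cat(sprintf("  split R-hat: max %.3f; min ESS %.0f\n",
                  max(rh, na.rm = TRUE),
                  min(x$diagnostics$ess, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' @export
summary.ezbhddm_post <- function(object, probs = c(0.025, 0.5, 0.975),
                                 ...) {
  flat <- apply(object$draws, 3, identity)  # (iter*chain) x param
  if (is.null(dim(flat))) flat <- matrix(flat, ncol = dim(object$draws)[3])
  qs <- t(apply(flat, 2, quantile, probs = probs))
  out <- data.frame(parameter = dimnames(object$draws)[[3]],
                    mean = colMeans(flat),
                    sd = apply(flat, 2, sd), qs,
                    row.names = NULL, check.names = FALSE)
  if (!is.null(object$diagnostics)) {
    out$rhat <- object$diagnostics$rhat
    out$ess <- object$diagnostics$ess
  }
  out
}

#' Extract posterior draws for selected parameters
#'
#' @param post An `ezbhddm_post` object.
#' @param pars Parameter names; defaults to all.
#' @param pooled If `TRUE` (default) chains are pooled into one matrix
#'   (draws x parameters); otherwise the subsetted array is returned.
#' @return Matrix or array of draws.
#' @export
posterior_draws <- function(post, pars = NULL, pooled = TRUE) {
  stopifnot(inherits(post, "ezbhddm_post"))
  nm <- dimnames(post$draws)[[3]]
  if (is.null(pars)) pars <- nm
  missing <- setdiff(pars, nm)
  if (length(missing) > 0) {
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  }
  sub <- post$draws[, , pars, drop = FALSE]
  if (!pooled) return(sub)
  out <- apply(sub, 3, identity)
  if (is.null(dim(out))) out <- matrix(out, ncol = length(pars))
  colnames(out) <- pars
  out
}
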