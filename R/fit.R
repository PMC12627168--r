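#' Fit the EZ Bayesian hierarchical drift diffusion model
#'
#' Samples the joint posterior of the population parameters (means and
#' SDs of drift rate, boundary separation and nondecision time, plus the
#' metaregression weight `beta` on the criterion parameter) and all
#' individual diffusion parameters, given per-cell summary statistics.
#' The likelihood is the proxy model: binomial for the number of correct
#' trials, normal for the mean RT, and a gamma law (or its normal
#' approximation) for the RT variance, evaluated at the forward EZ
#' predictions.
#'
#' The sampler is Metropolis-within-Gibbs with Gaussian random-walk
#' steps: individual parameters are conditionally independent across
#' participants given the population parameters, so their scalar updates
#' are carried out as vectorized blocks; population-level scalars are
#' updated one at a time (SDs on the log scale with the Jacobian
#' correction).  Proposal SDs adapt toward the target acceptance rate
#' during warmup and are frozen afterwards.  Starting values come from
#' the inverse EZ estimators ([init_from_ez()]).
#'
#' @param stats Per-cell summary statistics: columns `participant`,
#'   optionally `condition`, `N`, `n_correct`, `mean_rt` (> 0), `var_rt`
#'   (> 0), and the covariate (see `x`).  One row per design cell; in a
#'   within-subjects design a participant has one row per condition.
#' @param criterion Which diffusion parameter regresses on the covariate.
#' @param x Covariate, one value per row of `stats`; defaults to
#'   `stats$x`.
#' @param priors A [prior_spec()].
#' @param cfg A [sampler_config()].
#' @param lik A [likelihood_config()].
#' @return An object of class `ezbhddm_fit` (inherits `ezbhddm_post`):
#'   draws array (iterations x chains x parameters) over
#'   `mu_drift`, `sd_drift`, `mu_bound`, `sd_bound`, `mu_ndt`, `sd_ndt`,
#'   `beta` and every individual parameter, plus split R-hat / ESS per
#'   parameter, acceptance rates, the resolved configuration and priors.
#' @examples
#' \donttest{
#' sim <- simulate_hierarchical(
#'   design_spec(8, 40, "regression", "drift"),
#'   population_params(beta = 0.5), seed = 1, dt = 1e-3)
#' fit <- fit_ezbhddm(sim$stats, "drift",
#'                    cfg = sampler_config(chains = 2, warmup = 200,
#'                                         draws = 400))
#' summary(fit)[1:7, ]
#' }
#' @export
fit_ezbhddm <- function(stats, criterion = c("drift", "boundary", "ndt"),
                        x = NULL, priors = prior_spec(),
                        cfg = sampler_config(),
                        lik = likelihood_config()) {
  criterion <- match.arg(criterion)
  req <- c("participant", "N", "n_correct", "mean_rt", "var_rt")
  if (!all(req %in% names(stats))) {
    stop("stats must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(x)) {
    if (!("x" %in% names(stats))) {
      stop("no covariate: supply x or an x column in stats")
    }
    x <- stats$x
  }
  if (length(x) != nrow(stats)) stop("covariate length must match cells")
  if (any(stats$var_rt <= 0)) stop("every cell needs var_rt > 0")
  if (any(stats$mean_rt <= 0)) stop("every cell needs mean_rt > 0")
  if (any(stats$N < lik$min_n)) {
    stop("a cell has fewer than min_n = ", lik$min_n, " trials")
  }
  if (any(stats$n_correct < 0 | stats$n_correct > stats$N)) {
    stop("n_correct must lie in 0..N")
  }

  part <- factor(stats$participant, levels = unique(stats$participant))
  pidx <- as.integer(part)
  P <- nlevels(part)
  n_cells <- nrow(stats)
  between <- n_cells == P
  N <- stats$N
  n_correct <- stats$n_correct
  mean_rt <- stats$mean_rt
  var_rt <- stats$var_rt
  vlaw <- lik$variance_law

  others <- setdiff(c("drift", "boundary", "ndt"), criterion)
  short <- c(drift = "drift", boundary = "bound", ndt = "ndt")
  mu_name <- function(p) paste0("mu_", short[[p]])
  sd_name <- function(p) paste0("sd_", short[[p]])

  # initial values from inverse EZ (prior-median fallback per cell)
  init <- init_from_ez(stats, priors)
  crit0 <- init$indiv[[criterion]]
  oth0 <- lapply(others, function(p) {
    vals <- init$indiv[[p]]
    as.numeric(tapply(vals, pidx, mean))
  })
  names(oth0) <- others
  # positivity repair for boundary inits
  if ("boundary" %in% others) oth0$boundary <- pmax(oth0$boundary, 0.05)
  if (criterion == "boundary") crit0 <- pmax(crit0, 0.05)

  cell_par <- function(critv, othv) {
    out <- list()
    out[[criterion]] <- critv
    for (p in others) out[[p]] <- othv[[p]][pidx]
    out
  }
  ll_of <- function(critv, othv) {
    cp <- cell_par(critv, othv)
    loglik_cells(cp$drift, cp$boundary, cp$ndt, N, n_correct, mean_rt,
                 var_rt, vlaw)
  }

  # repair any cell where the EZ start has no likelihood support
  cur <- ll_of(crit0, oth0)
  if (any(!is.finite(cur))) {
    fb <- c(drift = prior_median(priors$mu_drift),
            boundary = prior_median(priors$mu_bound),
            ndt = prior_median(priors$mu_ndt))
    bad_cells <- which(!is.finite(cur))
    crit0[bad_cells] <- fb[[criterion]]
    for (p in others) oth0[[p]][unique(pidx[bad_cells])] <- fb[[p]]
    cur <- ll_of(crit0, oth0)
    if (any(!is.finite(cur))) {
      stop("no finite initialization found for cell(s) ",
           paste(head(which(!is.finite(cur)), 5), collapse = ", "))
    }
  }

  pop0 <- init$pop
  # parameter names, in recording order
  pop_names <- c("mu_drift", "sd_drift", "mu_bound", "sd_bound",
                 "mu_ndt", "sd_ndt", "beta")
  indiv_names <- unlist(lapply(c("drift", "boundary", "ndt"), function(p) {
    if (p == criterion && !between) {
      paste0(short[[p]], "[", stats$participant, ",", stats$condition, "]")
    } else if (p == criterion) {
      paste0(short[[p]], "[", stats$participant, "]")
    } else {
      paste0(short[[p]], "[", levels(part), "]")
    }
  }))
  par_names <- c(pop_names, indiv_names)
  n_par <- length(par_names)

  draws <- array(NA_real_, dim = c(cfg$draws, cfg$chains, n_par),
                 dimnames = list(NULL, NULL, par_names))
  block_names <- c("crit", paste0("oth_", others), pop_names)
  accept <- matrix(0, nrow = cfg$chains, ncol = length(block_names),
                   dimnames = list(NULL, block_names))

  ta <- cfg$target_accept
  n_sweeps <- cfg$warmup + cfg$draws

  for (ch in seq_len(cfg$chains)) {
    set.seed(cfg$seed + 1000L * (ch - 1L))
    critv <- crit0
    othv <- oth0
    mu <- c(drift = pop0$mu_drift, boundary = pop0$mu_bound,
            ndt = pop0$mu_ndt)
    lsd <- log(c(drift = pop0$sd_drift, boundary = pop0$sd_bound,
                 ndt = pop0$sd_ndt))
    beta <- pop0$beta
    cur_ll <- ll_of(critv, othv)

    ls_crit <- rep(log(0.2), n_cells)
    ls_oth <- lapply(othv, function(v) rep(log(0.1), P))
    ls_pop <- setNames(rep(log(0.1), 7), pop_names)
    acc_tally <- setNames(numeric(length(block_names)), block_names)

    group_ld <- function(p, mu_p, sd_p, b) {
      if (p == criterion) {
        sum(dnorm(critv, mu_p + b * x, sd_p, log = TRUE))
      } else {
        sum(dnorm(othv[[p]], mu_p, sd_p, log = TRUE))
      }
    }

    for (t in seq_len(n_sweeps)) {
      in_warmup <- t <= cfg$warmup
      g <- adapt_gamma(t)

      # --- criterion parameter, one scalar walk per cell, vectorized ---
      prop <- critv + exp(ls_crit) * rnorm(n_cells)
      ll_new <- ll_of(prop, othv)
      m_cell <- mu[[criterion]] + beta * x
      logr <- (ll_new - cur_ll) +
        dnorm(prop, m_cell, exp(lsd[[criterion]]), log = TRUE) -
        dnorm(critv, m_cell, exp(lsd[[criterion]]), log = TRUE)
      acc <- log(runif(n_cells)) < logr
      acc[!is.finite(logr)] <- FALSE
      critv[acc] <- prop[acc]
      cur_ll[acc] <- ll_new[acc]
      if (in_warmup) {
        ls_crit <- ls_crit + g * (acc - ta)
      } else {
        acc_tally[["crit"]] <- acc_tally[["crit"]] + mean(acc)
      }

      # --- non-criterion parameters, one scalar walk per participant ---
      for (p in others) {
        prop_p <- othv[[p]] + exp(ls_oth[[p]]) * rnorm(P)
        oth_prop <- othv
        oth_prop[[p]] <- prop_p
        ll_new <- ll_of(critv, oth_prop)
        dll <- ll_new - cur_ll
        dll[!is.finite(ll_new)] <- -Inf
        dll_p <- if (between) dll else as.numeric(rowsum(dll, pidx))
        logr <- dll_p +
          dnorm(prop_p, mu[[p]], exp(lsd[[p]]), log = TRUE) -
          dnorm(othv[[p]], mu[[p]], exp(lsd[[p]]), log = TRUE)
        acc <- log(runif(P)) < logr
        acc[!is.finite(logr)] <- FALSE
        othv[[p]][acc] <- prop_p[acc]
        acc_cell <- acc[pidx]
        cur_ll[acc_cell] <- ll_new[acc_cell]
        bn <- paste0("oth_", p)
        if (in_warmup) {
          ls_oth[[p]] <- ls_oth[[p]] + g * (acc - ta)
        } else {
          acc_tally[[bn]] <- acc_tally[[bn]] + mean(acc)
        }
      }

      # --- population-level scalars ---
      for (p in c("drift", "boundary", "ndt")) {
        # mean
        nm <- mu_name(p)
        cur_t <- prior_logdens(priors[[nm]], mu[[p]]) +
          group_ld(p, mu[[p]], exp(lsd[[p]]), beta)
        prop1 <- mu[[p]] + exp(ls_pop[[nm]]) * rnorm(1)
        prop_t <- prior_logdens(priors[[nm]], prop1)
        if (is.finite(prop_t)) {
          prop_t <- prop_t + group_ld(p, prop1, exp(lsd[[p]]), beta)
        }
        a <- is.finite(prop_t) && log(runif(1)) < (prop_t - cur_t)
        if (a) mu[[p]] <- prop1
        if (in_warmup) {
          ls_pop[[nm]] <- ls_pop[[nm]] + g * ((a * 1) - ta)
        } else {
          acc_tally[[nm]] <- acc_tally[[nm]] + a
        }
        # SD, on the log scale with Jacobian
        nm <- sd_name(p)
        cur_t <- prior_logdens(priors[[nm]], exp(lsd[[p]])) + lsd[[p]] +
          group_ld(p, mu[[p]], exp(lsd[[p]]), beta)
        prop1 <- lsd[[p]] + exp(ls_pop[[nm]]) * rnorm(1)
        prop_t <- prior_logdens(priors[[nm]], exp(prop1)) + prop1
        if (is.finite(prop_t)) {
          prop_t <- prop_t + group_ld(p, mu[[p]], exp(prop1), beta)
        }
        a <- is.finite(prop_t) && log(runif(1)) < (prop_t - cur_t)
        if (a) lsd[[p]] <- prop1
        if (in_warmup) {
          ls_pop[[nm]] <- ls_pop[[nm]] + g * ((a * 1) - ta)
        } else {
          acc_tally[[nm]] <- acc_tally[[nm]] + a
        }
      }
      # regression weight
      cur_t <- prior_logdens(priors$beta, beta) +
        group_ld(criterion, mu[[criterion]], exp(lsd[[criterion]]), beta)
      prop1 <- beta + exp(ls_pop[["beta"]]) * rnorm(1)
      prop_t <- prior_logdens(priors$beta, prop1)
      if (is.finite(prop_t)) {
        prop_t <- prop_t +
          group_ld(criterion, mu[[criterion]], exp(lsd[[criterion]]),
                   prop1)
      }
      a <- is.finite(prop_t) && log(runif(1)) < (prop_t - cur_t)
      if (a) beta <- prop1
      if (in_warmup) {
        ls_pop[["beta"]] <- ls_pop[["beta"]] + g * ((a * 1) - ta)
      } else {
        acc_tally[["beta"]] <- acc_tally[["beta"]] + a
      }

      if (!in_warmup) {
        row <- c(mu[["drift"]], exp(lsd[["drift"]]), mu[["boundary"]],
                 exp(lsd[["boundary"]]), mu[["ndt"]], exp(lsd[["ndt"]]),
                 beta)
        for (p in c("drift", "boundary", "ndt")) {
          row <- c(row, if (p == criterion) critv else othv[[p]])
        }
        draws[t - cfg$warmup, ch, ] <- row
      }
    }
    accept[ch, ] <- acc_tally / cfg$draws
  }

  make_posterior(draws, accept, cfg,
                 extra = list(criterion = criterion, priors = priors,
                              lik = lik, stats = stats, x = x,
                              init = init)) -> post
  class(post) <- c("ezbhddm_fit", class(post))
  post
}

#' @export
print.ezbhddm_fit <- function(x, ...) {
  cat("EZ Bayesian hierarchical DDM fit\n")
  cat("  criterion:", x$criterion, "| cells:", nrow(x$stats),
      "| chains:", dim(x$draws)[2], "x", dim(x$draws)[1], "draws\n")
  b <- posterior_draws(x, "beta")
  ci <- quantile(b, c(0.025, 0.975))
  cat(sprintf("  beta: mean %.3f, 95%% CI [%.3f, %.3f]\n",
              mean(b), ci[1], ci[2]))
  rh <- x$diagnostics$rhat
  if (!all(is.na(rh))) {
    cat(sprintf("  split R-hat: max %.3f (%.0f%% of parameters < 1.05)\n",
                max(rh, na.rm = TRUE), 100 * mean(rh < 1.05, na.rm = TRUE)))
  }
  invisible(x)
}
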