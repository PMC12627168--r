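# Polynomial rolling hash (mod 2^31 - 1) of a configuration string; used
# for cache keys and for deriving replicate seeds deterministically from
# (base seed, cell, index).  Exact in double arithmetic: intermediate
# values stay below 2^53.
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Deterministic replicate seed below 2^31.
replicate_seed <- function(base_seed, cell_hash, r) {
  as.integer((as.numeric(base_seed) * 1000003 + as.numeric(cell_hash) * 97 +
                as.numeric(r) * 31 + 17) %% 2147483629)
}

cell_hash <- function(criterion, design, P, T_trials, beta_true, reps) {
  config_hash(paste(criterion, design, P, T_trials,
              format(beta_true, digits = 12), reps, sep = "|"))
}

#' Run one parameter-recovery cell
#'
#' Simulates `reps` hierarchical datasets at a fixed scenario (criterion
#' parameter x design), fits each with [fit_ezbhddm()], and records the
#' posterior mean and central 95% credible interval of the regression
#' weight and of the population means.  Aggregates report the bias of the
#' `beta` estimates, their empirical SD across replicates, and the
#' fraction of credible intervals covering the generating value.
#' Replicates whose sampler fails are recorded with their error message,
#' never silently dropped.
#'
#' @param criterion,design Scenario: which parameter carries the weight,
#'   and `"regression"`, `"ttest_between"` or `"ttest_within"`.
#' @param P,T_trials Participants and trials per cell.
#' @param beta_true Generating regression weight.
#' @param reps Number of replicate datasets.
#' @param base_seed Base seed; replicate seeds are derived
#'   deterministically from (base seed, cell hash, replicate index).
#' @param pop Generating [population_params()]; its `beta` is overridden
#'   by `beta_true`.
#' @param cfg Sampler settings for each replicate fit.  The default is a
#'   desk-scale setting (2 chains, 500 warmup, 1000 draws) sized for
#'   recovery sweeps; increase for final analyses.
#' @param lik A [likelihood_config()].
#' @param dt Euler step for the data simulator.
#' @param bayes_factor If `TRUE`, also compute the Savage-Dickey
#'   `BF10` for `beta != 0` in every replicate.
#' @param priors A [prior_spec()].
#' @return An object of class `ezbhddm_recovery`: `replicates` (one row
#'   per replicate: seed, `beta_mean`, `beta_lo`, `beta_hi`, posterior
#'   means of the population means, R-hat summary, optional `bf10`,
#'   `ok`/`error`), `summary` (bias, empirical SD, coverage, failure
#'   count) and the cell configuration.
#' @export
run_recovery_cell <- function(criterion = "drift", design = "regression",
                              P = 80, T_trials = 80, beta_true = 0.5,
                              reps = 100, base_seed = 1,
                              pop = population_params(),
                              cfg = sampler_config(chains = 2,
                                                   warmup = 500,
                                                   draws = 1000),
                              lik = likelihood_config(), dt = 1e-4,
                              bayes_factor = FALSE,
                              priors = prior_spec()) {
  if (reps < 1) stop("reps must be at least 1")
  pop$beta <- beta_true
  hash <- cell_hash(criterion, design, P, T_trials, beta_true, reps)
  design_obj <- design_spec(P, T_trials, design, criterion)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    seed_r <- replicate_seed(base_seed, hash, r)
    row <- data.frame(replicate = r, seed = seed_r, beta_mean = NA_real_,
                      beta_lo = NA_real_, beta_hi = NA_real_,
                      mu_drift = NA_real_, mu_bound = NA_real_,
                      mu_ndt = NA_real_, rhat_max = NA_real_,
                      rhat_frac_ok = NA_real_, bf10 = NA_real_,
                      ok = FALSE, error = NA_character_)
    res <- tryCatch({
      sim <- simulate_hierarchical(design_obj, pop, seed = seed_r, dt = dt)
      fcfg <- cfg
      fcfg$seed <- replicate_seed(base_seed, hash, r + reps)
      fit <- fit_ezbhddm(sim$stats, criterion, priors = priors,
                         cfg = fcfg, lik = lik)
      b <- posterior_draws(fit, "beta")
      ci <- quantile(b, c(0.025, 0.975))
      sm <- summary(fit)
      pm <- setNames(sm$mean, sm$parameter)
      rh <- fit$diagnostics$rhat
      row$beta_mean <- mean(b)
      row$beta_lo <- ci[[1]]
      row$beta_hi <- ci[[2]]
      row$mu_drift <- pm[["mu_drift"]]
      row$mu_bound <- pm[["mu_bound"]]
      row$mu_ndt <- pm[["mu_ndt"]]
      row$rhat_max <- max(rh, na.rm = TRUE)
      row$rhat_frac_ok <- mean(rh < 1.05, na.rm = TRUE)
      if (bayes_factor) {
        row$bf10 <- savage_dickey(fit, priors = priors)$bf10
      }
      row$ok <- TRUE
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[r]] <- res
  }
  replicates <- do.call(rbind, rows)
  out <- structure(list(
    replicates = replicates,
    summary = recovery_summary(replicates, beta_true),
    criterion = criterion, design = design, P = P, T_trials = T_trials,
    beta_true = beta_true, reps = reps, base_seed = base_seed,
    hash = hash, pop = pop, cfg = cfg
  ), class = "ezbhddm_recovery")
  out
}

# Aggregate a replicate table; invariant to replicate ordering.
recovery_summary <- function(replicates, beta_true) {
  okr <- replicates[replicates$ok, , drop = FALSE]
  list(
    n_ok = nrow(okr),
    n_failed = sum(!replicates$ok),
    beta_bias = mean(okr$beta_mean) - beta_true,
    beta_sd = if (nrow(okr) > 1) sd(okr$beta_mean) else NA_real_,
    coverage = mean(okr$beta_lo <= beta_true & beta_true <= okr$beta_hi),
    median_bf10 = if (all(is.na(okr$bf10))) NA_real_ else
      median(okr$bf10, na.rm = TRUE)
  )
}

#' @export
print.ezbhddm_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "recovery cell: %s / %s, P=%d, T=%d, beta=%.3g (%d/%d replicates ok)\n",
    x$criterion, x$design, x$P, x$T_trials, x$beta_true, s$n_ok, x$reps))
  cat(sprintf("  beta bias %.4f, empirical SD %.4f, 95%% CI coverage %.3f\n",
              s$beta_bias, s$beta_sd, s$coverage))
  if (!is.na(s$median_bf10)) {
    cat(sprintf("  median BF10 %.3g\n", s$median_bf10))
  }
  invisible(x)
}

#' Run a grid of recovery cells
#'
#' Full crossing of participant counts, trial counts, scenarios and
#' generating regression weights.  Cells are cached by a content hash of
#' their configuration, so an interrupted grid resumes without
#' recomputation (cache hits are logged).
#'
#' @param P_values,T_values Integer grids.
#' @param scenarios Data frame with columns `criterion` and `design`, one
#'   row per scenario; default is the drift-criterion regression design.
#' @param beta_values Generating regression weights.
#' @param reps Replicates per cell.
#' @param base_seed Base seed, combined with each cell's hash.
#' @param cache_dir Optional directory for cell caches (RDS files,
#'   runtime scratch only).
#' @param ... Passed to [run_recovery_cell()].
#' @return A data frame of class `ezbhddm_grid` with one row per cell
#'   (scenario, sizes, beta, bias, empirical SD, coverage, failures) and
#'   the full cell objects in attribute `"cells"`.
#' @export
run_grid <- function(P_values, T_values,
                     scenarios = data.frame(criterion = "drift",
                                            design = "regression"),
                     beta_values = 0.5, reps = 100, base_seed = 1,
                     cache_dir = NULL, ...) {
  if (length(P_values) == 0 || length(T_values) == 0 ||
      nrow(scenarios) == 0 || length(beta_values) == 0) {
    stop("empty grid")
  }
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  cells <- list()
  rows <- list()
  k <- 0
  for (s in seq_len(nrow(scenarios))) {
    for (P in P_values) for (T_trials in T_values) {
      for (b in beta_values) {
        k <- k + 1
        hash <- cell_hash(scenarios$criterion[s], scenarios$design[s],
                          P, T_trials, b, reps)
        cache_file <- if (!is.null(cache_dir)) {
          file.path(cache_dir, sprintf("cell-%d.rds", hash))
        }
        if (!is.null(cache_file) && file.exists(cache_file)) {
          cell <- readRDS(cache_file)
          message("cache hit: ", basename(cache_file))
        } else {
          cell <- run_recovery_cell(scenarios$criterion[s],
                                    scenarios$design[s], P, T_trials,
                                    beta_true = b, reps = reps,
                                    base_seed = base_seed, ...)
          if (!is.null(cache_file)) saveRDS(cell, cache_file)
        }
        cells[[k]] <- cell
        rows[[k]] <- data.frame(
          criterion = scenarios$criterion[s], design = scenarios$design[s],
          P = P, T_trials = T_trials, beta_true = b, reps = reps,
          n_ok = cell$summary$n_ok, n_failed = cell$summary$n_failed,
          beta_bias = cell$summary$beta_bias,
          beta_sd = cell$summary$beta_sd,
          coverage = cell$summary$coverage
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cells") <- cells
  class(out) <- c("ezbhddm_grid", class(out))
  out
}

#' Savage-Dickey Bayes factor for the regression weight
#'
#' For the point null `beta = 0` nested in the metaregression model, the
#' Bayes factor in favor of the null is the ratio of posterior to prior
#' density at zero; `bf10` is its reciprocal.  The posterior density is
#' estimated from the pooled post-warmup draws by a Gaussian kernel
#' density (Sheather-Jones bandwidth, with the default bandwidth as a
#' fallback); a moment-matched normal approximation is also reported, and
#' the result is flagged when the two disagree by more than 10%.
#'
#' @param x An `ezbhddm_fit` (its `beta` draws are used) or a numeric
#'   vector of posterior draws of the weight.
#' @param priors A [prior_spec()]; the `beta` component must be a normal
#'   so its density at zero is analytic.
#' @param min_draws Fewer pooled draws than this is an error (density
#'   estimation at a point needs a stable sample).
#' @return A list of class `ezbhddm_bf`: `bf10`, `bf01`, `prior_dens0`,
#'   `post_dens0`, `post_dens0_normal`, `method`, `disagree`.
#' @examples
#' savage_dickey(rnorm(5000, 0, 0.5))$bf01  # about 2 against N(0,1) prior
#' @export
savage_dickey <- function(x, priors = prior_spec(), min_draws = 100) {
  b <- if (inherits(x, "ezbhddm_post")) {
    as.numeric(posterior_draws(x, "beta"))
  } else {
    as.numeric(x)
  }
  b <- b[is.finite(b)]
  if (length(b) < min_draws) {
    stop("too few draws (", length(b), ") for a stable density estimate")
  }
  bp <- priors$beta
  if (bp$family != "normal") {
    stop("Savage-Dickey needs an analytic (normal) beta prior")
  }
  prior0 <- dnorm(0, bp$mean, bp$sd)
  dens <- tryCatch(density(b, bw = "SJ"),
                   error = function(e) density(b),
                   warning = function(w) density(b))
  post0 <- if (0 < min(dens$x) || 0 > max(dens$x)) {
    0
  } else {
    approx(dens$x, dens$y, xout = 0)$y
  }
  post0_norm <- max(dnorm(0, mean(b), sd(b)), .Machine$double.xmin)
  # when the draws leave no support near zero the kernel estimate
  # underflows; the moment-matched normal still gives an informative
  # magnitude for the (overwhelming) Bayes factor
  method <- "gaussian_kde_sj"
  if (!is.finite(post0) || post0 <= 0) {
    post0 <- post0_norm
    method <- "moment_normal_fallback"
  }
  disagree <- abs(post0 - post0_norm) / post0_norm > 0.10
  bf01 <- post0 / prior0
  structure(list(bf10 = 1 / bf01, bf01 = bf01, prior_dens0 = prior0,
                 post_dens0 = post0, post_dens0_normal = post0_norm,
                 bf01_normal = post0_norm / prior0,
                 method = method, disagree = disagree,
                 n_draws = length(b)),
            class = "ezbhddm_bf")
}

#' @export
print.ezbhddm_bf <- function(x, ...) {
  cat(sprintf("Savage-Dickey BF10 = %.4g (BF01 = %.4g), %s on %d draws\n",
              x$bf10, x$bf01, x$method, x$n_draws))
  if (x$disagree) {
    cat(sprintf("  note: normal-approximation BF01 = %.4g differs by >10%%\n",
                x$bf01_normal))
  }
  invisible(x)
}

#' Plot a recovery grid
#'
#' Estimate-versus-truth panels in the style of recovery-study figures:
#' per (P, T) panel, the median and central 95% band of the posterior-mean
#' `beta` estimates across replicates.  Requires ggplot2.
#'
#' @param grid An `ezbhddm_grid` from [run_grid()].
#' @return A ggplot object.
#' @export
plot_recovery <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_recovery requires the ggplot2 package")
  }
  cells <- attr(grid, "cells")
  pieces <- lapply(cells, function(cell) {
    ok <- cell$replicates[cell$replicates$ok, , drop = FALSE]
    data.frame(P = cell$P, T_trials = cell$T_trials,
               beta_true = cell$beta_true, beta_mean = ok$beta_mean)
  })
  df <- do.call(rbind, pieces)
  agg <- aggregate(beta_mean ~ P + T_trials + beta_true, df,
                   function(v) c(med = median(v),
                                 lo = quantile(v, 0.025),
                                 hi = quantile(v, 0.975)))
  agg <- cbind(agg[1:3], as.data.frame(agg$beta_mean))
  names(agg)[4:6] <- c("med", "lo", "hi")
  ggplot2::ggplot(agg, ggplot2::aes(x = beta_true)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = med)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_grid(T_trials ~ P, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "generating regression weight",
                  y = "posterior-mean estimate")
}
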