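#' Configure the proxy likelihood
#'
#' @param variance_law Sampling law used for the observed RT variance:
#'   `"normal_approx"` (large-sample normal with variance
#'   \eqn{2V^2/(N-1)}; the default) or `"gamma_exact"` (the exact
#'   \eqn{\mathrm{Gamma}((N-1)/2,\ 2V/(N-1))} law from which the normal
#'   approximation derives).
#' @param min_n Minimum trials per cell the likelihood will accept.
#' @return A list of class `ezbhddm_lik`.
#' @export
likelihood_config <- function(variance_law = c("normal_approx",
                                               "gamma_exact"),
                              min_n = 2L) {
  variance_law <- match.arg(variance_law)
  min_n <- as.integer(min_n)
  if (min_n < 2) stop("min_n must be at least 2")
  structure(list(variance_law = variance_law, min_n = min_n),
            class = "ezbhddm_lik")
}

# Vectorized per-cell log-likelihood.  Returns -Inf (the sampler's
# rejection sentinel) for invalid parameter proposals instead of raising,
# so Metropolis steps reject cleanly.
loglik_cells <- function(drift, boundary, ndt, N, n_correct, mean_rt,
                         var_rt, variance_law = "normal_approx") {
  n <- length(N)
  drift <- rep_len(drift, n)
  boundary <- rep_len(boundary, n)
  ndt <- rep_len(ndt, n)
  ll <- rep(-Inf, n)
  ok <- is.finite(drift) & is.finite(boundary) & is.finite(ndt) &
    boundary > 0
  if (!any(ok)) return(ll)
  f <- forward_core(drift[ok], boundary[ok], ndt[ok])
  Nk <- N[ok]
  llb <- dbinom(n_correct[ok], Nk, f$pred_acc, log = TRUE)
  llm <- dnorm(mean_rt[ok], f$pred_mean, sqrt(f$pred_var / Nk), log = TRUE)
  llv <- if (variance_law == "gamma_exact") {
    dgamma(var_rt[ok], shape = (Nk - 1) / 2,
           scale = 2 * f$pred_var / (Nk - 1), log = TRUE)
  } else {
    dnorm(var_rt[ok], f$pred_var,
          sqrt(2 * f$pred_var^2 / (Nk - 1)), log = TRUE)
  }
  tot <- llb + llm + llv
  tot[!is.finite(tot)] <- -Inf
  ll[ok] <- tot
  ll
}

#' Proxy log-likelihood of one cell's summary statistics
#'
#' Scores a cell's observed summaries against the sampling distributions
#' implied by a diffusion-parameter triple: the number of correct trials
#' is binomial in the predicted accuracy rate, the observed mean RT is
#' normal around the predicted mean with variance `pred_var / N`, and the
#' observed RT variance follows either a gamma law (exact for normal
#' samples) or its large-sample normal approximation, per the
#' configuration.  Predicted statistics come from [ez_forward()].
#'
#' @param params A one-row data frame (or list) with `drift`, `boundary`,
#'   `ndt`, e.g. from [ddm_params()].
#' @param stats A one-row data frame with `N`, `n_correct`, `mean_rt`,
#'   `var_rt`, e.g. from [summarize_cell()].
#' @param cfg A [likelihood_config()].
#' @param components If `TRUE`, attach the three term values as an
#'   attribute `"components"` (named `binomial`, `mean`, `variance`).
#' @return The log-likelihood (scalar); `-Inf` for parameter values
#'   outside the support (non-positive boundary).
#' @examples
#' s <- data.frame(N = 10, n_correct = 7, mean_rt = 0.53, var_rt = 0.034)
#' loglik_cell(ddm_params(1, 1, 0.3), s)
#' @export
loglik_cell <- function(params, stats, cfg = likelihood_config(),
                        components = FALSE) {
  if (any(stats$N < cfg$min_n)) {
    stop("cell has fewer than min_n = ", cfg$min_n, " trials")
  }
  if (stats$n_correct < 0 || stats$n_correct > stats$N ||
      stats$var_rt < 0) {
    stop("invalid summary statistics")
  }
  ll <- loglik_cells(params$drift, params$boundary, params$ndt,
                     stats$N, stats$n_correct, stats$mean_rt, stats$var_rt,
                     cfg$variance_law)
  if (components && is.finite(ll)) {
    f <- ez_forward(params$drift, params$boundary, params$ndt)
    comp <- c(
      binomial = dbinom(stats$n_correct, stats$N, f$pred_acc, log = TRUE),
      mean = dnorm(stats$mean_rt, f$pred_mean,
                   sqrt(f$pred_var / stats$N), log = TRUE),
      variance = if (cfg$variance_law == "gamma_exact") {
        dgamma(stats$var_rt, shape = (stats$N - 1) / 2,
               scale = 2 * f$pred_var / (stats$N - 1), log = TRUE)
      } else {
        dnorm(stats$var_rt, f$pred_var,
              sqrt(2 * f$pred_var^2 / (stats$N - 1)), log = TRUE)
      }
    )
    attr(ll, "components") <- comp
  }
  ll
}

#' Proxy log-likelihood of a whole dataset
#'
#' Sums [loglik_cell()] over cells, which are independent given their
#' parameters.  The parameter table and the statistics table must be
#' aligned row by row on (`participant`, `condition`).
#'
#' @param params Data frame with one row per cell: `participant`,
#'   optionally `condition`, and `drift`, `boundary`, `ndt`.
#' @param stats Data frame with one row per cell: `participant`,
#'   optionally `condition`, and `N`, `n_correct`, `mean_rt`, `var_rt`.
#' @param cfg A [likelihood_config()].
#' @return The total log-likelihood; `-Inf` if any cell is `-Inf`.
#' @export
loglik_dataset <- function(params, stats, cfg = likelihood_config()) {
  if (nrow(params) != nrow(stats)) {
    stop("misaligned tables: row counts differ")
  }
  for (key in intersect(c("participant", "condition"),
                        intersect(names(params), names(stats)))) {
    if (!identical(as.character(params[[key]]),
                   as.character(stats[[key]]))) {
      stop("misaligned tables: ", key, " keys differ")
    }
  }
  if (any(stats$N < cfg$min_n)) {
    stop("a cell has fewer than min_n = ", cfg$min_n, " trials")
  }
  ll <- loglik_cells(params$drift, params$boundary, params$ndt,
                     stats$N, stats$n_correct, stats$mean_rt, stats$var_rt,
                     cfg$variance_law)
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}

#' Closed-form maximum of the proxy likelihood for one cell
#'
#' The inverse EZ estimators, applied to the (edge-corrected) observed
#' summaries, maximize the per-cell proxy likelihood up to terms of order
#' 1/N; see the package vignette for the exact statement.
#'
#' @param stats One-row data frame with `N`, `n_correct`, `mean_rt`,
#'   `var_rt`.
#' @param edge_rule Edge-correction policy, see [edge_correct()].
#' @return A one-row data frame with `drift`, `boundary`, `ndt`.
#' @export
mle_cell <- function(stats, edge_rule = c("half", "none")) {
  edge_rule <- match.arg(edge_rule)
  acc <- edge_correct(stats$n_correct, stats$N, policy = edge_rule)
  ez_inverse(acc, stats$mean_rt, stats$var_rt)
}
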