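#' Construct and validate a set of diffusion parameters
#'
#' A single empirical unit's diffusion parameters: drift rate (evidence
#' units per second, any sign), boundary separation (evidence units,
#' strictly positive) and nondecision time (seconds, non-negative).
#'
#' @param drift Drift rate \eqn{\nu}: mean evidence accumulated per second.
#' @param boundary Boundary separation \eqn{\alpha}: distance between the
#'   two absorbing response boundaries; must be positive.
#' @param ndt Nondecision time \eqn{\tau} in seconds: encoding plus motor
#'   time; must be non-negative.
#' @return A one-row data frame with columns `drift`, `boundary`, `ndt`.
#' @examples
#' ddm_params(1, 1.5, 0.3)
#' @export
ddm_params <- function(drift, boundary, ndt) {
  stopifnot(length(drift) == 1, length(boundary) == 1, length(ndt) == 1)
  if (!is.finite(drift) || !is.finite(boundary) || !is.finite(ndt)) {
    stop("diffusion parameters must be finite")
  }
  if (boundary <= 0) stop("boundary separation must be > 0")
  if (ndt < 0) stop("nondecision time must be >= 0")
  data.frame(drift = drift, boundary = boundary, ndt = ndt)
}

# Decision-time variance of the unbiased diffusion; h = boundary * drift,
# q = exp(-h).  The closed form's numerator 1 - 2hq - q^2 cancels to O(h^3)
# near h = 0, so a series branch takes over below |h| = 1e-3 and the exact
# limit boundary^4/24 below |h| = 1e-6.
ez_var_dt <- function(drift, boundary, h, q) {
  v <- numeric(length(h))
  small <- abs(h) < 1e-6
  mid <- !small & abs(h) < 1e-3
  big <- !small & !mid
  if (any(big)) {
    hb <- h[big]
    qb <- q[big]
    num <- 1 - 2 * hb * qb - qb^2
    v[big] <- (boundary[big] / (2 * drift[big]^3)) * num / (1 + qb)^2
  }
  if (any(mid)) {
    hm <- h[mid]
    num <- hm^3 / 3 - hm^4 / 3 + 11 * hm^5 / 60 - 13 * hm^6 / 180
    v[mid] <- (boundary[mid]^4 / (2 * hm^3)) * num / (1 + q[mid])^2
  }
  if (any(small)) v[small] <- boundary[small]^4 / 24
  v
}

# Allocation-light forward kernel (no validation, returns a plain list);
# callers guarantee finite inputs and positive boundary.
forward_core <- function(drift, boundary, ndt) {
  h <- boundary * drift
  q <- exp(-h)
  mean_dt <- boundary^2 / 4
  nz <- abs(h) >= 1e-6
  if (any(nz)) {
    mean_dt[nz] <- (boundary[nz] / (2 * drift[nz])) * tanh(h[nz] / 2)
  }
  list(pred_acc = plogis(h), pred_mean = ndt + mean_dt,
       pred_var = ez_var_dt(drift, boundary, h, q))
}

#' Forward EZ system: predicted summary statistics from diffusion parameters
#'
#' Maps diffusion parameters to the model-implied accuracy rate and the
#' mean and variance of the correct response times, for an unbiased Wiener
#' diffusion with unit diffusion coefficient starting midway between the
#' boundaries.  With \eqn{q = \exp(-\alpha\nu)}:
#' \deqn{R = 1/(q+1),\quad
#'       M = \tau + \frac{\alpha}{2\nu}\,\frac{1-q}{1+q},\quad
#'       V = \frac{\alpha}{2\nu^3}\,\frac{1-2\alpha\nu q-q^2}{(q+1)^2}.}
#' At \eqn{\nu = 0} the removable singularity is handled analytically:
#' \eqn{R = 1/2}, \eqn{M = \tau + \alpha^2/4}, \eqn{V = \alpha^4/24}.
#'
#' @param drift,boundary,ndt Diffusion parameters, recycled to a common
#'   length.  `boundary` must be positive.
#' @return A data frame with columns `pred_acc` (in (0,1)), `pred_mean`
#'   (seconds) and `pred_var` (seconds squared).
#' @examples
#' ez_forward(1, 1, 0.3)  # accuracy 0.731, mean 0.531, variance 0.0344
#' @seealso [ez_inverse()] for the closed-form estimators.
#' @export
ez_forward <- function(drift, boundary, ndt) {
  n <- max(length(drift), length(boundary), length(ndt))
  drift <- rep_len(as.numeric(drift), n)
  boundary <- rep_len(as.numeric(boundary), n)
  ndt <- rep_len(as.numeric(ndt), n)
  if (anyNA(drift) || anyNA(boundary) || anyNA(ndt) ||
      any(!is.finite(drift)) || any(!is.finite(boundary)) ||
      any(!is.finite(ndt))) {
    stop("non-finite diffusion parameters")
  }
  if (any(boundary <= 0)) stop("boundary separation must be > 0")
  as.data.frame(forward_core(drift, boundary, ndt))
}

#' Inverse EZ system: closed-form diffusion-parameter estimators
#'
#' Recovers drift rate, boundary separation and nondecision time from an
#' observed accuracy rate and the mean and variance of the correct
#' response times.  With \eqn{L = \mathrm{logit}(R)}:
#' \deqn{\hat\nu = \mathrm{sgn}(R - 1/2)
#'   \left[\frac{L(R^2L - RL + R - 1/2)}{V}\right]^{1/4},\quad
#'   \hat\alpha = L/\hat\nu,}
#' and \eqn{\hat\tau = M - (\hat\alpha/2\hat\nu)\,
#' (1-e^{-\hat\nu\hat\alpha})/(1+e^{-\hat\nu\hat\alpha})}.
#' The system is the exact algebraic inverse of [ez_forward()].
#'
#' @param acc Observed accuracy rate, strictly inside (0,1) and not equal
#'   to 1/2 (apply [edge_correct()] to raw counts first).
#' @param mean_rt Observed mean of the correct response times (seconds).
#' @param var_rt Observed variance of the correct response times; must be
#'   positive.
#' @return A data frame with columns `drift`, `boundary`, `ndt`.
#' @examples
#' f <- ez_forward(1, 1, 0.3)
#' ez_inverse(f$pred_acc, f$pred_mean, f$pred_var)  # recovers (1, 1, 0.3)
#' @export
ez_inverse <- function(acc, mean_rt, var_rt) {
  n <- max(length(acc), length(mean_rt), length(var_rt))
  acc <- rep_len(as.numeric(acc), n)
  mean_rt <- rep_len(as.numeric(mean_rt), n)
  var_rt <- rep_len(as.numeric(var_rt), n)
  if (any(!is.finite(acc)) || any(!is.finite(mean_rt)) ||
      any(!is.finite(var_rt))) {
    stop("non-finite summary statistics")
  }
  if (any(acc <= 0 | acc >= 1)) {
    stop("accuracy rate must be strictly inside (0, 1); edge-correct first")
  }
  if (any(acc == 0.5)) {
    stop("accuracy rate exactly 1/2: chance-level cell, drift sign and ",
         "boundary are not identified")
  }
  if (any(var_rt <= 0)) stop("variance of correct RTs must be > 0")
  L <- qlogis(acc)
  A <- L * (acc^2 * L - acc * L + acc - 0.5) / var_rt
  drift <- sign(acc - 0.5) * A^0.25
  boundary <- L / drift
  q <- exp(-drift * boundary)
  ndt <- mean_rt - (boundary / (2 * drift)) * (1 - q) / (1 + q)
  data.frame(drift = drift, boundary = boundary, ndt = ndt)
}

#' Edge-correct an observed accuracy rate
#'
#' The logit in the inverse EZ system diverges when every trial (or no
#' trial) is correct.  The default policy replaces a proportion of 0 with
#' \eqn{1/(2N)} and a proportion of 1 with \eqn{1 - 1/(2N)}, the standard
#' continuity correction for logits of extreme proportions; interior
#' proportions are returned unchanged.
#'
#' @param n_correct Number of correct trials (integer, 0..`n_trials`).
#' @param n_trials Total number of trials in the cell; must be positive.
#' @param policy `"half"` (the \eqn{1/(2N)} rule) or `"none"` (return the
#'   raw proportion).
#' @return The (possibly corrected) accuracy rate, vectorized.
#' @examples
#' edge_correct(100, 100)  # 0.995
#' edge_correct(0, 20)     # 0.025
#' @export
edge_correct <- function(n_correct, n_trials, policy = c("half", "none")) {
  policy <- match.arg(policy)
  n <- max(length(n_correct), length(n_trials))
  n_correct <- rep_len(n_correct, n)
  n_trials <- rep_len(n_trials, n)
  if (any(n_trials <= 0)) stop("n_trials must be > 0")
  if (any(n_correct < 0 | n_correct > n_trials)) {
    stop("n_correct must lie in 0..n_trials")
  }
  r <- n_correct / n_trials
  if (policy == "half") {
    r[n_correct == 0] <- 1 / (2 * n_trials[n_correct == 0])
    r[n_correct == n_trials] <- 1 - 1 / (2 * n_trials[n_correct == n_trials])
  }
  r
}

#' Summarize one design cell of trials
#'
#' Computes the summary statistics the proxy likelihood scores: total trial
#' count, number of correct responses, and the mean and unbiased variance
#' of the response times.  By default only correct-trial RTs enter the
#' moments; under the unbiased three-parameter diffusion the correct and
#' error RT distributions coincide, so an all-trials variant is offered.
#'
#' @param rt Response times in seconds.
#' @param accuracy 0/1 accuracy per trial (1 = correct / upper boundary).
#' @param correct_only If `TRUE` (default) RT moments use correct trials
#'   only; if `FALSE`, all trials.
#' @return A one-row data frame with columns `N`, `n_correct`, `mean_rt`,
#'   `var_rt`.
#' @examples
#' summarize_cell(c(0.5, 0.7, 0.6), c(1, 1, 0))
#' @export
summarize_cell <- function(rt, accuracy, correct_only = TRUE) {
  if (length(rt) != length(accuracy)) stop("rt and accuracy lengths differ")
  if (!all(accuracy %in% c(0, 1))) stop("accuracy must be 0 or 1")
  N <- length(rt)
  n_correct <- sum(accuracy == 1)
  use <- if (correct_only) rt[accuracy == 1] else rt
  if (n_correct < 2) {
    stop("cell too small: need at least 2 correct trials for an RT variance")
  }
  data.frame(N = N, n_correct = n_correct,
             mean_rt = mean(use), var_rt = var(use))
}

#' Summarize a trial table into per-cell summary statistics
#'
#' Splits a long-format trial table by participant (and condition, when
#' present) and applies [summarize_cell()] to each cell.  Cells with fewer
#' than two correct trials cannot provide an RT variance; they are dropped
#' with a warning rather than failing the run.
#'
#' @param trials Data frame with columns `participant`, `accuracy`, `rt`
#'   and optionally `condition`.
#' @param correct_only Passed to [summarize_cell()].
#' @return A data frame with one row per cell: `participant`, `condition`
#'   (if present in the input), `N`, `n_correct`, `mean_rt`, `var_rt`.  Any
#'   additional per-cell-constant column (e.g. a covariate `x`) is carried
#'   through.
#' @export
summarize_trials <- function(trials, correct_only = TRUE) {
  req <- c("participant", "accuracy", "rt")
  if (!all(req %in% names(trials))) {
    stop("trials must have columns: ", paste(req, collapse = ", "))
  }
  has_cond <- "condition" %in% names(trials)
  key <- if (has_cond) {
    interaction(trials$participant, trials$condition, drop = TRUE, lex.order = TRUE)
  } else {
    factor(trials$participant, levels = unique(trials$participant))
  }
  carry <- setdiff(names(trials), c(req, "condition"))
  pieces <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    cell <- trials[idx, , drop = FALSE]
    s <- tryCatch(
      summarize_cell(cell$rt, cell$accuracy, correct_only = correct_only),
      error = function(e) NULL
    )
    if (is.null(s)) return(NULL)
    out <- data.frame(participant = cell$participant[1])
    if (has_cond) out$condition <- cell$condition[1]
    out <- cbind(out, s)
    for (cc in carry) {
      if (length(unique(cell[[cc]])) == 1) out[[cc]] <- cell[[cc]][1]
    }
    out
  })
  dropped <- sum(vapply(pieces, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " cell(s) dropped: fewer than 2 correct trials")
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("no valid cells after summarizing")
  rownames(out) <- NULL
  out
}
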