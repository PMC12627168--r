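#' Specify a study design for simulation and recovery
#'
#' @param P Number of participants (positive integer).
#' @param T_trials Trials per design cell (integer, at least 2: the RT
#'   variance needs two correct trials).
#' @param design One of `"regression"` (per-participant covariate in
#'   \[0,1\]), `"ttest_between"` (binary per-participant covariate) or
#'   `"ttest_within"` (two conditions per participant, covariate 0/1 per
#'   condition).
#' @param criterion Which diffusion parameter carries the metaregression
#'   weight: `"drift"`, `"boundary"` or `"ndt"`.
#' @param x Optional covariate values: length `P` for the between designs,
#'   one per condition for the within design.  Defaults: evenly spaced on
#'   \[0,1\] for `"regression"`, a balanced 0/1 split for
#'   `"ttest_between"`, and `c(0, 1)` for `"ttest_within"`.
#' @return An object of class `ezbhddm_design`.
#' @export
design_spec <- function(P, T_trials,
                        design = c("regression", "ttest_between",
                                   "ttest_within"),
                        criterion = c("drift", "boundary", "ndt"),
                        x = NULL) {
  design <- match.arg(design)
  criterion <- match.arg(criterion)
  P <- as.integer(P)
  T_trials <- as.integer(T_trials)
  if (P < 1) stop("P must be a positive integer")
  if (T_trials < 2) stop("T_trials must be at least 2")
  if (is.null(x)) {
    x <- switch(design,
      regression = if (P == 1) 0.5 else seq(0, 1, length.out = P),
      ttest_between = sort(rep(c(0, 1), length.out = P)),
      ttest_within = c(0, 1)
    )
  }
  if (design == "ttest_within") {
    if (length(x) < 2) stop("within design needs one covariate per condition")
  } else {
    if (length(x) != P) stop("covariate length must equal P")
    if (design == "ttest_between" && !all(x %in% c(0, 1))) {
      stop("ttest_between covariate must be binary 0/1")
    }
    if (design == "regression" && (any(x < 0) || any(x > 1))) {
      stop("regression covariate must lie in [0, 1]")
    }
  }
  structure(list(P = P, T_trials = T_trials, design = design,
                 criterion = criterion, x = x),
            class = "ezbhddm_design")
}

#' Specify population-level parameters
#'
#' Group-level means and standard deviations of the three diffusion
#' parameters, plus the metaregression weight applied to the criterion
#' parameter designated in the design.  Defaults describe a typical
#' two-choice task under the unit-diffusion-coefficient scaling: mean
#' drift 1, boundary separation 1.5, nondecision time 0.4 s, with
#' moderate between-person spread.
#'
#' @param mu_drift,sd_drift Mean and SD of individual drift rates.
#' @param mu_bound,sd_bound Mean and SD of individual boundary separations;
#'   `mu_bound` must be positive.
#' @param mu_ndt,sd_ndt Mean and SD of individual nondecision times
#'   (seconds); `mu_ndt` must be non-negative.
#' @param beta Metaregression weight on the criterion parameter.
#' @return An object of class `ezbhddm_pop` (a named list).
#' @export
population_params <- function(mu_drift = 1, sd_drift = 0.5,
                              mu_bound = 1.5, sd_bound = 0.2,
                              mu_ndt = 0.4, sd_ndt = 0.06,
                              beta = 0) {
  pop <- list(mu_drift = mu_drift, sd_drift = sd_drift,
              mu_bound = mu_bound, sd_bound = sd_bound,
              mu_ndt = mu_ndt, sd_ndt = sd_ndt, beta = beta)
  if (any(!vapply(pop, is.finite, logical(1)))) {
    stop("population parameters must be finite")
  }
  if (sd_drift <= 0 || sd_bound <= 0 || sd_ndt <= 0) {
    stop("population standard deviations must be > 0")
  }
  if (mu_bound <= 0) stop("mu_bound must be > 0")
  if (mu_ndt < 0) stop("mu_ndt must be >= 0")
  structure(pop, class = "ezbhddm_pop")
}

#' Simulate Wiener diffusion trials
#'
#' Simulates two-choice trials from an unbiased Wiener diffusion (unit
#' diffusion coefficient, start at `boundary/2`) by an Euler-Maruyama walk
#' with step mean `drift * dt` and step SD `sqrt(dt)`, absorbed at 0 or
#' `boundary`.  The response time is `ndt` plus the absorption time;
#' accuracy is 1 when the upper boundary is hit.  Discretization biases
#' absorption times upward by O(sqrt(dt)); see the package vignette.
#'
#' @param n Number of trials (at least 1).
#' @param drift,boundary,ndt Diffusion parameters; scalars or length-`n`
#'   vectors (one triple per trial).
#' @param dt Euler time step in seconds (positive; default 1e-4).
#' @param max_time Simulation horizon in seconds; the rare trial still
#'   unabsorbed at the horizon is resolved by the sign of its current
#'   position and triggers a warning.
#' @param boundary_correction If `TRUE` (default), apply the continuity
#'   correction for discretely monitored barriers: each absorbing
#'   boundary is pulled inward by \eqn{0.5826\sqrt{dt}}, which removes
#'   the leading O(sqrt(dt)) overshoot bias of the Euler scheme in both
#'   accuracy and absorption time.  Set to `FALSE` for the uncorrected
#'   walk.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `accuracy` (0/1) and `rt` (seconds,
#'   always greater than `ndt`).
#' @examples
#' simulate_trials(5, 1, 1, 0.3, dt = 1e-3, seed = 1)
#' @export
simulate_trials <- function(n, drift, boundary, ndt, dt = 1e-4,
                            max_time = 20, boundary_correction = TRUE,
                            seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be at least 1")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  drift <- rep_len(as.numeric(drift), n)
  boundary <- rep_len(as.numeric(boundary), n)
  ndt <- rep_len(as.numeric(ndt), n)
  if (any(!is.finite(drift)) || any(!is.finite(boundary)) ||
      any(!is.finite(ndt))) {
    stop("non-finite diffusion parameters")
  }
  if (any(boundary <= 0)) stop("boundary separation must be > 0")
  if (any(ndt < 0)) stop("nondecision time must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  b_eff <- effective_boundary(boundary, dt, boundary_correction)
  out <- euler_sim_cpp(drift, b_eff, ndt, dt, max_time)
  if (any(out$censored == 1)) {
    warning(sum(out$censored), " trial(s) unabsorbed at max_time = ",
            max_time, " s; resolved by current position")
  }
  data.frame(accuracy = out$accuracy, rt = out$rt)
}

#' Simulate a single Wiener diffusion trial
#'
#' Convenience wrapper around [simulate_trials()] with `n = 1`.
#'
#' @inheritParams simulate_trials
#' @return A one-row data frame with columns `accuracy` and `rt`.
#' @export
simulate_trial <- function(drift, boundary, ndt, dt = 1e-4, max_time = 20,
                           seed = NULL) {
  simulate_trials(1, drift, boundary, ndt, dt = dt, max_time = max_time,
                  seed = seed)
}

# Continuity-corrected boundary separation for discretely monitored
# absorption (each barrier pulled in by 0.5826 * sqrt(dt)).
effective_boundary <- function(boundary, dt, correct = TRUE) {
  if (!correct) return(boundary)
  shift <- 2 * 0.5826 * sqrt(dt)
  if (any(boundary <= 2 * shift)) {
    stop("boundary separation too small for this dt; reduce dt")
  }
  boundary - shift
}

# Draw individual parameters from a normal parent, rejecting draws below
# `floor` (positivity constraint on boundary and nondecision time).
draw_truncated <- function(n, mean, sd, floor = -Inf, max_tries = 1000) {
  out <- rnorm(n, mean, sd)
  rejections <- 0L
  tries <- 0L
  while (any(bad <- out < floor)) {
    rejections <- rejections + sum(bad)
    out[bad] <- rnorm(sum(bad), mean[bad], sd)
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not draw parameters above the positivity floor; ",
           "population mean/SD place almost no mass there")
    }
  }
  attr(out, "rejections") <- rejections
  out
}

#' Simulate a full hierarchical dataset
#'
#' Draws individual diffusion parameters from normal parent distributions
#' -- with the criterion parameter's mean shifted by `beta * x` -- then
#' simulates `T_trials` Wiener diffusion trials per design cell and returns
#' both the per-cell summary statistics and the true individual parameters
#' for recovery scoring.  In the within-subjects design each participant
#' contributes one cell per condition, with an independent criterion draw
#' per cell and shared values of the other two parameters.
#'
#' Parent draws of boundary separation below `bound_floor`, or of
#' nondecision time below `ndt_floor`, are rejection-resampled (the parent
#' normals are otherwise untruncated); the number of rejections is
#' reported.  The rare cell with fewer than two correct trials is
#' re-simulated so every cell yields a valid RT variance.
#'
#' @param design An [design_spec()] object.
#' @param pop A [population_params()] object.
#' @param seed Optional integer seed.
#' @param dt,max_time Passed to the trial simulator.
#' @param bound_floor,ndt_floor Positivity floors for parent draws.
#' @param correct_only Passed to [summarize_cell()].
#' @return A list of class `ezbhddm_sim` with elements `stats` (per-cell
#'   data frame: `participant`, `condition`, `x`, `N`, `n_correct`,
#'   `mean_rt`, `var_rt`), `truth` (per-cell true `drift`, `boundary`,
#'   `ndt`), `trials` (the raw trial table), `pop`, `design`, `seed`,
#'   `n_rejections` and `n_resimulated`.
#' @export
simulate_hierarchical <- function(design, pop, seed = NULL, dt = 1e-4,
                                  max_time = 20, bound_floor = 0.01,
                                  ndt_floor = 0, correct_only = TRUE,
                                  boundary_correction = TRUE) {
  stopifnot(inherits(design, "ezbhddm_design"), inherits(pop, "ezbhddm_pop"))
  if (!is.null(seed)) set.seed(seed)
  P <- design$P
  within <- design$design == "ttest_within"
  n_cond <- if (within) length(design$x) else 1L
  # one row per cell
  cells <- if (within) {
    data.frame(participant = rep(seq_len(P), each = n_cond),
               condition = rep(seq_len(n_cond), times = P),
               x = rep(design$x, times = P))
  } else {
    data.frame(participant = seq_len(P), condition = 1L, x = design$x)
  }
  n_cells <- nrow(cells)

  crit <- design$criterion
  mu <- c(drift = pop$mu_drift, boundary = pop$mu_bound, ndt = pop$mu_ndt)
  sds <- c(drift = pop$sd_drift, boundary = pop$sd_bound, ndt = pop$sd_ndt)
  floors <- c(drift = -Inf, boundary = bound_floor, ndt = ndt_floor)
  # map cell rows to each parameter's mean; criterion gets beta * x
  n_rej <- 0L
  par_cell <- list()
  for (pname in c("drift", "boundary", "ndt")) {
    if (pname == crit) {
      m <- mu[[pname]] + pop$beta * cells$x
      d <- draw_truncated(n_cells, m, sds[[pname]], floors[[pname]])
      par_cell[[pname]] <- as.numeric(d)
      n_rej <- n_rej + attr(d, "rejections")
    } else {
      m <- rep(mu[[pname]], P)
      d <- draw_truncated(P, m, sds[[pname]], floors[[pname]])
      par_cell[[pname]] <- as.numeric(d)[cells$participant]
      n_rej <- n_rej + attr(d, "rejections")
    }
  }
  truth <- cbind(cells[c("participant", "condition", "x")],
                 as.data.frame(par_cell))

  T_trials <- design$T_trials
  idx_cell <- rep(seq_len(n_cells), each = T_trials)
  b_eff <- effective_boundary(truth$boundary, dt, boundary_correction)
  tr <- euler_sim_cpp(truth$drift[idx_cell], b_eff[idx_cell],
                      truth$ndt[idx_cell], dt, max_time)
  trials <- data.frame(participant = cells$participant[idx_cell],
                       condition = cells$condition[idx_cell],
                       x = cells$x[idx_cell],
                       accuracy = tr$accuracy, rt = tr$rt)

  # re-simulate the rare cell without >= 2 correct trials
  n_resim <- 0L
  repeat {
    n_corr <- tapply(trials$accuracy, idx_cell, sum)
    bad <- which(n_corr < 2)
    if (length(bad) == 0) break
    n_resim <- n_resim + length(bad)
    if (n_resim > 200 * n_cells) {
      stop("cells persistently produce < 2 correct trials; ",
           "population parameters imply near-floor accuracy")
    }
    for (b in bad) {
      rows <- which(idx_cell == b)
      rtr <- euler_sim_cpp(rep(truth$drift[b], T_trials),
                           rep(b_eff[b], T_trials),
                           rep(truth$ndt[b], T_trials), dt, max_time)
      trials$accuracy[rows] <- rtr$accuracy
      trials$rt[rows] <- rtr$rt
    }
  }

  stats <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    rows <- idx_cell == i
    summarize_cell(trials$rt[rows], trials$accuracy[rows],
                   correct_only = correct_only)
  }))
  stats <- cbind(cells[c("participant", "condition", "x")], stats)
  rownames(stats) <- NULL

  structure(list(stats = stats, truth = truth, trials = trials, pop = pop,
                 design = design, seed = seed, dt = dt,
                 n_rejections = n_rej, n_resimulated = n_resim),
            class = "ezbhddm_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the trial-level CSV (`participant`, `condition`, `accuracy`,
#' `rt`), the true-parameters CSV, and a sidecar JSON recording the seed,
#' time step, design and population parameters.
#'
#' @param sim An `ezbhddm_sim` object from [simulate_hierarchical()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "ezbhddm_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    trials = file.path(dir, paste0(prefix, "_trials.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.csv")),
    summaries = file.path(dir, paste0(prefix, "_summaries.csv")),
    meta = file.path(dir, paste0(prefix, "_meta.json"))
  )
  write.csv(sim$trials, paths[["trials"]], row.names = FALSE)
  write.csv(sim$truth, paths[["truth"]], row.names = FALSE)
  write.csv(sim$stats, paths[["summaries"]], row.names = FALSE)
  meta <- list(seed = sim$seed, dt = sim$dt,
               design = unclass(sim$design), pop = unclass(sim$pop),
               n_rejections = sim$n_rejections,
               n_resimulated = sim$n_resimulated,
               package_version = as.character(packageVersion("ezbhddm")))
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
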