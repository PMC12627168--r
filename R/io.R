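#' Read and validate a trial-level CSV
#'
#' Expects a header row and (after renaming via `columns`) the columns
#' `participant`, `accuracy` (0/1) and `rt` (positive, finite), with
#' `condition` and a covariate column optional.  Rows with non-positive
#' or non-finite RT are rejected individually and reported; any accuracy
#' value outside \{0, 1\} is a hard error naming the offending value.
#'
#' @param path CSV file path.
#' @param columns Named character vector mapping the required names to
#'   the file's column names, e.g.
#'   `c(participant = "subj", accuracy = "acc", rt = "RT")`.
#' @param rt_unit `"s"` (default) or `"ms"`; millisecond RTs are
#'   converted to seconds.
#' @return Validated trial data frame; the per-row validation report is
#'   attached as attribute `"validation"` (a list with `n_read`,
#'   `n_dropped`, `dropped_rows`).
#' @export
read_trials <- function(path, columns = NULL, rt_unit = c("s", "ms")) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty trial file: ", path)
  if (!is.null(columns)) {
    for (nm in names(columns)) {
      if (!(columns[[nm]] %in% names(df))) {
        stop("mapped column not in file: ", columns[[nm]])
      }
      names(df)[names(df) == columns[[nm]]] <- nm
    }
  }
  req <- c("participant", "accuracy", "rt")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  bad_acc <- !(df$accuracy %in% c(0, 1))
  if (any(bad_acc)) {
    stop("accuracy must be 0 or 1; found value '",
         df$accuracy[which(bad_acc)[1]], "' in row ", which(bad_acc)[1])
  }
  df$rt <- as.numeric(df$rt)
  if (rt_unit == "ms") df$rt <- df$rt / 1000
  drop <- !is.finite(df$rt) | df$rt <= 0
  report <- list(n_read = nrow(df), n_dropped = sum(drop),
                 dropped_rows = which(drop))
  if (any(drop)) {
    message(sum(drop), " row(s) dropped: non-positive or non-finite RT")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid rows after RT validation")
  rownames(df) <- NULL
  attr(df, "validation") <- report
  df
}

#' Read and validate a per-cell summary CSV
#'
#' Enables meta-analytic input: cells described only by conventionally
#' reported statistics.  Requires per cell either `n_correct` or an
#' `accuracy` rate column alongside `N` (or `n_trials`), plus `mean_rt`
#' and `var_rt`.  Rates are converted to integer counts; a rate whose
#' implied count is farther than `rate_tol` from an integer is an error
#' (it cannot come from a count out of `N`).
#'
#' @param path CSV file path.
#' @param rate_tol Tolerance (in trials) for rate-to-count conversion.
#' @return Validated per-cell data frame with columns `participant`,
#'   optional `condition` and covariate, `N`, `n_correct`, `mean_rt`,
#'   `var_rt`.
#' @export
read_summaries <- function(path, rate_tol = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty summary file: ", path)
  if (!("N" %in% names(df)) && "n_trials" %in% names(df)) {
    names(df)[names(df) == "n_trials"] <- "N"
  }
  req <- c("participant", "N", "mean_rt", "var_rt")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!("n_correct" %in% names(df))) {
    if (!("accuracy" %in% names(df))) {
      stop("need either an n_correct or an accuracy (rate) column")
    }
    counts <- df$accuracy * df$N
    off <- abs(counts - round(counts))
    if (any(off > rate_tol)) {
      i <- which(off > rate_tol)[1]
      stop(sprintf(
        "accuracy rate %.6g with N = %d implies a non-integer count %.6g",
        df$accuracy[i], df$N[i], counts[i]))
    }
    df$n_correct <- as.integer(round(counts))
  }
  if (any(df$n_correct < 0 | df$n_correct > df$N)) {
    stop("n_correct must lie in 0..N")
  }
  if (any(df$var_rt < 0)) stop("var_rt must be non-negative")
  if (any(df$mean_rt <= 0)) stop("mean_rt must be positive")
  if (any(df$N < 2)) stop("every cell needs N >= 2")
  df
}

#' Write posterior draws, diagnostics and provenance of a fit
#'
#' Writes a columnar draws CSV (`chain`, `iter`, `parameter`, `value`),
#' a diagnostics JSON (per-parameter split R-hat and ESS, acceptance
#' rates), a provenance JSON (resolved sampler configuration, priors,
#' seed, package version) and a short human-readable summary.
#'
#' @param fit An `ezbhddm_fit` or `ezbhddm_post` object.
#' @param dir Output directory, created if missing.
#' @param prefix File-name prefix.
#' @param pars Which parameters to write; default the seven population
#'   parameters (individual parameters multiply file size quickly).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, prefix = "fit",
                      pars = c("mu_drift", "sd_drift", "mu_bound",
                               "sd_bound", "mu_ndt", "sd_ndt", "beta")) {
  stopifnot(inherits(fit, "ezbhddm_post"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- dimnames(fit$draws)[[3]]
  pars <- intersect(pars, nm)
  if (length(pars) == 0) pars <- nm
  dm <- dim(fit$draws)
  long <- do.call(rbind, lapply(pars, function(p) {
    data.frame(chain = rep(seq_len(dm[2]), each = dm[1]),
               iter = rep(seq_len(dm[1]), times = dm[2]),
               parameter = p,
               value = as.numeric(fit$draws[, , p]))
  }))
  paths <- c(draws = file.path(dir, paste0(prefix, "_draws.csv")),
             diagnostics = file.path(dir, paste0(prefix,
                                                 "_diagnostics.json")),
             provenance = file.path(dir, paste0(prefix,
                                                "_provenance.json")),
             summary = file.path(dir, paste0(prefix, "_summary.txt")))
  write.csv(long, paths[["draws"]], row.names = FALSE)
  jsonlite::write_json(
    list(diagnostics = fit$diagnostics,
         acceptance = as.data.frame(fit$accept)),
    paths[["diagnostics"]], auto_unbox = TRUE, digits = NA)
  prov <- list(config = unclass(fit$config),
               seed = fit$config$seed,
               criterion = fit$criterion,
               priors = if (!is.null(fit$priors)) unclass(fit$priors),
               likelihood = if (!is.null(fit$lik)) unclass(fit$lik),
               package_version = as.character(packageVersion("ezbhddm")))
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  sm <- summary(fit)
  txt <- utils::capture.output(print(sm[sm$parameter %in% pars, ],
                                     row.names = FALSE))
  writeLines(txt, paths[["summary"]])
  invisible(paths)
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json, got: .", ext)
  }
  if (!is.list(cfg)) stop("malformed config: top level must be a mapping")
  cfg
}

cli_usage <- function() {
  paste(
    "usage: ezbhddm <subcommand> [options]",
    "subcommands:",
    "  simulate   --out DIR [--config FILE] [--seed INT]",
    "  summarize  --trials FILE --out DIR",
    "  fit        --out DIR (--trials FILE | --summaries FILE)",
    "             [--criterion drift|boundary|ndt] [--config FILE]",
    "             [--seed INT]",
    "  recover    --out DIR [--config FILE] [--seed INT]",
    "  bf         --out DIR (--trials FILE | --summaries FILE)",
    "             [--criterion ...] [--config FILE] [--seed INT]",
    sep = "\n")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}

cli_sampler_config <- function(cfg, seed) {
  s <- cfg$sampler
  sampler_config(
    chains = if (!is.null(s$chains)) s$chains else 2L,
    warmup = if (!is.null(s$warmup)) s$warmup else 500L,
    draws = if (!is.null(s$draws)) s$draws else 1000L,
    seed = seed
  )
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `summarize`, `fit`, `recover`
#' and `bf`; see `inst/cli/ezbhddm` for the executable wrapper.  Every
#' run writes a provenance record (resolved configuration, seed, package
#' version) beside its outputs.  Errors are reported on stderr and turn
#' into a non-zero exit status rather than an R traceback.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly: 0 on success, 1 on usage or
#'   runtime error.
#' @export
ez_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      !(args[1] %in% c("simulate", "summarize", "fit", "recover", "bf"))) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- args[1]
  status <- tryCatch({
    opts <- parse_cli_args(args[-1])
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else
      list()
    seed <- as.integer(
      if (!is.null(opts$seed)) opts$seed
      else if (!is.null(cfg$seed)) cfg$seed else 1L)
    if (is.null(opts$out)) stop("--out is required")
    out_dir <- opts$out
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

    if (sub == "simulate") {
      m <- cfg$model
      d <- cfg$design
      design <- design_spec(
        P = if (!is.null(d$P)) d$P else 20L,
        T_trials = if (!is.null(d$T_trials)) d$T_trials else 40L,
        design = if (!is.null(d$design)) d$design else "regression",
        criterion = if (!is.null(m$criterion)) m$criterion else "drift")
      pop_args <- cfg$population
      pop <- if (is.null(pop_args)) population_params() else
        do.call(population_params, pop_args)
      dt <- if (!is.null(cfg$dt)) cfg$dt else 1e-4
      sim <- simulate_hierarchical(design, pop, seed = seed, dt = dt)
      write_sim(sim, out_dir)
    } else if (sub == "summarize") {
      if (is.null(opts$trials)) stop("--trials is required")
      trials <- read_trials(opts$trials)
      stats <- summarize_trials(trials)
      write.csv(stats, file.path(out_dir, "summaries.csv"),
                row.names = FALSE)
    } else if (sub %in% c("fit", "bf")) {
      stats <- cli_read_stats(opts)
      cov <- if (!is.null(opts$covariate)) opts$covariate
        else cfg$model$covariate
      if (!is.null(cov)) {
        if (!(cov %in% names(stats))) {
          stop("covariate column not found: ", cov)
        }
        names(stats)[names(stats) == cov] <- "x"
      }
      criterion <- if (!is.null(opts$criterion)) opts$criterion
        else if (!is.null(cfg$model$criterion)) cfg$model$criterion
        else "drift"
      fit <- fit_ezbhddm(stats, criterion,
                         cfg = cli_sampler_config(cfg, seed))
      write_fit(fit, out_dir)
      if (sub == "bf") {
        bf <- savage_dickey(fit)
        jsonlite::write_json(unclass(bf),
                             file.path(out_dir, "bayes_factor.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    } else if (sub == "recover") {
      st <- cfg$study
      cell <- run_recovery_cell(
        criterion = if (!is.null(st$criterion)) st$criterion else "drift",
        design = if (!is.null(st$design)) st$design else "regression",
        P = if (!is.null(st$P)) st$P else 20L,
        T_trials = if (!is.null(st$T_trials)) st$T_trials else 40L,
        beta_true = if (!is.null(st$beta_true)) st$beta_true else 0.5,
        reps = if (!is.null(st$reps)) st$reps else 10L,
        base_seed = seed,
        cfg = cli_sampler_config(cfg, seed))
      write.csv(cell$replicates, file.path(out_dir, "recovery.csv"),
                row.names = FALSE)
      jsonlite::write_json(cell$summary,
                           file.path(out_dir, "recovery_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    prov <- list(subcommand = sub, seed = seed, config = cfg,
                 package_version = as.character(packageVersion("ezbhddm")))
    jsonlite::write_json(prov, file.path(out_dir, "run_provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_read_stats <- function(opts) {
  if (!is.null(opts$summaries)) {
    read_summaries(opts$summaries)
  } else if (!is.null(opts$trials)) {
    summarize_trials(read_trials(opts$trials))
  } else {
    stop("need --trials or --summaries")
  }
}
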