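test_that("every simulated response time exceeds the nondecision time", {
  tr <- simulate_trials(2000, 0.8, 1.2, 0.25, dt = 1e-3, seed = 42)
  expect_equal(nrow(tr), 2000)
  expect_true(all(tr$rt > 0.25))
  expect_true(all(tr$accuracy %in% c(0, 1)))
})

test_that("zero drift yields chance accuracy from the midpoint start", {
  tr <- simulate_trials(40000, 0, 1, 0.2, dt = 1e-3, seed = 7)
  se <- sqrt(0.25 / 40000)
  expect_lt(abs(mean(tr$accuracy) - 0.5), 3 * se)
})

test_that("the simulator is deterministic under a fixed seed", {
  a <- simulate_trials(200, 1, 1, 0.3, dt = 1e-3, seed = 99)
  b <- simulate_trials(200, 1, 1, 0.3, dt = 1e-3, seed = 99)
  expect_identical(a, b)
})

test_that("invalid simulation requests are rejected", {
  expect_error(simulate_trials(0, 1, 1, 0.3), "at least 1")
  expect_error(simulate_trials(10, 1, 1, 0.3, dt = 0), "dt")
  expect_error(simulate_trials(10, 1, -1, 0.3), "boundary")
  expect_error(simulate_trials(10, Inf, 1, 0.3), "finite")
  expect_error(simulate_trials(10, 1, 1, -0.1), "nondecision")
})

test_that("halving the time step barely moves the large-sample moments", {
  n <- 30000
  t1 <- simulate_trials(n, 1, 1, 0.3, dt = 2e-3, seed = 11)
  t2 <- simulate_trials(n, 1, 1, 0.3, dt = 1e-3, seed = 12)
  se_acc <- sqrt(2 * 0.73 * 0.27 / n)
  se_m <- sqrt(2 * 0.0344 / (0.73 * n))
  # documented residual discretization allowance after the continuity
  # correction: O(dt) in each statistic, bounded by 0.004 here
  expect_lt(abs(mean(t1$accuracy) - mean(t2$accuracy)), 3 * se_acc + 0.004)
  expect_lt(abs(mean(t1$rt[t1$accuracy == 1]) -
                  mean(t2$rt[t2$accuracy == 1])), 3 * se_m + 0.004)
})

test_that("design and population constructors validate their inputs", {
  d <- design_spec(10, 40, "regression", "drift")
  expect_equal(length(d$x), 10)
  expect_true(all(d$x >= 0 & d$x <= 1))
  expect_equal(design_spec(6, 20, "ttest_between", "drift")$x,
               c(0, 0, 0, 1, 1, 1))
  expect_equal(design_spec(6, 20, "ttest_within", "ndt")$x, c(0, 1))
  expect_error(design_spec(10, 1, "regression", "drift"), "at least 2")
  expect_error(design_spec(10, 40, "regression", "drift", x = c(0, 1)),
               "length")
  expect_error(design_spec(4, 40, "ttest_between", "drift",
                           x = c(0, 1, 2, 1)), "binary")
  expect_error(population_params(sd_drift = 0), "standard deviations")
  expect_error(population_params(mu_bound = -1), "mu_bound")
})

test_that("hierarchical criterion draws are exchangeable when beta is 0", {
  sim <- simulate_hierarchical(
    design_spec(200, 4, "ttest_between", "drift"),
    population_params(beta = 0), seed = 3, dt = 5e-3)
  v <- sim$truth$drift
  x <- sim$truth$x
  diff <- mean(v[x == 1]) - mean(v[x == 0])
  se <- 0.5 * sqrt(1 / sum(x == 1) + 1 / sum(x == 0))
  expect_lt(abs(diff), 3 * se)
})

test_that("degenerate parent SDs collapse individuals onto the means", {
  sim <- simulate_hierarchical(
    design_spec(12, 4, "regression", "drift"),
    population_params(sd_drift = 1e-6, sd_bound = 1e-6, sd_ndt = 1e-6,
                      beta = 0),
    seed = 4, dt = 5e-3)
  expect_lt(max(abs(sim$truth$drift - 1)), 1e-4)
  expect_lt(max(abs(sim$truth$boundary - 1.5)), 1e-4)
  expect_lt(max(abs(sim$truth$ndt - 0.4)), 1e-4)
})

test_that("a between-groups drift shift matches the generating weight", {
  sim <- simulate_hierarchical(
    design_spec(320, 4, "ttest_between", "drift"),
    population_params(beta = 0.5), seed = 5, dt = 5e-3)
  v <- sim$truth$drift
  x <- sim$truth$x
  diff <- mean(v[x == 1]) - mean(v[x == 0])
  se <- 0.5 * sqrt(1 / 160 + 1 / 160)
  expect_lt(abs(diff - 0.5), 3 * se)
})

test_that("within-subject designs give one criterion draw per condition", {
  sim <- simulate_hierarchical(
    design_spec(15, 10, "ttest_within", "drift"),
    population_params(beta = 1), seed = 6, dt = 2e-3)
  expect_equal(nrow(sim$stats), 30)
  expect_equal(sort(unique(sim$stats$condition)), c(1, 2))
  # non-criterion parameters shared within participant
  b <- tapply(sim$truth$boundary, sim$truth$participant,
              function(z) diff(range(z)))
  expect_true(all(b == 0))
})

test_that("simulated datasets round-trip through the plain-text writers", {
  sim <- simulate_hierarchical(
    design_spec(5, 10, "regression", "drift"),
    population_params(), seed = 8, dt = 2e-3)
  dir <- tempfile("simout")
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["trials"]])
  expect_equal(nrow(back), 50)
  expect_equal(back$rt, sim$trials$rt)
  meta <- jsonlite::read_json(paths[["meta"]])
  expect_equal(meta$seed, 8)
  stats_back <- read_summaries(paths[["summaries"]])
  expect_equal(stats_back$n_correct, sim$stats$n_correct)
})
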