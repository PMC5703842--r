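test_that("unit filtering keeps rates in [5, 100] spikes/s, bounds inclusive", {
  dur <- 100
  sp <- data.frame(
    unit_id = rep(c("slow", "edge_lo", "mid", "edge_hi", "fast"),
                  c(490, 500, 2000, 10000, 15000)),
    timestamp_s = runif(27990, 0, dur)
  )
  kept <- unique(filter_units(sp, dur)$unit_id)
  expect_setequal(kept, c("edge_lo", "mid", "edge_hi"))
  expect_error(filter_units(sp, 0), "positive")
})

test_that("the design matrix encodes task epochs and elapsed time", {
  cfg <- task_config(n_trials = 2, iti_s = 2, outcome_dur_s = 1)
  # one banked red trial and one popped orange trial, controlled times
  tr <- make_trials(
    type = c("free", "free"), risk = c("red", "orange"),
    t_start = c(0.975, 12), t_stop = c(6, NA), t_pop = c(8, 4),
    outcome = c("banked", "popped"), points = c(180, 0), config = cfg
  )
  d <- build_design(tr, bin_s = 0.05, t_end_s = 20)
  X <- d$X

  # a bin centered mid-ITI carries no task information
  i_iti <- which.min(abs(d$centers - 10))
  expect_true(all(X[i_iti, ] == 0))

  # bin centered exactly 5 s into trial 1: elapsed-time column = log 6
  i5 <- which(abs(d$centers - (0.975 + 5)) < 1e-9)
  expect_equal(unname(X[i5, "elapsed_log"]), log(6))
  expect_equal(unname(X[i5, c("trial", "inflation", "risk_high")]),
               c(1, 1, 1))

  # inflation and outcome periods never overlap
  expect_true(all(X[, "inflation"] + X[, "outcome"] <= 1))
  # trial indicator covers exactly inflation plus outcome
  expect_equal(X[, "trial"], pmax(X[, "inflation"], X[, "outcome"]))
  # popped trial flags the no-points outcome during its outcome epoch
  i_out2 <- which(d$centers > 16 & d$centers < 17)
  expect_true(all(X[i_out2, "outcome_nopoints"] == 1))
  expect_true(all(X[i_out2, "risk_medium"] == 1))
  # elapsed time is zero outside trials
  expect_true(all(X[X[, "trial"] == 0, "elapsed_log"] == 0))
})

test_that("overlapping trials are rejected", {
  cfg <- task_config(n_trials = 2)
  tr <- make_trials(
    type = c("free", "free"), risk = c("red", "red"),
    t_start = c(1, 3), t_stop = c(5, 5), t_pop = c(9, 9),
    outcome = c("banked", "banked"), points = c(150, 150), config = cfg
  )
  expect_error(build_design(tr), "overlap")
})

test_that("intercept-only and degenerate fits use closed forms", {
  cfg <- task_config(n_trials = 3, seed = 2)
  tr <- simulate_agent_stops(generate_trials(cfg), default_policy(cfg), cfg)
  d <- build_design(tr, bin_s = 0.05)

  # constant-rate unit: the Poisson MLE of the baseline is the mean rate
  set.seed(11)
  n <- nrow(d$X)
  counts <- rpois(n, 10 * 0.05)
  d0 <- d
  d0$X[] <- 0   # all columns constant -> dropped -> intercept only
  fit <- suppressWarnings(fit_poisson_glm(d0, counts, seed = 1))
  expect_equal(fit$f0_hz, mean(counts) / 0.05)
  expect_equal(fit$nonzero, character(0))

  # all-zero counts: coefficients zero, baseline floored, no -Inf
  # (a short session can leave a risk level unused, hence the constant
  # column warning)
  fit0 <- suppressWarnings(fit_poisson_glm(d, integer(n), seed = 1))
  expect_true(is.finite(fit0$beta0))
  expect_true(all(fit0$beta == 0))

  expect_error(fit_poisson_glm(d, counts[-1], seed = 1), "aligned")
  expect_error(fit_poisson_glm(d, counts + 0.5, seed = 1), "integer")
})

test_that("regularized fit recovers a known trial gain and the 1-SE rule is more parsimonious", {
  cfg <- task_config(n_trials = 150, seed = 7)
  tr <- simulate_agent_stops(generate_trials(cfg), default_policy(cfg), cfg)
  params <- neural_gen_params(
    glm_truth = list(beta0 = log(10), beta = c(trial = log(1.5)),
                     gamma = 0.3)
  )
  sp <- simulate_spikes(tr, params, seed = 11)
  d <- attr(sp, "design")
  counts <- bin_spikes(sp$timestamp_s, session_end(tr), 0.05)

  fit_min <- fit_poisson_glm(d, counts, rule = "min", mixing_grid = 0.5,
                             seed = 1)
  expect_equal(exp(fit_min$beta[["trial"]]), 1.5, tolerance = 0.12)
  expect_equal(fit_min$gamma, 0.3, tolerance = 0.12)
  expect_equal(fit_min$f0_hz, 10, tolerance = 0.1)

  fit_1se <- fit_poisson_glm(d, counts, rule = "1se", mixing_grid = 0.5,
                             seed = 1)
  expect_gte(fit_1se$lambda, fit_min$lambda)
  fit_none <- fit_poisson_glm(d, counts, rule = "none", mixing_grid = 0.5,
                              seed = 1)
  expect_lte(fit_none$lambda, fit_min$lambda)
})

test_that("effect sizes transform coefficients to percent change", {
  fit <- structure(
    list(beta0 = log(10),
         beta = c(trial = 0, outcome = log(2), elapsed_log = 0.1),
         gamma = 0.1, f0_hz = 10, bin_s = 0.05),
    class = "glm_fit"
  )
  es <- effect_sizes(fit, representative_elapsed_s = 5)
  expect_equal(es$percent_change[es$regressor == "trial"], 0)
  expect_false(es$present[es$regressor == "trial"])
  expect_equal(es$percent_change[es$regressor == "outcome"], 100)
  # time effect: (6^0.1 - 1) * 100 ~ 19.6%
  expect_equal(es$percent_change[es$regressor == "elapsed_log"],
               (6^0.1 - 1) * 100)
  expect_equal((6^0.1 - 1) * 100, 19.62, tolerance = 1e-3)
})

test_that("shuffling the bins destroys task effects", {
  cfg <- task_config(n_trials = 60, seed = 13)
  tr <- simulate_agent_stops(generate_trials(cfg), default_policy(cfg), cfg)
  params <- neural_gen_params(
    glm_truth = list(beta0 = log(12), beta = c(trial = log(1.6)),
                     gamma = 0.3)
  )
  sp <- simulate_spikes(tr, params, seed = 3)
  d <- attr(sp, "design")
  counts <- bin_spikes(sp$timestamp_s, session_end(tr), 0.05)
  sh <- shuffle_control(d, counts, seed = 5, reps = 2, mixing_grid = 0.5)
  expect_equal(sum(sh$nonzero), 0)
  expect_identical(sort(unique(sh$rep)), 1:2)
})
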