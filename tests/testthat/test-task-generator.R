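test_that("pop times follow the configured truncated-normal distributions", {
  cfg <- task_config(
    risk_levels = data.frame(label = "red", mean_pop_s = 3, sd_pop_s = 0.9,
                             risk = "high"),
    n_trials = 10000, frac_forced = 0, include_gray = FALSE, seed = 42
  )
  tr <- generate_trials(cfg)
  # Monte-Carlo error of the mean is sd/sqrt(n) ~ 0.009 s
  expect_equal(mean(tr$t_pop_s), 3, tolerance = 0.02)
  expect_equal(sd(tr$t_pop_s), 0.9, tolerance = 0.03)
  expect_true(all(tr$t_pop_s > 0))
})

test_that("vanishing pop-time spread collapses onto the mean", {
  cfg <- task_config(
    risk_levels = data.frame(label = "red", mean_pop_s = 3,
                             sd_pop_s = 1e-12, risk = "high"),
    n_trials = 50, frac_forced = 0, include_gray = FALSE, seed = 1
  )
  tr <- generate_trials(cfg)
  expect_equal(tr$t_pop_s, rep(3, 50), tolerance = 1e-9)
})

test_that("control-type quotas are exact and errors are raised early", {
  cfg <- task_config(n_trials = 1000, frac_forced = 0.25,
                     include_gray = FALSE, seed = 7)
  tr <- generate_trials(cfg)
  expect_identical(sum(tr$type == "forced"), 250L)
  expect_identical(sum(tr$type == "free"), 750L)

  cfg2 <- task_config(n_trials = 200, frac_forced = 0.25,
                      include_gray = TRUE, frac_gray = 0.1, seed = 7)
  tr2 <- generate_trials(cfg2)
  expect_identical(sum(tr2$type == "forced"), 50L)
  expect_identical(sum(tr2$type == "gray"), 20L)
  expect_true(all(tr2$risk[tr2$type == "gray"] == "gray"))

  expect_error(task_config(n_trials = 0), "n_trials")
  expect_error(task_config(gray_ring_source = "violet"), "violet")
})

test_that("stop outcomes follow the banked/popped point rules", {
  cfg <- task_config(n_trials = 2, frac_forced = 0, include_gray = FALSE)
  tr <- make_trials(
    type = c("free", "free"), risk = c("red", "red"),
    t_start = c(2, 10), t_stop = NA_real_, t_pop = c(3, 3),
    outcome = NA_character_, points = NA_real_, config = cfg
  )
  pol2 <- agent_policy(c(red = 2), c(red = 0), jitter_s = 0)
  out <- simulate_agent_stops(tr, pol2, cfg)
  expect_equal(out$outcome, c("banked", "banked"))
  expect_equal(out$points, c(60, 60))   # 30 points/s x 2 s

  pol4 <- agent_policy(c(red = 4), c(red = 0), jitter_s = 0)
  out <- simulate_agent_stops(tr, pol4, cfg)
  expect_equal(out$outcome, c("popped", "popped"))
  expect_equal(out$points, c(0, 0))
})

test_that("banked points always equal rate x stop time; pops earn nothing", {
  cfg <- task_config(n_trials = 400, seed = 3)
  tr <- simulate_agent_stops(generate_trials(cfg), default_policy(cfg), cfg)
  banked <- tr$outcome == "banked" & tr$type == "free"
  expect_equal(tr$points[banked], 30 * tr$t_stop_s[banked])
  expect_equal(tr$points[tr$outcome == "popped"],
               rep(0, sum(tr$outcome == "popped")))
  expect_equal(tr$points[tr$type == "gray"],
               rep(0, sum(tr$type == "gray")))
  expect_equal(tr$points[tr$type == "forced"],
               30 * tr$t_ring_s[tr$type == "forced"])
})

test_that("a very conservative policy almost never pops", {
  cfg <- task_config(n_trials = 2000, frac_forced = 0,
                     include_gray = FALSE, seed = 9)
  pol <- agent_policy(
    c(red = 0.5, orange = 0.5, yellow = 0.5),
    c(red = 0.05, orange = 0.05, yellow = 0.05), jitter_s = 0
  )
  tr <- simulate_agent_stops(generate_trials(cfg), pol, cfg)
  # pop requires pop time < stop ~ 0.5 s; for red this has probability
  # pnorm(0.5, 3, 0.9) ~ 0.003 (larger than for other colours)
  expect_lt(mean(tr$outcome == "popped"), 0.01)
})

test_that("trial start times are consistent with realized durations", {
  cfg <- task_config(n_trials = 50, seed = 21)
  tr <- simulate_agent_stops(generate_trials(cfg), default_policy(cfg), cfg)
  dur <- trial_duration(tr) + cfg$outcome_dur_s
  expect_equal(diff(tr$t_start_s), dur[-50] + cfg$iti_s)
  expect_equal(tr$t_start_s[1], cfg$iti_s)
})

test_that("simulated spikes follow the generative Poisson model", {
  cfg <- task_config(n_trials = 60, seed = 5)
  tr <- simulate_agent_stops(generate_trials(cfg), default_policy(cfg), cfg)

  # constant rate: beta = 0, gamma = 0, baseline 10 spikes/s
  params <- neural_gen_params(glm_truth = list(beta0 = log(10), beta = NULL,
                                               gamma = 0))
  sp <- simulate_spikes(tr, params, seed = 2)
  t_end <- session_end(tr)
  rate <- nrow(sp) / t_end
  expect_equal(rate, 10, tolerance = 0.05)

  # low-rate per-bin mean: 0.5 spikes/s at 50 ms bins -> 0.025 per bin
  params_lo <- neural_gen_params(glm_truth = list(beta0 = log(0.5),
                                                  beta = NULL, gamma = 0))
  sp_lo <- simulate_spikes(tr, params_lo, seed = 3)
  counts <- bin_spikes(sp_lo$timestamp_s, t_end, 0.05)
  expect_equal(mean(counts$counts), 0.025, tolerance = 0.2)

  # positive time exponent: late-trial bins fire more than early bins
  params_g <- neural_gen_params(glm_truth = list(beta0 = log(10),
                                                 beta = NULL, gamma = 0.5))
  sp_g <- simulate_spikes(tr, params_g, seed = 4)
  design <- attr(sp_g, "design")
  cg <- bin_spikes(sp_g$timestamp_s, t_end, 0.05)$counts
  el <- design$X[, "elapsed_log"]
  early <- el > 0 & el < log(2)      # first second of each trial
  late <- el > log(4)                # beyond 3 s elapsed
  expect_gt(mean(cg[late]), mean(cg[early]))

  # rate overflow is an error, not a silent clip
  params_bad <- neural_gen_params(glm_truth = list(beta0 = log(1e6),
                                                   beta = NULL, gamma = 0))
  expect_error(simulate_spikes(tr, params_bad, seed = 5), "exceeds")
})

test_that("hazard-generated stop times are insensitive to halving dt", {
  rl <- data.frame(label = "red", mean_pop_s = 3, sd_pop_s = 0.9,
                   risk = "high")
  cfg <- task_config(risk_levels = rl, n_trials = 1500, frac_forced = 0,
                     include_gray = FALSE, seed = 31)
  truth <- list(m = c(red = 3), s = c(red = 0.9), mu = 0)
  tr1 <- generate_trials(cfg); tr1$t_pop_s <- 1e6
  tr2 <- tr1
  a <- simulate_hazard_stops(tr1, truth, fs_hz = 40, seed = 8)
  b <- simulate_hazard_stops(tr2, truth, fs_hz = 80, seed = 8)
  ks <- suppressWarnings(
    stats::ks.test(a$t_stop_s[a$outcome == "banked"],
                   b$t_stop_s[b$outcome == "banked"])
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("per-stage seed derivation is deterministic and distinct", {
  expect_identical(derive_seed(1L, "trials"), derive_seed(1L, "trials"))
  expect_false(derive_seed(1L, "trials") == derive_seed(1L, "agent"))
  expect_false(derive_seed(1L, "trials") == derive_seed(2L, "trials"))
  expect_true(derive_seed(2147483000L, "x") >= 0)
})
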