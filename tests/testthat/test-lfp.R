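fs <- 1000
tt <- seq(1 / fs, 20, by = 1 / fs)

test_that("common-average referencing removes shared signal exactly", {
  x <- sin(2 * pi * 6 * tt)
  artifact <- 5 * sin(2 * pi * 1 * tt) + 3
  rec <- make_rec(cbind(x + artifact, -x + artifact, artifact), fs)
  ref <- common_average_reference(rec)
  expect_equal(max(abs(rowMeans(ref$signals))), 0)
  # channels x and -x already have zero mean: unchanged by CAR
  rec2 <- make_rec(cbind(x, -x), fs)
  ref2 <- common_average_reference(rec2)
  expect_equal(ref2$signals, rec2$signals)
  # single channel: degenerate, zeroed with a warning
  expect_warning(ref1 <- common_average_reference(make_rec(cbind(x), fs)),
                 "single channel")
  expect_equal(max(abs(ref1$signals)), 0)
})

test_that("Hilbert band power recovers squared amplitude of in-band tones", {
  x <- sin(2 * pi * 6 * tt)
  rec <- make_rec(cbind(x, 2 * x), fs)
  bands <- lfp_bands()
  bp <- band_power(rec, bands[bands$name == "theta", ])
  interior <- 400:(nrow(bp$power) - 400)
  expect_equal(mean(bp$power[interior, 1]), 1, tolerance = 0.02)
  # doubling the amplitude quadruples the power
  expect_equal(mean(bp$power[interior, 2]), 4, tolerance = 0.02)
  expect_true(all(bp$power >= 0))
  # out-of-band rejection
  bp_beta <- band_power(rec, bands[bands$name == "beta", ])
  expect_lt(mean(bp_beta$power[interior, 1]), 1e-4)
  # band above Nyquist is an error
  rec_slow <- make_rec(cbind(x[1:2000]), 100)
  expect_error(band_power(rec_slow, bands[bands$name == "gamma", ]),
               "Nyquist")
})

test_that("artifact detection flags railing and power bursts with a guard", {
  x <- sin(2 * pi * 6 * tt)
  rec <- make_rec(cbind(x), fs)
  expect_false(any(detect_artifacts(rec)))

  # 1 s saturation plateau
  x_sat <- x
  x_sat[5001:6000] <- 1.002
  m <- detect_artifacts(make_rec(cbind(x_sat), fs), guard_s = 0.1)
  expect_true(all(m[5001:6000, 1]))
  expect_true(all(m[4950:5000, 1]))    # guard before
  expect_true(all(m[6001:6050, 1]))    # guard after
  expect_false(any(m[1:4000, 1]))

  # 20x amplitude burst caught by the power rule
  x_burst <- x
  x_burst[10001:10400] <- 20 * x[10001:10400]
  m2 <- detect_artifacts(make_rec(cbind(x_burst), fs))
  expect_true(all(m2[10050:10350, 1]))
  expect_false(any(m2[1:9000, 1]))
})

test_that("peri-event traces are flat at z ~ 0 for stationary power", {
  set.seed(4)
  pw <- exp(rnorm(8000, 0, 0.2))
  bp <- make_bps(cbind(pw), fs = 200)
  events <- seq(3, 37, by = 2)
  tr <- peri_event_trace(bp, events, window = c(-1, 1))
  # median of 18 z-scored events: sd ~ 1.25 / sqrt(18) ~ 0.3
  expect_lt(max(abs(tr$trace), na.rm = TRUE), 1.2)
  expect_lt(abs(mean(tr$trace, na.rm = TRUE)), 0.2)
  expect_true(all(tr$n_events == length(events)))

  # single event: the trace is that event's z-scored log power
  tr1 <- peri_event_trace(bp, events[1], window = c(-1, 1))
  z <- (log(pw) - mean(log(pw))) / sd(log(pw))
  idx <- round(events[1] * 200) + 1 + seq(-200, 200)
  expect_equal(unname(tr1$trace[, 1]), z[idx])
})

test_that("masked samples are excluded from peri-event statistics", {
  pw <- matrix(1, 2000, 1)
  bp <- make_bps(pw, fs = 200)
  bp$mask[1001:1200, 1] <- TRUE
  bp$power[1001:1200, 1] <- 1e6   # masked artifact must not leak through
  tr <- peri_event_trace(bp, c(3, 5.5), window = c(-0.5, 0.5),
                         min_events = 2)
  # time points where the masked event contributes fewer than 2 events
  expect_true(anyNA(tr$trace))
  expect_true(all(tr$n_events <= 2))
})

test_that("a simulated pre-stop theta ramp is recovered in the trace", {
  cfg <- task_config(n_trials = 60, frac_forced = 0, include_gray = FALSE,
                     seed = 19)
  tr <- simulate_agent_stops(generate_trials(cfg), default_policy(cfg), cfg)
  params <- neural_gen_params(
    lfp_bands = data.frame(name = "theta", center_hz = 6, baseline_amp = 1,
                           ramp_gain = 2, ramp_onset_s = 2),
    noise_amp = 0.5, n_channels = 2, fs_hz = 400
  )
  rec <- simulate_lfp(tr, params, seed = 23)
  bands <- lfp_bands()
  bp <- band_power(rec, bands[bands$name == "theta", ])
  stops <- tr$t_start_s + tr$t_stop_s
  stops <- stops[tr$outcome == "banked"]
  trc <- peri_event_trace(bp, stops, window = c(-2, 0),
                          average_channels = TRUE)
  fitlm <- lm(trc$trace ~ trc$time_s)
  expect_gt(coef(fitlm)[2], 0)
  expect_lt(summary(fitlm)$coefficients[2, 4], 0.05)

  # with no ramp the pre-stop slope is null
  params0 <- params
  params0$lfp_bands$ramp_gain <- 1
  rec0 <- simulate_lfp(tr, params0, seed = 23)
  bp0 <- band_power(rec0, bands[bands$name == "theta", ])
  trc0 <- peri_event_trace(bp0, stops, window = c(-2, 0),
                           average_channels = TRUE)
  expect_lt(abs(coef(lm(trc0$trace ~ trc0$time_s))[2]),
            abs(coef(fitlm)[2]) / 2)
})

test_that("z-scored channel averaging weights channels equally; raw averaging does not", {
  # three channels: two weak channels with a positive power modulation
  # after the event, one very high-power channel with a negative one.
  # Averaging z-scored log traces follows the channel majority (positive
  # contrast); averaging raw power is dominated by the strong channel and
  # flips the sign.
  set.seed(123)
  n <- 8000
  mod <- rep(0, n); mod[2201:2400] <- 1   # 11.0-12.0 s at 200 Hz
  mk <- function(gain, scale) {
    scale * exp(gain * mod + rnorm(n, 0, 0.05))
  }
  bp <- make_bps(cbind(mk(0.5, 1), mk(0.5, 1), mk(-0.5, 1e4)), fs = 200)
  ev <- 11
  zavg <- peri_event_trace(bp, ev, window = c(-1, 1),
                           average_channels = TRUE, zscore = TRUE)
  raw <- peri_event_trace(bp, ev, window = c(-1, 1),
                          average_channels = TRUE, zscore = FALSE)
  inwin <- zavg$time_s > 0.05 & zavg$time_s < 0.95
  prewin <- zavg$time_s < -0.05
  z_effect <- mean(zavg$trace[inwin]) - mean(zavg$trace[prewin])
  raw_effect <- mean(raw$trace[inwin]) - mean(raw$trace[prewin])
  expect_gt(z_effect, 0)    # equal weighting: the majority wins
  expect_lt(raw_effect, 0)  # power-scale average: the loud channel wins
  # per-channel z traces carry the opposing modulations
  zch <- peri_event_trace(bp, ev, window = c(-1, 1), zscore = TRUE)
  eff <- colMeans(zch$trace[inwin, ]) - colMeans(zch$trace[prewin, ])
  expect_gt(eff[1], 0)
  expect_lt(eff[3], 0)
})

test_that("the wavelet transform concentrates power at the tone frequency", {
  x <- sin(2 * pi * 10 * tt[1:4000])
  tf <- wavelet_tfr(x, fs, tfr_freqs(40))
  interior <- 1000:3000
  ridge <- tf$freqs[apply(tf$power[, interior], 2, which.max)]
  expect_true(all(ridge == tf$freqs[which.min(abs(tf$freqs - 10))]))

  # two tones give two ridges
  x2 <- sin(2 * pi * 5 * tt[1:4000]) + sin(2 * pi * 40 * tt[1:4000])
  tf2 <- wavelet_tfr(x2, fs, tfr_freqs(40))
  pk <- rowMeans(tf2$power[, interior])
  local_max <- which(diff(sign(diff(pk))) == -2) + 1
  f_max <- tf2$freqs[local_max]
  expect_true(any(abs(f_max - 5) < 1))
  expect_true(any(abs(f_max - 40) < 5))
  expect_error(wavelet_tfr(x, 80, tfr_freqs(40)), "Nyquist")
})

test_that("white-noise wavelet power is flat across log-spaced frequencies", {
  set.seed(9)
  mean_pw <- rowMeans(vapply(1:30, function(i) {
    x <- rnorm(3000)
    tf <- wavelet_tfr(x, 200, tfr_freqs(15))
    rowMeans(tf$power[, 800:2200])
  }, numeric(15)))
  # unit-energy wavelets: expected power equals the (flat) noise spectral
  # density at every frequency
  expect_lt(max(mean_pw) / min(mean_pw), 1.25)
})

test_that("decibel normalization and contrasts satisfy their identities", {
  pw <- matrix(2, 10, 60)
  m <- make_tfr(pw, times = seq(-2, 0.95, by = 0.05))
  # P = P0 everywhere -> exactly 0 dB
  expect_equal(normalize_db(m)$power, matrix(0, 10, 60))
  m10 <- m; m10$power <- 10 * pw
  expect_equal(normalize_db(m10, p0 = rowMeans(pw))$power,
               matrix(10, 10, 60))
  mhalf <- m; mhalf$power <- pw / 2
  expect_equal(normalize_db(mhalf, p0 = rowMeans(pw))$power[1, 1],
               10 * log10(0.5), tolerance = 1e-12)

  # shared baseline across a list of trials
  maps <- list(m, m10)
  nd <- normalize_db(maps, baseline = c(-1.5, -0.5))
  p0 <- attr(nd[[1]], "p0")
  expect_equal(p0, rowMeans((pw + 10 * pw) / 2))
  expect_equal(nd[[2]]$power - nd[[1]]$power, matrix(10, 10, 60))

  # contrast identities: zero for identical conditions, antisymmetric
  a <- make_tfr(matrix(4, 10, 60)); b <- make_tfr(matrix(2, 10, 60))
  expect_equal(contrast_db(a, a)$power, matrix(0, 10, 60))
  expect_equal(contrast_db(a, b)$power, -contrast_db(b, a)$power)
  expect_equal(contrast_db(a, b)$power[1, 1], 10 * log10(2))
})

test_that("peri-event maps share a grid and average correctly", {
  x <- sin(2 * pi * 10 * tt[1:6000])
  maps <- peri_event_tfr(x, fs, events = c(2, 3, 4), window = c(-0.5, 0.5),
                         freqs = tfr_freqs(10))
  expect_length(maps, 3)
  expect_equal(maps[[1]]$times, maps[[2]]$times)
  avg <- tfr_mean(maps)
  expect_equal(avg$power,
               (maps[[1]]$power + maps[[2]]$power + maps[[3]]$power) / 3)
  # events too close to the edge are dropped
  maps2 <- peri_event_tfr(x, fs, events = c(0.1, 3), window = c(-0.5, 0.5),
                          freqs = tfr_freqs(10))
  expect_length(maps2, 1)
})
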