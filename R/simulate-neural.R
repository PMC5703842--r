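#' Simulate spike trains from the task Poisson model
#'
#' Generates spikes from the same model that [fit_poisson_glm()] fits:
#' per 50 ms bin, `log f = beta0 + beta X + gamma log(t - t0 + 1)` with
#' `f` in spikes/s, and Poisson counts with mean `f * bin_s`. Timestamps
#' are placed uniformly within their bins so that re-binning recovers the
#' drawn counts exactly.
#'
#' @param trials a completed `trial_table`.
#' @param params a [neural_gen_params()]; `glm_truth$beta` is a named
#'   vector matching columns of [build_design()] (missing names mean 0).
#' @param bin_s bin width in seconds.
#' @param seed RNG seed.
#' @param n_units number of i.i.d. units to draw.
#' @param max_rate_hz guard: an error is raised (not silently clipped) if
#'   the model rate exceeds this anywhere.
#' @return data.frame with columns `unit_id`, `timestamp_s`; the
#'   underlying `glm_design` is attached as attribute `"design"`.
#' @export
simulate_spikes <- function(trials, params, bin_s = 0.05, seed = 1L,
                            n_units = 1L, max_rate_hz = 1e4) {
  stopifnot(inherits(params, "neural_gen_params"))
  design <- build_design(trials, bin_s = bin_s)
  tr <- params$glm_truth
  logf <- rep(tr$beta0, nrow(design$X))
  if (!is.null(tr$beta) && length(tr$beta)) {
    miss <- setdiff(names(tr$beta), colnames(design$X))
    if (length(miss)) stop("unknown design columns in glm_truth$beta: ",
                           paste(miss, collapse = ", "))
    logf <- logf + design$X[, names(tr$beta), drop = FALSE] %*% tr$beta
  }
  if (!is.null(tr$gamma) && tr$gamma != 0) {
    logf <- logf + tr$gamma * design$X[, "elapsed_log"]
  }
  if (any(logf > log(max_rate_hz))) {
    stop("simulated firing rate exceeds ", max_rate_hz,
         " spikes/s; check glm_truth")
  }
  mu <- exp(as.numeric(logf)) * bin_s

  set.seed(derive_seed(seed, "spikes"))
  events <- lapply(seq_len(n_units), function(u) {
    counts <- stats::rpois(length(mu), mu)
    nz <- which(counts > 0)
    ts <- rep(design$centers[nz] - bin_s / 2, counts[nz]) +
      stats::runif(sum(counts)) * bin_s
    data.frame(unit_id = sprintf("u%02d", u), timestamp_s = sort(ts))
  })
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

#' Synthesize 1/f background noise by spectral shaping
#' @noRd
pink_noise <- function(n, fs, amp, exponent = 1) {
  # FFT length padded to a highly composite size; mixed-radix FFTs on
  # near-prime lengths degrade to quadratic time
  m <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  freq <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  freq[freq > fs / 2] <- fs - freq[freq > fs / 2]   # fold to +/- Nyquist
  shape <- c(0, 1 / freq[-1]^(exponent / 2))        # kill DC
  x <- Re(stats::fft(spec * shape, inverse = TRUE))[seq_len(n)] / m
  amp * x / stats::sd(x)
}

#' Simulate a multichannel LFP recording for a session
#'
#' Each channel is 1/f background noise plus one sinusoid per configured
#' band. A band's instantaneous amplitude is its baseline except for a
#' linear ramp that starts `ramp_onset_s` before each voluntary stop and
#' reaches `ramp_gain` times baseline at the stop, emulating the
#' pre-decision power ramps the analyses are designed to detect. An
#' optional abrupt amplitude step follows balloon pops. Deterministic
#' given the seed.
#'
#' @param trials a completed `trial_table`.
#' @param params a [neural_gen_params()].
#' @param seed RNG seed.
#' @param common_artifact optional numeric vector (recycled/truncated to
#'   the session length) added identically to every channel, e.g. to test
#'   common-average referencing.
#' @return object of class `lfp_recording`: list with `signals` (samples
#'   x channels matrix), `fs_hz`, `channel_ids`, `t_s`.
#' @export
simulate_lfp <- function(trials, params, seed = 1L, common_artifact = NULL) {
  stopifnot(inherits(params, "neural_gen_params"))
  fs <- params$fs_hz
  if (any(params$lfp_bands$center_hz >= fs / 2)) {
    stop("band center frequency at or above Nyquist")
  }
  t_end <- session_end(trials)
  n <- ceiling(t_end * fs)
  t <- (seq_len(n) - 1) / fs

  stops <- trials$t_start_s + trials$t_stop_s
  stops <- stops[trials$type == "free" & trials$outcome == "banked"]
  pops <- trials$t_start_s + trials$t_pop_s
  pops <- pops[!is.na(trials$t_pop_s) & trials$outcome == "popped"]

  set.seed(derive_seed(seed, "lfp"))
  sig <- matrix(0, n, params$n_channels)
  for (ch in seq_len(params$n_channels)) {
    x <- pink_noise(n, fs, params$noise_amp, params$noise_exponent)
    for (b in seq_len(nrow(params$lfp_bands))) {
      band <- params$lfp_bands[b, ]
      env <- rep(band$baseline_amp, n)
      if (band$ramp_gain != 1) {
        for (s0 in stops) {
          idx <- which(t >= s0 - band$ramp_onset_s & t < s0)
          frac <- (t[idx] - (s0 - band$ramp_onset_s)) / band$ramp_onset_s
          env[idx] <- env[idx] * (1 + (band$ramp_gain - 1) * frac)
        }
      }
      if (params$pop_step_gain != 1) {
        for (p0 in pops) {
          idx <- which(t >= p0 & t < p0 + 0.5)
          env[idx] <- env[idx] * params$pop_step_gain
        }
      }
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + env * sin(2 * pi * band$center_hz * t + phase)
    }
    sig[, ch] <- x
  }
  if (!is.null(common_artifact)) {
    sig <- sig + rep_len(common_artifact, n)
  }
  structure(
    list(signals = sig, fs_hz = fs,
         channel_ids = sprintf("ch%02d", seq_len(params$n_channels)),
         t_s = t),
    class = "lfp_recording"
  )
}

#' Generate stop times from the discrete-time hazard model
#'
#' The generative inverse of [fit_hazard_model()]: within each trial,
#' time advances on a `fs_hz` grid and a voluntary stop is drawn per bin
#' as Bernoulli with probability `min(1, lambda_i(t) dt)`, where
#' `lambda_i(t) = h_i(t) exp(mu + X(t) . beta)` and `h_i` is the normal
#' hazard of the trial's risk level. The first event ends the trial; if
#' the hidden pop time arrives first the trial is recorded as popped
#' (censored).
#'
#' @param trials a `trial_table` (pop times drawn, outcomes may be
#'   unsimulated; any previous outcomes are overwritten for free trials).
#' @param truth list with named vectors `m`, `s` (per risk label), scalar
#'   `mu`, and optional `beta`.
#' @param regressors optional function `(trial_id, t_bins)` returning the
#'   regressor matrix (bins x length(beta)) for a trial; `NULL` means no
#'   neural modulation (beta = 0).
#' @param fs_hz hazard grid rate, default 40 Hz.
#' @param seed RNG seed.
#' @param max_horizon_s bail-out horizon per trial.
#' @param max_sat_frac abort if more than this fraction of bins saturate
#'   at `lambda dt > 1` (guidance: reduce the bin width).
#' @return the trial table with free-trial `t_stop_s`, `outcome`,
#'   `points` filled in from the hazard draws.
#' @export
simulate_hazard_stops <- function(trials, truth, regressors = NULL,
                                  fs_hz = 40, seed = 1L,
                                  max_horizon_s = 30,
                                  max_sat_frac = 0.01) {
  config <- attr(trials, "config")
  rate <- if (is.null(config)) 30 else config$reward_rate
  dt <- 1 / fs_hz
  set.seed(derive_seed(seed, "hazardstops"))

  n_sat <- 0L; n_bins <- 0L
  free <- which(trials$type == "free")
  for (i in free) {
    risk <- trials$risk[i]
    tb <- seq(dt / 2, max_horizon_s, by = dt)
    h <- normal_hazard(tb, truth$m[[risk]], truth$s[[risk]])
    eta <- truth$mu
    if (!is.null(regressors) && !is.null(truth$beta)) {
      X <- regressors(trials$trial_id[i], tb)
      eta <- eta + as.numeric(X %*% truth$beta)
    }
    p <- h * exp(eta) * dt
    ev <- which(stats::runif(length(p)) < pmin(p, 1))
    t_stop <- if (length(ev)) tb[ev[1]] + dt / 2 else Inf
    # saturation is only meaningful over bins the trial actually traverses
    lived <- seq_len(min(length(p),
                         ceiling(min(t_stop, trials$t_pop_s[i]) / dt)))
    n_sat <- n_sat + sum(p[lived] > 1); n_bins <- n_bins + length(lived)
    if (t_stop < trials$t_pop_s[i]) {
      trials$t_stop_s[i] <- t_stop
      trials$outcome[i] <- "banked"
      trials$points[i] <- rate * t_stop
    } else {
      trials$t_stop_s[i] <- NA_real_
      trials$outcome[i] <- "popped"
      trials$points[i] <- 0
    }
  }
  if (n_bins > 0 && n_sat / n_bins > max_sat_frac) {
    stop("hazard probability saturated (lambda*dt > 1) in ",
         sprintf("%.1f%%", 100 * n_sat / n_bins),
         " of bins; reduce dt (increase fs_hz) or the hazard scale")
  }
  # recompute session-clock starts from realized durations
  if (!is.null(config)) {
    dur <- trial_duration(trials) + config$outcome_dur_s
    n <- nrow(trials)
    trials$t_start_s <- config$iti_s + c(0, cumsum(dur[-n] + config$iti_s))
  }
  trials
}

#' Convenience wrapper: simulate a full session
#'
#' Trials, agent stops, spikes and LFP from one master seed, with
#' per-stage seeds derived by [derive_seed()].
#'
#' @param config a [task_config()].
#' @param policy an [agent_policy()]; default stops near 85% of each
#'   colour's mean pop time with 0.5 s spread.
#' @param params a [neural_gen_params()].
#' @param n_units number of simulated units.
#' @param seed master seed (defaults to `config$seed`).
#' @return list with `trials`, `spikes`, `lfp`, `config`, `params`.
#' @export
simulate_session <- function(config = task_config(),
                             policy = NULL,
                             params = neural_gen_params(),
                             n_units = 2L,
                             seed = config$seed) {
  if (is.null(policy)) {
    rl <- config$risk_levels
    policy <- agent_policy(
      target_mean_s = stats::setNames(0.85 * rl$mean_pop_s, rl$label),
      target_sd_s = stats::setNames(pmax(0.3, 0.15 * rl$mean_pop_s),
                                    rl$label)
    )
  }
  trials <- generate_trials(config)
  trials <- simulate_agent_stops(trials, policy, config,
                                 seed = derive_seed(seed, "stops"))
  spikes <- simulate_spikes(trials, params, seed = derive_seed(seed, "spk"),
                            n_units = n_units)
  lfp <- simulate_lfp(trials, params, seed = derive_seed(seed, "field"))
  list(trials = trials, spikes = spikes, lfp = lfp,
       config = config, params = params)
}
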