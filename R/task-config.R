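#' Task configuration for the continuous balloon risk task
#'
#' Describes a session of the continuous-time balloon analog risk task
#' (BART): a subject inflates a balloon whose value grows linearly in time
#' and must stop before a hidden, colour-specific Gaussian pop time.
#'
#' @param risk_levels data.frame with columns `label`, `mean_pop_s`,
#'   `sd_pop_s`. Defaults to the three task colours: red (3 +/- 0.9 s),
#'   orange (6.5 +/- 1.95 s), yellow (10 +/- 3 s); the standard deviation
#'   is 30% of the mean for every colour.
#' @param reward_rate balloon value growth in points per second (default 30).
#' @param frac_forced fraction of balloons shown a pre-drawn pop ring
#'   (forced trials, default 0.25). Assignment is by exact quota.
#' @param include_gray include gray no-reward control balloons.
#' @param frac_gray fraction of gray control balloons when included
#'   (default 0.1; the task description gives no fraction).
#' @param gray_ring_source risk label whose pop-time distribution draws the
#'   gray-ring radii (default "orange", the intermediate risk level).
#' @param n_trials number of trials in the session.
#' @param iti_s inter-trial interval in seconds (default 2; not stated by
#'   the task description, see the methods vignette).
#' @param outcome_dur_s duration of the outcome epoch appended after the
#'   stop or pop (default 1 s).
#' @param seed RNG seed for the session.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(risk_levels = default_risk_levels(),
                        reward_rate = 30,
                        frac_forced = 0.25,
                        include_gray = TRUE,
                        frac_gray = 0.1,
                        gray_ring_source = "orange",
                        n_trials = 100L,
                        iti_s = 2,
                        outcome_dur_s = 1,
                        seed = 1L) {
  risk_levels <- as.data.frame(risk_levels)
  stopifnot(
    all(c("label", "mean_pop_s", "sd_pop_s") %in% names(risk_levels)),
    all(risk_levels$mean_pop_s > 0),
    all(risk_levels$sd_pop_s > 0),
    reward_rate > 0,
    frac_forced >= 0, frac_forced <= 1,
    frac_gray >= 0, frac_gray <= 1,
    iti_s >= 0, outcome_dur_s >= 0
  )
  if (n_trials <= 0) stop("n_trials must be positive")
  if (include_gray && !gray_ring_source %in% risk_levels$label) {
    stop("unknown gray_ring_source label: ", gray_ring_source)
  }
  structure(
    list(
      risk_levels = risk_levels,
      reward_rate = reward_rate,
      frac_forced = frac_forced,
      include_gray = include_gray,
      frac_gray = if (include_gray) frac_gray else 0,
      gray_ring_source = gray_ring_source,
      n_trials = as.integer(n_trials),
      iti_s = iti_s,
      outcome_dur_s = outcome_dur_s,
      seed = as.integer(seed)
    ),
    class = "task_config"
  )
}

#' Default risk levels of the task
#'
#' @return data.frame of the three balloon colours with the Gaussian
#'   pop-time parameters used in the task: red 3 +/- 0.9 s, orange
#'   6.5 +/- 1.95 s, yellow 10 +/- 3 s.
#' @export
default_risk_levels <- function() {
  data.frame(
    label = c("red", "orange", "yellow"),
    mean_pop_s = c(3, 6.5, 10),
    sd_pop_s = c(0.9, 1.95, 3),
    risk = c("high", "medium", "low")
  )
}

#' Stopping policy for the simulated agent
#'
#' A stand-in for subject behaviour: per risk level, intended stop times
#' are drawn from a normal distribution (truncated at zero).
#'
#' @param target_mean_s named numeric vector, intended mean stop time per
#'   risk label.
#' @param target_sd_s named numeric vector (or scalar) of stop-time SDs.
#' @param jitter_s motor reaction jitter SD added on top (default 0.05 s).
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(target_mean_s, target_sd_s = 0.5, jitter_s = 0.05) {
  stopifnot(all(target_mean_s > 0), all(target_sd_s >= 0), jitter_s >= 0)
  if (length(target_sd_s) == 1L) {
    target_sd_s <- stats::setNames(
      rep(target_sd_s, length(target_mean_s)), names(target_mean_s)
    )
  }
  structure(
    list(target_mean_s = target_mean_s, target_sd_s = target_sd_s,
         jitter_s = jitter_s),
    class = "agent_policy"
  )
}

#' Generative parameters for synthetic neural data
#'
#' @param glm_truth list with `beta0` (baseline log rate, spikes/s scale),
#'   `beta` (named coefficients matching design columns of
#'   [build_design()]), and `gamma` (exponent of the power-law
#'   elapsed-time gain `(t - t0 + 1)^gamma`).
#' @param lfp_bands data.frame with columns `name`, `center_hz`,
#'   `baseline_amp`, `ramp_gain` (multiplicative amplitude gain reached at
#'   the stop), `ramp_onset_s` (seconds before a voluntary stop at which
#'   the linear amplitude ramp begins).
#' @param noise_amp amplitude of the 1/f background noise.
#' @param noise_exponent spectral exponent of the background (default 1).
#' @param n_channels number of LFP channels.
#' @param fs_hz LFP sampling rate in Hz.
#' @param pop_step_gain optional amplitude gain applied for 0.5 s after
#'   balloon pops (default 1 = none).
#' @param hazard_truth optional list with `m` and `s` (named per risk
#'   label), `mu` (intercept) and `beta` (coefficients on channel x band
#'   regressors) for hazard-model stop generation.
#' @return An object of class `neural_gen_params`.
#' @export
neural_gen_params <- function(glm_truth = list(beta0 = log(10), beta = NULL,
                                               gamma = 0),
                              lfp_bands = default_lfp_gen_bands(),
                              noise_amp = 1,
                              noise_exponent = 1,
                              n_channels = 4L,
                              fs_hz = 1000,
                              pop_step_gain = 1,
                              hazard_truth = NULL) {
  lfp_bands <- as.data.frame(lfp_bands)
  stopifnot(
    n_channels >= 1,
    fs_hz > 2 * max(lfp_bands$center_hz),
    all(lfp_bands$baseline_amp >= 0),
    all(lfp_bands$ramp_onset_s > 0)
  )
  structure(
    list(glm_truth = glm_truth, lfp_bands = lfp_bands,
         noise_amp = noise_amp, noise_exponent = noise_exponent,
         n_channels = as.integer(n_channels), fs_hz = fs_hz,
         pop_step_gain = pop_step_gain, hazard_truth = hazard_truth),
    class = "neural_gen_params"
  )
}

#' @rdname neural_gen_params
#' @export
default_lfp_gen_bands <- function() {
  data.frame(
    name = c("theta", "beta"),
    center_hz = c(6, 20),
    baseline_amp = c(1, 1),
    ramp_gain = c(2, 1.5),
    ramp_onset_s = c(2, 0.5)
  )
}

#' Derive a per-stage RNG seed from a master seed
#'
#' Deterministic, stage-name-keyed stream splitting so every stochastic
#' stage of the pipeline is independently reproducible.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage) {
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
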