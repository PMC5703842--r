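#' Draw from a normal distribution truncated to strictly positive values
#'
#' Negative draws are redrawn rather than clipped, so sample moments stay
#' close to the nominal (mean, sd) whenever the truncated mass is small,
#' as it is for all task colours.
#' @noRd
rnorm_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  if (all(sd == 0)) return(mean)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0 & sd > 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate the trial table for a synthetic session
#'
#' Draws one row per balloon: a risk colour, a hidden pop time from the
#' colour's Gaussian distribution (truncated at zero by redrawing), and a
#' trial type. Forced and gray control balloons carry a pre-drawn ring
#' time instead of a hidden pop. Risk colours and control types are
#' assigned by exact quota and shuffled, so a session with `n_trials`
#' divisible by the quota denominator contains exactly the configured
#' fraction of each type.
#'
#' Times `t_pop_s`, `t_ring_s` and (after [simulate_agent_stops()])
#' `t_stop_s` are measured from the trial start; `t_start_s` is on the
#' session clock. Start times are provisionally spaced by the inter-trial
#' interval plus the maximal trial duration and are recomputed once stop
#' times are known.
#'
#' @param config a [task_config()].
#' @return data.frame of class `trial_table` with columns `trial_id`,
#'   `type` (free/forced/gray), `risk`, `t_start_s`, `t_stop_s`,
#'   `t_pop_s`, `t_ring_s`, `outcome`, `points`.
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_trials
  set.seed(derive_seed(config$seed, "trials"))

  n_gray <- if (config$include_gray) round(config$frac_gray * n) else 0L
  n_forced <- round(config$frac_forced * n)
  n_free <- n - n_gray - n_forced
  if (n_free < 0) stop("frac_forced + frac_gray exceed 1")
  type <- sample(rep(c("free", "forced", "gray"),
                     c(n_free, n_forced, n_gray)))

  rl <- config$risk_levels
  k <- nrow(rl)
  n_col <- n - n_gray   # gray balloons have no risk colour
  base <- n_col %/% k
  extra <- sample(rl$label, n_col - base * k)
  colours <- sample(c(rep(rl$label, base), extra))
  risk <- character(n)
  risk[type != "gray"] <- colours
  risk[type == "gray"] <- "gray"

  t_pop <- rep(NA_real_, n)
  t_ring <- rep(NA_real_, n)
  for (i in seq_len(k)) {
    lab <- rl$label[i]
    idx <- which(risk == lab & type == "free")
    t_pop[idx] <- rnorm_pos(length(idx), rl$mean_pop_s[i], rl$sd_pop_s[i])
    idx <- which(risk == lab & type == "forced")
    t_ring[idx] <- rnorm_pos(length(idx), rl$mean_pop_s[i], rl$sd_pop_s[i])
  }
  src <- rl[rl$label == config$gray_ring_source, ]
  idx <- which(type == "gray")
  t_ring[idx] <- rnorm_pos(length(idx), src$mean_pop_s, src$sd_pop_s)

  dur <- ifelse(type == "free", t_pop, t_ring) + config$outcome_dur_s
  t_start <- config$iti_s + c(0, cumsum(dur[-n] + config$iti_s))

  out <- data.frame(
    trial_id = seq_len(n),
    type = type,
    risk = risk,
    t_start_s = t_start,
    t_stop_s = NA_real_,
    t_pop_s = t_pop,
    t_ring_s = t_ring,
    outcome = NA_character_,
    points = NA_real_
  )
  class(out) <- c("trial_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' Simulate stop decisions and outcomes for a trial table
#'
#' Free trials receive an intended stop time drawn from the policy's
#' per-risk normal distribution (plus reaction jitter, truncated at zero).
#' If the intended stop precedes the hidden pop time the balloon is
#' banked for `reward_rate * stop time` points, otherwise it pops for 0
#' points. Forced control trials always bank at the ring time; gray
#' control trials end at the ring time with 0 points. Session-clock start
#' times are then recomputed from the realized trial durations.
#'
#' @param trials a `trial_table` from [generate_trials()].
#' @param policy an [agent_policy()].
#' @param config the [task_config()] of the session (defaults to the one
#'   attached to `trials`).
#' @param seed RNG seed.
#' @return the completed `trial_table`.
#' @export
simulate_agent_stops <- function(trials, policy,
                                 config = attr(trials, "config"),
                                 seed = config$seed + 1L) {
  stopifnot(inherits(policy, "agent_policy"), !is.null(config))
  set.seed(derive_seed(seed, "agent"))
  rate <- config$reward_rate

  free <- which(trials$type == "free")
  mu <- policy$target_mean_s[trials$risk[free]]
  sd <- policy$target_sd_s[trials$risk[free]]
  if (anyNA(mu)) stop("policy lacks a target for some risk label")
  intended <- rnorm_pos(length(free), mu, sqrt(sd^2 + policy$jitter_s^2))

  banked <- intended < trials$t_pop_s[free]
  trials$t_stop_s[free] <- ifelse(banked, intended, NA_real_)
  trials$outcome[free] <- ifelse(banked, "banked", "popped")
  trials$points[free] <- ifelse(banked, rate * intended, 0)

  forced <- trials$type == "forced"
  trials$t_stop_s[forced] <- trials$t_ring_s[forced]
  trials$outcome[forced] <- "banked"
  trials$points[forced] <- rate * trials$t_ring_s[forced]

  gray <- trials$type == "gray"
  trials$t_stop_s[gray] <- trials$t_ring_s[gray]
  trials$outcome[gray] <- "gray"
  trials$points[gray] <- 0

  dur <- trial_duration(trials) + config$outcome_dur_s
  n <- nrow(trials)
  trials$t_start_s <- config$iti_s + c(0, cumsum(dur[-n] + config$iti_s))
  attr(trials, "config") <- config
  trials
}

#' Trial duration up to the stop or pop, in seconds
#' @param trials a `trial_table`.
#' @return numeric vector of inflation durations.
#' @export
trial_duration <- function(trials) {
  ifelse(!is.na(trials$t_stop_s), trials$t_stop_s,
         ifelse(!is.na(trials$t_pop_s), trials$t_pop_s, trials$t_ring_s))
}

#' Session end time implied by a trial table
#'
#' End of the last trial's outcome epoch plus one inter-trial interval.
#' @param trials a `trial_table`.
#' @param config the session's [task_config()].
#' @return time in seconds on the session clock.
#' @export
session_end <- function(trials, config = attr(trials, "config")) {
  n <- nrow(trials)
  outcome_dur <- if (is.null(config)) 1 else config$outcome_dur_s
  iti <- if (is.null(config)) 2 else config$iti_s
  trials$t_start_s[n] + trial_duration(trials)[n] + outcome_dur + iti
}
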