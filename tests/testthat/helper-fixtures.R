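# Shared fixture builders; everything is generated in code at test time.

# a minimal completed trial table with fully controlled times
make_trials <- function(type, risk, t_start, t_stop, t_pop, outcome,
                        points, config = task_config(n_trials = length(type))) {
  tr <- data.frame(
    trial_id = seq_along(type), type = type, risk = risk,
    t_start_s = t_start, t_stop_s = t_stop, t_pop_s = t_pop,
    t_ring_s = NA_real_, outcome = outcome, points = points
  )
  class(tr) <- c("trial_table", "data.frame")
  attr(tr, "config") <- config
  tr
}

# an lfp_recording wrapping a plain signal matrix
make_rec <- function(signals, fs) {
  signals <- as.matrix(signals)
  structure(
    list(signals = signals, fs_hz = fs,
         channel_ids = sprintf("ch%02d", seq_len(ncol(signals))),
         t_s = (seq_len(nrow(signals)) - 1) / fs),
    class = "lfp_recording"
  )
}

# a band_power_series with fully controlled power values
make_bps <- function(power, fs, band = "theta") {
  power <- as.matrix(power)
  structure(
    list(power = power, fs_hz = fs, band = band,
         mask = matrix(FALSE, nrow(power), ncol(power)),
         t_s = (seq_len(nrow(power)) - 1) / fs,
         channel_ids = sprintf("ch%02d", seq_len(ncol(power)))),
    class = "band_power_series"
  )
}

# a tfr_map with given power matrix and event-relative times
make_tfr <- function(power, freqs = NULL, times = NULL) {
  power <- as.matrix(power)
  if (is.null(freqs)) freqs <- seq_len(nrow(power))
  if (is.null(times)) times <- seq(-2, 1, length.out = ncol(power))
  structure(list(power = power, freqs = freqs, times = times, w = 9,
                 edge = matrix(FALSE, nrow(power), ncol(power))),
            class = "tfr_map")
}

# standard agent policy used across tests: stops near 85% of the mean
default_policy <- function(config) {
  rl <- config$risk_levels
  agent_policy(
    target_mean_s = stats::setNames(0.85 * rl$mean_pop_s, rl$label),
    target_sd_s = stats::setNames(pmax(0.3, 0.15 * rl$mean_pop_s), rl$label)
  )
}

# hazard-model simulation: trials + (optional) regressors -> hazard_design
make_hazard_design <- function(n_trials = 90, p = 4, beta = NULL, seed = 99,
                               fs = 40,
                               m = c(red = 2.5, orange = 5.5, yellow = 8.5),
                               s = c(red = 0.8, orange = 1.6, yellow = 2.5),
                               mu = 0) {
  cfg <- task_config(n_trials = n_trials, frac_forced = 0,
                     include_gray = FALSE, seed = seed)
  tr <- generate_trials(cfg)
  dt <- 1 / fs
  set.seed(derive_seed(seed, "hdesign"))
  store <- new.env()
  regf <- function(id, tb) {
    X <- matrix(stats::rnorm(length(tb) * p), length(tb), p)
    assign(as.character(id), X, envir = store)
    X
  }
  truth <- list(m = m, s = s, mu = mu, beta = beta)
  tr <- simulate_hazard_stops(tr, truth,
                              regressors = if (!is.null(beta)) regf else NULL,
                              fs_hz = fs, seed = seed + 1)
  bins <- list(); Xs <- list()
  for (i in seq_len(nrow(tr))) {
    end_t <- if (tr$outcome[i] == "banked") tr$t_stop_s[i] else tr$t_pop_s[i]
    last <- if (tr$outcome[i] == "banked") round(tr$t_stop_s[i] / dt) else
      floor(end_t / dt - 0.5)
    if (last < 1) next
    tb <- seq_len(last) * dt
    ev <- integer(last)
    if (tr$outcome[i] == "banked") ev[last] <- 1L
    bins[[length(bins) + 1]] <- data.frame(
      trial_id = tr$trial_id[i], risk = tr$risk[i], t = tb, event = ev,
      censored = tr$outcome[i] == "popped"
    )
    X <- if (!is.null(beta))
      get(as.character(tr$trial_id[i]), envir = store)[seq_len(last), ,
                                                       drop = FALSE]
    else matrix(stats::rnorm(last * p), last, p)
    Xs[[length(Xs) + 1]] <- X
  }
  bins <- do.call(rbind, bins)
  X <- do.call(rbind, Xs)
  if (p > 0) colnames(X) <- paste0("r", seq_len(p))
  else X <- matrix(0, nrow(bins), 0)
  list(design = stnbart:::hazard_design_from_parts(bins, X, dt),
       trials = tr)
}

# white-noise per-trial maps for cluster tests
make_maps <- function(n, nf = 40, nt = 80) {
  lapply(seq_len(n), function(i) matrix(stats::rnorm(nf * nt), nf, nt))
}
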