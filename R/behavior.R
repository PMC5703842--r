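#' Expected reward of stopping at time t
#'
#' For Gaussian pop times tau ~ N(mu, sigma^2) and balloon value growing
#' linearly at `rate` points/s, the expected reward of planning to stop
#' at time `t` is the value banked times the probability the balloon has
#' survived: `rate * t * (1 - Phi((t - mu) / sigma))`.
#'
#' @param t stop time(s) in seconds, `>= 0`.
#' @param mean_s,sd_s pop-time distribution parameters (sd_s > 0).
#' @param rate reward slope in points per second.
#' @return expected points, same length as `t`.
#' @export
expected_reward <- function(t, mean_s, sd_s, rate = 30) {
  stopifnot(sd_s > 0, rate > 0)
  if (any(t < 0)) stop("t must be non-negative")
  rate * t * stats::pnorm(t, mean_s, sd_s, lower.tail = FALSE)
}

#' Optimal stop time under Gaussian pop risk
#'
#' Numerically maximizes [expected_reward()] over `(0, mu + 6 sigma]`
#' using a dense 1 ms grid followed by local golden-section refinement.
#' The maximizer does not depend on the reward rate, which scales the
#' objective.
#'
#' @inheritParams expected_reward
#' @param grid_s grid resolution in seconds (default 1 ms).
#' @return optimal stop time in seconds.
#' @export
optimal_stop_time <- function(mean_s, sd_s, rate = 30, grid_s = 1e-3) {
  stopifnot(mean_s > 0, sd_s > 0)
  # the reward rate only scales the objective, so the search runs at unit
  # rate: invariance of the maximizer to the rate is then exact
  upper <- mean_s + 6 * sd_s
  grid <- seq(grid_s, upper, by = grid_s)
  i <- which.max(expected_reward(grid, mean_s, sd_s, rate = 1))
  lo <- max(grid_s / 2, grid[i] - grid_s)
  hi <- min(upper, grid[i] + grid_s)
  stats::optimize(function(t) expected_reward(t, mean_s, sd_s, rate = 1),
                  c(lo, hi), maximum = TRUE, tol = 1e-8)$maximum
}

#' Per-condition behavioural summary of a session
#'
#' Summarizes a completed trial table per risk level and trial type:
#' number of trials, mean inflation time (time from trial start to the
#' stop or pop), mean voluntary stop time among banked trials, fraction
#' of popped balloons, and mean points. Conditions with no trials are
#' returned with `NA` values and `n = 0` rather than dropped silently.
#'
#' @param trials a completed `trial_table`.
#' @return data.frame with one row per (risk, type) condition present in
#'   the session design.
#' @export
behavioral_summary <- function(trials) {
  if (anyNA(trials$outcome)) {
    stop("trial table has unsimulated outcomes; run simulate_agent_stops()")
  }
  conds <- unique(trials[, c("risk", "type")])
  conds <- conds[order(conds$type, conds$risk), ]
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- trials$risk == conds$risk[i] & trials$type == conds$type[i]
    tt <- trials[sel, ]
    n <- nrow(tt)
    data.frame(
      risk = conds$risk[i], type = conds$type[i], n = n,
      mean_inflate_s = if (n) mean(trial_duration(tt)) else NA_real_,
      mean_stop_s = if (any(tt$outcome == "banked"))
        mean(tt$t_stop_s[tt$outcome == "banked"]) else NA_real_,
      frac_popped = if (n) mean(tt$outcome == "popped") else NA_real_,
      mean_points = if (n) mean(tt$points) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
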