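#' Hazard function of the normal event-time distribution
#'
#' `h(t) = phi(z) / (s (1 - Phi(z)))` with `z = (t - m) / s`, evaluated
#' through the log survival function so it stays finite, accurate and
#' monotone far into the upper tail (z well beyond 8), where the naive
#' ratio would overflow. For a normal event-time law the hazard is
#' nondecreasing and approaches the Mills-ratio asymptote `z / s`.
#'
#' @param t time(s).
#' @param m,s location and scale of the event-time distribution (s > 0).
#' @return hazard rate(s), same length as `t`.
#' @export
normal_hazard <- function(t, m, s) {
  if (s <= 0) stop("s must be positive")
  z <- (t - m) / s
  exp(stats::dnorm(z, log = TRUE) -
        stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)) / s
}

#' Build the discrete-time hazard design from band power
#'
#' Restricts time to within-trial bins on a `fs_hz` (default 40 Hz) grid
#' of trial time, codes the bin containing the voluntary stop of each
#' successfully banked free trial as the event (all other bins 0), and
#' treats popped trials as censored: their bins end at the pop with no
#' event. Control (forced/gray) trials carry no voluntary stop and are
#' excluded. Each regressor is the mean of per-channel standardized log
#' band power over the trailing `window_s` seconds before the bin; bins
#' whose trailing window precedes the trial start or overlaps masked
#' artifact samples are dropped (counted in `n_dropped`). Regressor
#' columns are re-standardized to mean 0, variance 1 over the retained
#' bins.
#'
#' @param band_powers named list of `band_power_series` (one per band,
#'   any sampling rate at or above `fs_hz` and divisible by it).
#' @param trials a completed `trial_table`.
#' @param fs_hz hazard grid rate.
#' @param window_s trailing regressor window.
#' @return object of class `hazard_design`: list with data.frame `bins`
#'   (`trial_id`, `risk`, `t`, `event`, `censored`), matrix `X`
#'   (columns `<band>_<channel>`), `dt`, `risk_levels`, `n_dropped`.
#' @export
build_hazard_design <- function(band_powers, trials, fs_hz = 40,
                                window_s = 0.5) {
  dt <- 1 / fs_hz
  if (!is.null(band_powers) && length(band_powers)) {
    zlogs <- lapply(band_powers, function(bp) {
      stopifnot(inherits(bp, "band_power_series"))
      lp <- log(pmax(bp$power, .Machine$double.xmin))
      lp[bp$mask] <- NA
      mu <- colMeans(lp, na.rm = TRUE)
      sd <- apply(lp, 2, stats::sd, na.rm = TRUE)
      sweep(sweep(lp, 2, mu), 2, pmax(sd, .Machine$double.eps), "/")
    })
    fs_pw <- vapply(band_powers, `[[`, 0, "fs_hz")
    if (length(unique(fs_pw)) != 1) stop("band powers at mixed rates")
    fs_pw <- fs_pw[1]
  } else {
    zlogs <- list(); fs_pw <- fs_hz
  }

  free <- trials[trials$type == "free", , drop = FALSE]
  rows <- list(); xs <- list(); n_dropped <- 0L
  for (i in seq_len(nrow(free))) {
    end_t <- if (free$outcome[i] == "banked") free$t_stop_s[i] else
      free$t_pop_s[i]
    # bin centers at multiples of dt; bin j covers [(j-0.5)dt, (j+0.5)dt)
    last <- if (free$outcome[i] == "banked")
      round(free$t_stop_s[i] / dt) else floor(end_t / dt - 0.5)
    if (last < 1) next
    tb <- seq_len(last) * dt
    event <- integer(last)
    if (free$outcome[i] == "banked") event[last] <- 1L

    keep <- tb - window_s >= 0
    n_dropped <- n_dropped + sum(!keep)

    Xi <- NULL
    if (length(zlogs)) {
      sess_t <- free$t_start_s[i] + tb
      k <- max(1L, as.integer(round(window_s * fs_pw)))
      i_end <- pmin(floor(sess_t * fs_pw) + 1L, nrow(zlogs[[1]]))
      i_start <- i_end - k + 1L
      ok <- i_start >= 1L
      Xi <- do.call(cbind, lapply(names(zlogs), function(bn) {
        z <- zlogs[[bn]]
        cols <- vapply(seq_len(ncol(z)), function(ch) {
          # trailing-window means via cumulative sums; windows containing
          # any masked (NA) sample are flagged NA and dropped
          na <- is.na(z[, ch])
          cs <- cumsum(ifelse(na, 0, z[, ch]))
          cn <- cumsum(na)
          lo <- function(v, idx) ifelse(idx > 1, v[pmax(idx - 1L, 1L)], 0)
          out <- rep(NA_real_, length(i_end))
          touched <- cn[i_end[ok]] - lo(cn, i_start[ok]) > 0
          vals <- (cs[i_end[ok]] - lo(cs, i_start[ok])) / k
          vals[touched] <- NA
          out[ok] <- vals
          out
        }, numeric(length(i_end)))
        colnames(cols) <- paste0(bn, "_", band_powers[[bn]]$channel_ids)
        cols
      }))
      drop_na <- rowSums(is.na(Xi)) > 0
      n_dropped <- n_dropped + sum(drop_na & keep)
      keep <- keep & !drop_na
    }
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      trial_id = free$trial_id[i], risk = free$risk[i], t = tb[keep],
      event = event[keep], censored = free$outcome[i] == "popped"
    )
    if (!is.null(Xi)) xs[[length(xs) + 1]] <- Xi[keep, , drop = FALSE]
  }
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL
  X <- if (length(xs)) do.call(rbind, xs) else
    matrix(0, nrow(bins), 0)
  X <- standardize_cols(X)
  structure(list(bins = bins, X = X, dt = dt,
                 risk_levels = sort(unique(bins$risk)),
                 n_dropped = n_dropped, window_s = window_s),
            class = "hazard_design")
}

#' Column standardization with a zero-variance guard: a constant
#' regressor (e.g. from a constant power signal) maps to all zeros
#' rather than NaN.
#' @noRd
standardize_cols <- function(X) {
  if (!ncol(X)) return(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sweep(sweep(X, 2, mu), 2, ifelse(sd > 0, sd, 1), "/")
}

#' Faster regressor construction from a precomputed matrix
#'
#' Convenience for simulations: build a `hazard_design` directly from a
#' bins table and regressor matrix (already on the hazard grid).
#' @noRd
hazard_design_from_parts <- function(bins, X, dt) {
  X <- standardize_cols(X)
  structure(list(bins = bins, X = X, dt = dt,
                 risk_levels = sort(unique(bins$risk)),
                 n_dropped = 0L, window_s = NA_real_),
            class = "hazard_design")
}

# The full Poisson log-likelihood is collapsed into a single observed
# node (the "zeros trick"), with the per-bin linear predictor built from
# vectorized expressions: bins share a common trial-time grid, so the
# log normal-hazard term is computed once per (risk level, grid time)
# pair and expanded by vector indexing. This keeps the sampler's graph
# tiny and every likelihood evaluation a handful of C-level vector
# operations. The survival term is floored at 1e-12 so the log hazard
# stays finite far into the upper tail.
hazard_jags_model <- function(p) {
  beta_block <- if (p > 0) "
    for (j in 1:P) {
      lam_hs[j] ~ dt(0, 1, 1) T(0,)
      beta[j] ~ dnorm(0, 1 / pow(tau_hs * lam_hs[j], 2))
    }
    tau_hs ~ dt(0, 1, 1) T(0,)
  " else ""
  eta <- if (p > 0) " + X %*% beta" else ""
  paste0("
  model {
    for (g in 1:G) {
      zg[g] <- (tg[g] - m[rg[g]]) / s[rg[g]]
      lh[g] <- logdensity.norm(zg[g], 0, 1) - log(s[rg[g]]) -
        log(max(1 - phi(zg[g]), 1.0E-12))
    }
    loglam <- lh[gidx] + mu_h + log_dt", eta, "
    for (n in 1:N) { explam[n] <- exp(loglam[n]) }
    # total Poisson log-likelihood as one node: sum(y log lambda) - sum(lambda)
    loglik <- inprod(y, loglam) - sum(explam)
    zero ~ dpois(BIGC - loglik)
    for (i in 1:R) {
      m[i] ~ dnorm(7.5, 0.04) T(0, 15)
      s[i] ~ dnorm(0, 0.04) T(0.05,)
    }
    mu_h ~ dnorm(0, 0.25)
  ", beta_block, "
  }")
}

#' Fit the Bayesian proportional-hazards model of voluntary stopping
#'
#' Discrete-time survival model on the hazard grid: within-trial event
#' indicators are Poisson within each bin with mean `lambda_i(t) dt`,
#' where `lambda_i(t) = h_i(t; m_i, s_i) exp(mu + X(t) beta)`, `h_i` the
#' normal-distribution hazard of risk level i, and `beta` the
#' channel-by-band power coefficients under a horseshoe prior
#' (half-Cauchy(0, 1) local and global scales), which shrinks irrelevant
#' regressors to zero while leaving real effects unshrunk. Locations
#' `m_i` get a broad normal prior on (0, 15) s, scales `s_i` a
#' half-normal, and the intercept `mu` a normal(0, 2^2). Popped trials
#' contribute only censored (non-event) bins.
#'
#' Sampling uses MCMC (JAGS) with, by default, four chains of 2,000
#' iterations, the first half discarded as burn-in, and a thinning
#' fraction of five. Convergence is assessed per reported parameter by
#' the Gelman-Rubin statistic (R-hat < 1.01) and bulk effective sample
#' size (> 400); failures are flagged in the output, never hidden.
#'
#' @param design a `hazard_design`.
#' @param chains number of chains.
#' @param iters iterations per chain (including burn-in).
#' @param warmup burn-in iterations (default half).
#' @param thin thinning fraction.
#' @param seed RNG seed (per-chain seeds are derived from it).
#' @param quiet suppress sampler progress output.
#' @return object of class `hazard_fit`: list with `summary`
#'   (data.frame: parameter, median, lower95, upper95, rhat, ess,
#'   converged), `draws` (a `coda::mcmc.list`), `converged` (overall
#'   flag), `risk_levels`, `coef_names`, `dt`.
#' @export
fit_hazard_model <- function(design, chains = 4, iters = 2000,
                             warmup = floor(iters / 2), thin = 5,
                             seed = 1L, quiet = TRUE) {
  stopifnot(inherits(design, "hazard_design"), iters > warmup)
  bins <- design$bins
  risk_levels <- design$risk_levels
  p <- ncol(design$X)
  grid <- unique(data.frame(risk = match(bins$risk, risk_levels),
                            t = bins$t))
  gidx <- match(
    paste(match(bins$risk, risk_levels), bins$t),
    paste(grid$risk, grid$t)
  )
  dat <- list(
    N = nrow(bins),
    y = bins$event,
    G = nrow(grid),
    tg = grid$t,
    rg = grid$risk,
    gidx = gidx,
    R = length(risk_levels),
    log_dt = log(design$dt),
    zero = 0,
    BIGC = 1e6
  )
  if (p > 0) { dat$X <- design$X; dat$P <- p }

  # initialize hazard locations near the observed event times per level
  ev <- bins[bins$event == 1, ]
  m0 <- vapply(risk_levels, function(r) {
    x <- ev$t[ev$risk == r]
    if (length(x)) min(max(mean(x), 0.5), 14.5) else 5
  }, 0)
  inits <- lapply(seq_len(chains), function(ch) {
    ii <- list(m = unname(m0), s = rep(2, length(risk_levels)), mu_h = 0,
               .RNG.name = "base::Mersenne-Twister",
               .RNG.seed = derive_seed(seed, paste0("chain", ch)))
    if (p > 0) { ii$beta <- rep(0, p); ii$lam_hs <- rep(1, p); ii$tau_hs <- 1 }
    ii
  })

  monitor <- c("m", "s", "mu_h", if (p > 0) "beta")
  n_adapt <- max(100, floor(warmup / 2))
  jm <- rjags::jags.model(textConnection(hazard_jags_model(p)), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = quiet)
  if (warmup > n_adapt) {
    stats::update(jm, warmup - n_adapt,
                  progress.bar = if (quiet) "none" else "text")
  }
  draws <- rjags::coda.samples(jm, monitor, n.iter = iters - warmup,
                               thin = thin,
                               progress.bar = if (quiet) "none" else "text")

  coef_names <- colnames(design$X)
  rename <- function(v) {
    v <- sub("^m\\[(\\d+)\\]$", "m_\\1", v)
    v <- sub("^s\\[(\\d+)\\]$", "s_\\1", v)
    for (i in seq_along(risk_levels)) {
      v <- sub(paste0("^m_", i, "$"), paste0("m_", risk_levels[i]), v)
      v <- sub(paste0("^s_", i, "$"), paste0("s_", risk_levels[i]), v)
    }
    if (length(coef_names)) {
      for (j in seq_along(coef_names)) {
        v <- sub(paste0("^beta\\[", j, "\\]$"),
                 paste0("beta_", coef_names[j]), v)
      }
    }
    v
  }

  all_draws <- do.call(rbind, lapply(draws, as.matrix))
  q <- t(apply(all_draws, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  rhat <- tryCatch(
    coda::gelman.diag(draws, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(all_draws))
  )
  ess <- coda::effectiveSize(draws)
  summ <- data.frame(
    parameter = rename(colnames(all_draws)),
    median = q[, 1], lower95 = q[, 2], upper95 = q[, 3],
    rhat = unname(rhat[colnames(all_draws)]),
    ess = unname(ess[colnames(all_draws)]),
    row.names = NULL
  )
  summ$converged <- !is.na(summ$rhat) & summ$rhat < 1.01 & summ$ess > 400
  converged <- all(summ$converged)
  if (!converged) {
    warning("hazard model: ", sum(!summ$converged),
            " parameter(s) failed convergence checks (R-hat/ESS)")
  }
  colnames(all_draws) <- rename(colnames(all_draws))
  structure(list(summary = summ, draws = draws, draws_matrix = all_draws,
                 converged = converged, risk_levels = risk_levels,
                 coef_names = coef_names, dt = design$dt),
            class = "hazard_fit")
}

#' Coefficient effects as percent hazard change per regressor SD
#'
#' Because regressors are standardized, `(exp(beta) - 1) * 100` is the
#' percent change in the stop hazard per standard deviation of the
#' channel-by-band log power. The transform is monotone, so a credible
#' interval overlaps 0 on the coefficient scale exactly when the
#' percent-change interval does.
#'
#' @param fit a `hazard_fit`.
#' @return data.frame per coefficient: posterior median and 95% interval
#'   of the percent change, and `overlaps_zero`.
#' @export
summarize_effects <- function(fit) {
  stopifnot(inherits(fit, "hazard_fit"))
  s <- fit$summary
  b <- s[grepl("^beta_", s$parameter), , drop = FALSE]
  data.frame(
    regressor = sub("^beta_", "", b$parameter),
    pct_median = (exp(b$median) - 1) * 100,
    pct_lower95 = (exp(b$lower95) - 1) * 100,
    pct_upper95 = (exp(b$upper95) - 1) * 100,
    overlaps_zero = b$lower95 <= 0 & b$upper95 >= 0,
    row.names = NULL
  )
}
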