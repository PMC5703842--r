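#' Reject units with implausible session-average firing rates
#'
#' Units whose session-average rate lies outside [5, 100] spikes/s are
#' removed, following established subthalamic physiology; the bounds are
#' inclusive, so a unit at exactly 5 or 100 spikes/s is retained.
#'
#' @param spikes data.frame with columns `unit_id`, `timestamp_s`.
#' @param session_duration_s session length in seconds (> 0).
#' @param min_rate,max_rate inclusive bounds in spikes/s.
#' @return `spikes` restricted to retained units.
#' @export
filter_units <- function(spikes, session_duration_s,
                         min_rate = 5, max_rate = 100) {
  if (session_duration_s <= 0) stop("session duration must be positive")
  rates <- table(spikes$unit_id) / session_duration_s
  keep <- names(rates)[rates >= min_rate & rates <= max_rate]
  spikes[spikes$unit_id %in% keep, , drop = FALSE]
}

#' Bin spike timestamps into uniform-count bins
#'
#' @param timestamps event times of one unit, seconds on the session clock.
#' @param t_end_s session end; bins cover `[0, t_end_s)`.
#' @param bin_s bin width, default 50 ms.
#' @return list with integer `counts`, `edges`, `centers`, `bin_s`.
#' @export
bin_spikes <- function(timestamps, t_end_s, bin_s = 0.05) {
  edges <- seq(0, ceiling(t_end_s / bin_s) * bin_s, by = bin_s)
  counts <- as.integer(
    table(cut(timestamps, breaks = edges, right = FALSE,
              include.lowest = FALSE))
  )
  list(counts = counts, edges = edges,
       centers = edges[-length(edges)] + bin_s / 2, bin_s = bin_s)
}

#' Build the task design matrix for the spiking model
#'
#' One row per 50 ms bin spanning the whole session. Columns: an
#' indicator for the entire trial period (inflation plus outcome epochs),
#' separate indicators for the inflation and outcome periods, an
#' indicator for no-point outcomes (reference level: banked reward),
#' trial-type indicators for risk levels high / medium / low and control
#' (forced and gray) trials with the inter-trial baseline as reference,
#' and a log-elapsed-time column `log(t - t0 + 1)` (natural log, bin
#' centers) that is active within trials and 0 outside. The regressors
#' are deliberately not orthogonalized; multicollinearity is handled by
#' regularization in [fit_poisson_glm()].
#'
#' @param trials a completed `trial_table`.
#' @param bin_s bin width in seconds (default 0.05).
#' @param t_end_s session end (defaults to the end of the last trial plus
#'   one inter-trial interval).
#' @return object of class `glm_design`: list with matrix `X`, `centers`,
#'   `bin_s`, `edges`.
#' @export
build_design <- function(trials, bin_s = 0.05, t_end_s = NULL) {
  config <- attr(trials, "config")
  outcome_dur <- if (is.null(config)) 1 else config$outcome_dur_s
  if (is.null(t_end_s)) t_end_s <- session_end(trials)
  dur <- trial_duration(trials)
  if (anyNA(dur)) stop("trial table has unsimulated outcomes")
  starts <- trials$t_start_s
  ends <- starts + dur
  if (any(starts[-1] < (ends + outcome_dur)[-length(ends)])) {
    stop("overlapping trials")
  }

  edges <- seq(0, ceiling(t_end_s / bin_s) * bin_s, by = bin_s)
  centers <- edges[-length(edges)] + bin_s / 2
  nb <- length(centers)

  # risk level of each trial, controls collapsed to one level
  rl <- if (is.null(config)) default_risk_levels() else config$risk_levels
  level_of <- stats::setNames(rl$risk, rl$label)
  trial_level <- ifelse(trials$type == "free",
                        unname(level_of[trials$risk]), "control")
  no_points <- trials$outcome %in% c("popped", "gray")

  cols <- c("trial", "inflation", "outcome", "outcome_nopoints",
            "risk_high", "risk_medium", "risk_low", "risk_control",
            "elapsed_log")
  X <- matrix(0, nb, length(cols), dimnames = list(NULL, cols))
  # assign by interval membership per trial (trials are non-overlapping)
  for (i in seq_len(nrow(trials))) {
    t0 <- starts[i]
    infl <- centers >= t0 & centers < ends[i]
    outc <- centers >= ends[i] & centers < ends[i] + outcome_dur
    inside <- infl | outc
    if (!any(inside)) next
    X[inside, "trial"] <- 1
    X[infl, "inflation"] <- 1
    X[outc, "outcome"] <- 1
    if (no_points[i]) X[outc, "outcome_nopoints"] <- 1
    X[inside, paste0("risk_", trial_level[i])] <- 1
    X[inside, "elapsed_log"] <- log(centers[inside] - t0 + 1)
  }
  structure(list(X = X, centers = centers, bin_s = bin_s, edges = edges),
            class = "glm_design")
}

#' Fit the regularized Poisson model of single-unit firing
#'
#' Models 50 ms spike counts as Poisson with log rate `beta0 + X beta`,
#' where the design includes the power-law elapsed-time gain as a
#' log-time column (its coefficient is the exponent gamma). Fitting uses
#' elastic-net regularization with 10-fold cross-validation over a grid
#' of mixing values; the penalty is chosen by the one-standard-error rule
#' (most parsimonious model statistically indistinguishable from the
#' best), by the CV minimum (`rule = "min"`), or effectively unpenalized
#' (`rule = "none"`, the smallest penalty on the path). An offset of
#' `log(bin width)` puts the intercept on the spikes-per-second scale.
#'
#' @param design a `glm_design` from [build_design()].
#' @param counts integer vector of spike counts, row-aligned with the
#'   design (or the list returned by [bin_spikes()]).
#' @param folds number of cross-validation folds (seeded random
#'   partitions of bins).
#' @param mixing_grid elastic-net mixing values to search (default 0.1 to
#'   1 in steps of 0.1).
#' @param rule `"1se"`, `"min"` or `"none"`.
#' @param seed RNG seed for the fold partition.
#' @param rate_floor_hz lower guard on the baseline rate used when a unit
#'   has no spikes at all (default 1e-3 spikes/s).
#' @return object of class `glm_fit`: list with `beta0` (log baseline
#'   rate, spikes/s scale), named `beta`, `gamma`, `f0_hz`, `lambda`,
#'   `mixing`, `rule`, `cv` (per-mixing CV curves), `nonzero`.
#' @export
fit_poisson_glm <- function(design, counts, folds = 10,
                            mixing_grid = seq(0.1, 1, by = 0.1),
                            rule = c("1se", "min", "none"), seed = 1L,
                            rate_floor_hz = 1e-3) {
  rule <- match.arg(rule)
  if (is.list(counts)) counts <- counts$counts
  X <- design$X
  if (length(counts) != nrow(X)) stop("counts and design are not aligned")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }

  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  if (!all(keep)) {
    warning("dropping constant design columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xk <- X[, keep, drop = FALSE]
  all_names <- colnames(X)

  const_fit <- function(beta0) {
    beta <- stats::setNames(rep(0, length(all_names)), all_names)
    structure(list(beta0 = beta0, beta = beta,
                   gamma = 0, f0_hz = exp(beta0), lambda = Inf,
                   mixing = NA_real_, rule = rule, cv = NULL,
                   nonzero = character(0), bin_s = design$bin_s),
              class = "glm_fit")
  }
  if (sum(counts) == 0) return(const_fit(log(rate_floor_hz)))
  if (ncol(Xk) == 0) {
    # intercept-only Poisson MLE: mean rate over the session
    return(const_fit(log(mean(counts) / design$bin_s)))
  }
  if (ncol(Xk) == 1) {
    # glmnet requires >= 2 columns; pad with an all-zero dummy
    Xk <- cbind(Xk, .dummy_ = 0)
  }

  set.seed(derive_seed(seed, "cvfolds"))
  foldid <- sample(rep(seq_len(folds), length.out = length(counts)))
  offset <- rep(log(design$bin_s), length(counts))

  cvs <- lapply(mixing_grid, function(a) {
    glmnet::cv.glmnet(Xk, counts, family = "poisson", offset = offset,
                      alpha = a, foldid = foldid, standardize = FALSE)
  })
  best_cvm <- vapply(cvs, function(cv) min(cv$cvm), 0)
  j <- which.min(best_cvm)
  cv <- cvs[[j]]
  lambda <- switch(rule,
    "1se" = cv$lambda.1se,
    "min" = cv$lambda.min,
    "none" = min(cv$lambda)
  )
  co <- as.matrix(stats::coef(cv$glmnet.fit, s = lambda, exact = FALSE))[, 1]
  co <- co[names(co) != ".dummy_"]
  beta <- stats::setNames(rep(0, length(all_names)), all_names)
  beta[names(co)[-1]] <- co[-1]
  beta0 <- unname(co[1])

  structure(list(
    beta0 = beta0,
    beta = beta,
    gamma = unname(beta["elapsed_log"]),
    f0_hz = exp(beta0),
    lambda = lambda,
    mixing = mixing_grid[j],
    rule = rule,
    cv = list(mixing_grid = mixing_grid, best_cvm = best_cvm, chosen = cv),
    nonzero = names(beta)[beta != 0],
    bin_s = design$bin_s
  ), class = "glm_fit")
}

#' Effect sizes as percent change from baseline firing
#'
#' Binary and categorical regressors are reported as the multiplicative
#' gain `(exp(beta) - 1) * 100` percent. The elapsed-time effect is the
#' power-law gain `((t + 1)^gamma - 1) * 100` evaluated at a
#' representative elapsed time (default 5 s). Regularization zeros out
#' absent effects exactly, which is flagged in `present`.
#'
#' @param fit a `glm_fit`.
#' @param representative_elapsed_s elapsed time at which the time effect
#'   is evaluated.
#' @return data.frame with columns `regressor`, `coefficient`,
#'   `percent_change`, `present`.
#' @export
effect_sizes <- function(fit, representative_elapsed_s = 5) {
  stopifnot(inherits(fit, "glm_fit"))
  beta <- fit$beta
  pct <- (exp(beta) - 1) * 100
  is_time <- names(beta) == "elapsed_log"
  pct[is_time] <- ((representative_elapsed_s + 1)^beta[is_time] - 1) * 100
  data.frame(
    regressor = names(beta),
    coefficient = unname(beta),
    percent_change = unname(pct),
    present = unname(beta != 0),
    row.names = NULL
  )
}

#' Shuffle control for the spiking model
#'
#' Randomly permutes the bin order of the spike counts, destroying any
#' temporal alignment with the task, refits the parsimonious
#' (one-standard-error) model, and reports which regressors survive with
#' nonzero coefficients. On real or well-simulated data the shuffled fits
#' should produce zero nonzero effects.
#'
#' @inheritParams fit_poisson_glm
#' @param reps number of shuffle replicates.
#' @param ... further arguments passed to [fit_poisson_glm()] (e.g.
#'   `mixing_grid`).
#' @return data.frame with one row per (rep, regressor): `coefficient`
#'   and `nonzero`.
#' @export
shuffle_control <- function(design, counts, seed = 1L, reps = 20,
                            folds = 10, ...) {
  if (is.list(counts)) counts <- counts$counts
  set.seed(derive_seed(seed, "shuffle"))
  perms <- lapply(seq_len(reps), function(i) sample(length(counts)))
  rows <- lapply(seq_len(reps), function(i) {
    fit <- fit_poisson_glm(design, counts[perms[[i]]], folds = folds,
                           rule = "1se", seed = seed + i, ...)
    data.frame(rep = i, regressor = names(fit$beta),
               coefficient = unname(fit$beta),
               nonzero = unname(fit$beta != 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
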