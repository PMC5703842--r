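#' Pipeline configuration
#'
#' All tunable parameters of the analysis stages, plus a master seed from
#' which every stochastic stage derives its own stream via
#' [derive_seed()]. Unknown arguments fail fast with the offending name.
#'
#' @param ... overrides of the defaults listed below.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # spiking model
    bin_s = 0.05, folds = 10, mixing_grid = seq(0.1, 1, by = 0.1),
    rule = "1se", representative_elapsed_s = 5,
    # LFP
    bands = c("theta", "beta"), fs_power = 200,
    peri_window = c(-3, 1), tfr_n_freqs = 40, tfr_w = 9,
    baseline = c(-1.5, -0.5), tfr_window = c(-2, 1),
    # cluster statistics
    n_perm = 1000, connectivity = 4, alpha = 0.05,
    # hazard model
    hazard_fs = 40, hazard_window_s = 0.5, hazard_bands = c("theta", "beta"),
    chains = 4, iters = 2000, warmup = 1000, thin = 5,
    stages = c("behavior", "spikes", "lfp", "clusters", "hazard")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full analysis pipeline on a session
#'
#' Executes, in order: behavioural summaries and optimal stop times; the
#' regularized Poisson spiking model per retained unit; LFP referencing,
#' artifact detection, band power and peri-stop traces; the cluster-mass
#' permutation contrast of time-frequency maps between banked and popped
#' trials; and the Bayesian hazard model of stop times from
#' channel-by-band power. Stage outputs are written as CSV under
#' `out_dir` together with a machine-readable `run_log.json` (parameters,
#' derived seeds, durations, warnings). Deterministic stages re-run with
#' the same seed produce byte-identical CSV output.
#'
#' @param session list with `trials`, `spikes`, `lfp`, `config` (from
#'   [simulate_session()] or [read_session()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results plus `log`.
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         out_dir = tempfile("stnbart_run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- session$trials
  results <- list()
  log <- list(parameters = unclass(config), stages = list())
  warns <- character()

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- withCallingHandlers(fun(), warning = function(w) {
      warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    log$stages[[name]] <<- list(
      seed = derive_seed(config$seed, name),
      duration_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    res
  }

  if ("behavior" %in% config$stages) {
    results$behavior <- run_stage("behavior", function() {
      summ <- behavioral_summary(trials)
      rl <- session$config$risk_levels
      opt <- data.frame(
        risk = rl$label,
        t_opt_s = vapply(seq_len(nrow(rl)), function(i) {
          optimal_stop_time(rl$mean_pop_s[i], rl$sd_pop_s[i],
                            session$config$reward_rate)
        }, 0)
      )
      data.table::fwrite(summ, file.path(out_dir, "behavior_summary.csv"))
      data.table::fwrite(opt, file.path(out_dir, "optimal_stops.csv"))
      list(summary = summ, optimal = opt)
    })
  }

  t_end <- session_end(trials, session$config)

  if ("spikes" %in% config$stages) {
    results$spikes <- run_stage("spikes", function() {
      sp <- filter_units(session$spikes, t_end)
      design <- build_design(trials, bin_s = config$bin_s, t_end_s = t_end)
      units <- unique(sp$unit_id)
      effects <- lapply(units, function(u) {
        counts <- bin_spikes(sp$timestamp_s[sp$unit_id == u], t_end,
                             config$bin_s)
        fit <- fit_poisson_glm(design, counts, folds = config$folds,
                               mixing_grid = config$mixing_grid,
                               rule = config$rule,
                               seed = derive_seed(config$seed, "spikes"))
        cbind(unit_id = u,
              effect_sizes(fit, config$representative_elapsed_s),
              f0_hz = fit$f0_hz)
      })
      tab <- do.call(rbind, effects)
      if (!is.null(tab)) {
        data.table::fwrite(tab, file.path(out_dir, "unit_effects.csv"))
      }
      list(effects = tab, n_units = length(units))
    })
  }

  lfp_stage <- NULL
  if (any(c("lfp", "clusters", "hazard") %in% config$stages)) {
    lfp_stage <- run_stage("lfp", function() {
      rec <- common_average_reference(session$lfp)
      mask <- detect_artifacts(rec)
      bands <- lfp_bands()
      bands <- bands[bands$name %in% config$bands, , drop = FALSE]
      bp <- lapply(seq_len(nrow(bands)), function(i) {
        band_power(rec, bands[i, ], fs_out = config$fs_power, mask = mask)
      })
      names(bp) <- bands$name
      stops <- trials$t_start_s + trials$t_stop_s
      stops <- stops[trials$type == "free" & trials$outcome == "banked"]
      traces <- lapply(names(bp), function(bn) {
        tr <- peri_event_trace(bp[[bn]], stops, window = config$peri_window,
                               average_channels = TRUE)
        data.frame(band = bn, time_s = tr$time_s, z_log_power = tr$trace)
      })
      traces <- do.call(rbind, traces)
      data.table::fwrite(traces, file.path(out_dir, "peri_stop_traces.csv"))
      list(rec = rec, mask = mask, band_power = bp, traces = traces,
           stops = stops)
    })
    results$lfp <- lfp_stage
  }

  if ("clusters" %in% config$stages) {
    results$clusters <- run_stage("clusters", function() {
      rec <- lfp_stage$rec
      fs200 <- config$fs_power
      freqs <- tfr_freqs(config$tfr_n_freqs)
      stops <- lfp_stage$stops
      pops <- trials$t_start_s + trials$t_pop_s
      pops <- pops[trials$outcome == "popped" & !is.na(trials$t_pop_s)]
      per_cond <- function(events) {
        per_ch <- lapply(seq_len(ncol(rec$signals)), function(ch) {
          x <- downsample_aa(rec$signals[, ch], rec$fs_hz, fs200)
          maps <- peri_event_tfr(x, fs200, events,
                                 window = config$tfr_window,
                                 freqs = freqs, w = config$tfr_w)
          normalize_db(maps, baseline = config$baseline)
        })
        # per-trial channel-average of dB maps
        lapply(seq_along(per_ch[[1]]), function(k) {
          tfr_mean(lapply(per_ch, `[[`, k))
        })
      }
      maps_a <- per_cond(stops)
      maps_b <- per_cond(pops)
      if (length(maps_a) < 2 || length(maps_b) < 2) {
        warning("too few trials for the cluster contrast; stage skipped")
        return(NULL)
      }
      cs <- permutation_null(maps_a, maps_b, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "clusters"),
                             connectivity = config$connectivity,
                             alpha = config$alpha)
      data.table::fwrite(cs$clusters, file.path(out_dir, "clusters.csv"))
      cs
    })
  }

  if ("hazard" %in% config$stages) {
    results$hazard <- run_stage("hazard", function() {
      rec <- lfp_stage$rec
      bands <- lfp_bands()
      bands <- bands[bands$name %in% config$hazard_bands, , drop = FALSE]
      bp40 <- lapply(seq_len(nrow(bands)), function(i) {
        band_power(rec, bands[i, ], fs_out = config$hazard_fs,
                   mask = lfp_stage$mask)
      })
      names(bp40) <- bands$name
      design <- build_hazard_design(bp40, trials, fs_hz = config$hazard_fs,
                                    window_s = config$hazard_window_s)
      fit <- fit_hazard_model(design, chains = config$chains,
                              iters = config$iters, warmup = config$warmup,
                              thin = config$thin,
                              seed = derive_seed(config$seed, "hazard"))
      data.table::fwrite(fit$summary, file.path(out_dir,
                                                "hazard_posterior.csv"))
      eff <- summarize_effects(fit)
      data.table::fwrite(eff, file.path(out_dir, "hazard_effects.csv"))
      list(fit = fit, effects = eff, design = design)
    })
  }

  log$warnings <- warns
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  results$log <- log
  results$out_dir <- out_dir
  invisible(results)
}
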