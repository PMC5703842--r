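SESSION_SCHEMA_VERSION <- 1L

TRIALS_COLS <- c("trial_id", "type", "risk", "t_start_s", "t_stop_s",
                 "t_pop_s", "t_ring_s", "outcome", "points")

#' Write a session directory
#'
#' Serializes a simulated (or imported) session as plain, language-neutral
#' files: `trials.csv`, `spikes.csv` (unit_id, timestamp_s), `lfp.csv`
#' (one column per channel), `lfp_meta.json` (sampling rate, channel ids)
#' and `config.json` (task configuration, generator parameters, seeds,
#' schema version).
#'
#' @param session list as returned by [simulate_session()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  trials <- as.data.frame(session$trials)[, TRIALS_COLS]
  data.table::fwrite(trials, file.path(path, "trials.csv"))
  data.table::fwrite(session$spikes, file.path(path, "spikes.csv"))
  lfp <- as.data.frame(session$lfp$signals)
  names(lfp) <- session$lfp$channel_ids
  data.table::fwrite(lfp, file.path(path, "lfp.csv"))
  jsonlite::write_json(
    list(fs_hz = session$lfp$fs_hz, channel_ids = session$lfp$channel_ids,
         n_samples = nrow(lfp)),
    file.path(path, "lfp_meta.json"), auto_unbox = TRUE, digits = NA
  )
  cfg <- session$config
  jsonlite::write_json(
    list(
      schema_version = SESSION_SCHEMA_VERSION,
      task = list(
        risk_levels = cfg$risk_levels, reward_rate = cfg$reward_rate,
        frac_forced = cfg$frac_forced, include_gray = cfg$include_gray,
        frac_gray = cfg$frac_gray, gray_ring_source = cfg$gray_ring_source,
        n_trials = cfg$n_trials, iti_s = cfg$iti_s,
        outcome_dur_s = cfg$outcome_dur_s, seed = cfg$seed
      ),
      neural = list(fs_hz = session$params$fs_hz,
                    n_channels = session$params$n_channels)
    ),
    file.path(path, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read and validate a session directory
#'
#' Loads the files written by [write_session()], validating the schema
#' (required files and columns, consistency between the sampling rate in
#' `config.json` and the LFP metadata). Write-then-read preserves
#' integers and strings exactly and signals to full double precision.
#'
#' @param path session directory.
#' @return list with `trials` (a `trial_table`), `spikes`, `lfp`
#'   (an `lfp_recording`) and `config` (a [task_config()]).
#' @export
read_session <- function(path) {
  need <- c("trials.csv", "spikes.csv", "lfp.csv", "lfp_meta.json",
            "config.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("session schema error in ", path, ": missing file(s) ",
         paste(missing, collapse = ", "))
  }
  trials <- as.data.frame(data.table::fread(file.path(path, "trials.csv")))
  bad <- setdiff(TRIALS_COLS, names(trials))
  if (length(bad)) {
    stop("session schema error in trials.csv: missing column(s) ",
         paste(bad, collapse = ", "))
  }
  spikes <- as.data.frame(data.table::fread(file.path(path, "spikes.csv")))
  if (!all(c("unit_id", "timestamp_s") %in% names(spikes))) {
    stop("session schema error in spikes.csv: need unit_id, timestamp_s")
  }
  meta <- jsonlite::read_json(file.path(path, "lfp_meta.json"),
                              simplifyVector = TRUE)
  meta$fs_hz <- as.numeric(meta$fs_hz)
  cfg_json <- jsonlite::read_json(file.path(path, "config.json"),
                                  simplifyVector = TRUE)
  if (!is.null(cfg_json$neural$fs_hz) &&
      cfg_json$neural$fs_hz != meta$fs_hz) {
    stop("session schema error: fs_hz mismatch between config.json (",
         cfg_json$neural$fs_hz, ") and lfp_meta.json (", meta$fs_hz, ")")
  }
  sig <- as.matrix(data.table::fread(file.path(path, "lfp.csv")))
  lfp <- structure(
    list(signals = unname(sig), fs_hz = meta$fs_hz,
         channel_ids = meta$channel_ids,
         t_s = (seq_len(nrow(sig)) - 1) / meta$fs_hz),
    class = "lfp_recording"
  )
  tk <- cfg_json$task
  config <- task_config(
    risk_levels = tk$risk_levels, reward_rate = tk$reward_rate,
    frac_forced = tk$frac_forced, include_gray = tk$include_gray,
    frac_gray = tk$frac_gray, gray_ring_source = tk$gray_ring_source,
    n_trials = tk$n_trials, iti_s = tk$iti_s,
    outcome_dur_s = tk$outcome_dur_s, seed = tk$seed
  )
  class(trials) <- c("trial_table", "data.frame")
  attr(trials, "config") <- config
  list(trials = trials, spikes = spikes, lfp = lfp, config = config)
}
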