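#' Canonical frequency bands
#'
#' delta (0.1, 4), theta (4, 8), alpha (8, 13), beta (13, 30) and gamma
#' (30, 80) Hz.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
lfp_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(0.1, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 80)
  )
}

#' Common-average reference
#'
#' Subtracts the across-channel mean from every channel at each sample,
#' removing global artifacts shared by all channels. After referencing
#' the cross-channel mean is exactly zero at every sample. A
#' single-channel recording is zeroed out entirely (degenerate case,
#' flagged with a warning).
#'
#' @param rec an `lfp_recording`.
#' @return the re-referenced `lfp_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (ncol(rec$signals) == 1L) {
    warning("common-average reference on a single channel zeroes the signal")
  }
  rec$signals <- rec$signals - rowMeans(rec$signals)
  rec
}

#' Analytic signal via the frequency domain
#' @noRd
analytic_signal <- function(x) {
  n0 <- length(x)
  # reflection-pad to a highly composite FFT length (mixed-radix FFTs on
  # near-prime lengths degrade to quadratic time); the padding also
  # softens the periodicity assumption at the ends
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) {
    ext <- min(n - n0, n0)
    x <- c(x, rev(x)[seq_len(ext)], rep(x[n0], n - n0 - ext))
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(stats::fft(x) * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Zero-phase Butterworth band-pass (order 4 per pass)
#' @noRd
bandpass_zero_phase <- function(x, fs, low, high, order = 4) {
  nyq <- fs / 2
  if (high >= nyq) stop("band edge at or above Nyquist (", nyq, " Hz)")
  # very low edges are applied as a separate high-pass for stability
  if (low / nyq < 0.005) {
    if (low > 0) {
      hp <- signal::butter(order, low / nyq, type = "high")
      x <- signal::filtfilt(hp, x)
    }
    lp <- signal::butter(order, high / nyq, type = "low")
    signal::filtfilt(lp, x)
  } else {
    bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
    signal::filtfilt(bp, x)
  }
}

#' Anti-aliased integer-factor downsampling
#' @noRd
downsample_aa <- function(x, fs, fs_out) {
  q <- fs / fs_out
  if (abs(q - round(q)) > 1e-9) {
    stop("fs must be an integer multiple of fs_out")
  }
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  lp <- signal::butter(4, 0.9 / q, type = "low")
  y <- signal::filtfilt(lp, x)
  y[seq(1, length(y), by = q)]
}

#' Instantaneous band power via the Hilbert transform
#'
#' Per channel: zero-phase band-pass at the native rate, anti-aliased
#' downsampling to `fs_out` (default 200 Hz), then the squared magnitude
#' of the analytic signal. For a pure in-band sinusoid of amplitude A the
#' power is A^2 away from the edges.
#'
#' @param rec an `lfp_recording`.
#' @param band one row of [lfp_bands()] (or any list with `name`,
#'   `low_hz`, `high_hz`).
#' @param fs_out output sampling rate, must divide the native rate.
#' @param mask optional logical matrix (samples x channels, native rate)
#'   of artifact samples from [detect_artifacts()].
#' @return object of class `band_power_series`: list with `power`
#'   (samples x channels), `fs_hz`, `band`, `mask`, `t_s`, `channel_ids`.
#' @export
band_power <- function(rec, band, fs_out = 200, mask = NULL) {
  stopifnot(inherits(rec, "lfp_recording"))
  band <- as.list(band)
  pw <- apply(rec$signals, 2, function(x) {
    xf <- bandpass_zero_phase(x, rec$fs_hz, band$low_hz, band$high_hz)
    xd <- downsample_aa(xf, rec$fs_hz, fs_out)
    Mod(analytic_signal(xd))^2
  })
  n <- nrow(pw)
  if (is.null(mask)) {
    m <- matrix(FALSE, n, ncol(pw))
  } else {
    q <- as.integer(round(rec$fs_hz / fs_out))
    m <- apply(mask, 2, function(col) {
      blocks <- ceiling(seq_along(col) / q)
      as.logical(tapply(col, blocks, any))[seq_len(n)]
    })
  }
  structure(
    list(power = pw, fs_hz = fs_out, band = band$name, mask = m,
         t_s = (seq_len(n) - 1) / fs_out, channel_ids = rec$channel_ids),
    class = "band_power_series"
  )
}

#' Detect recording artifacts
#'
#' Two rules per channel: "railing" (sustained maximal amplitude), where
#' `|x|` stays at or above `rail_frac` of the channel's absolute maximum
#' for at least `rail_min_dur_s`; and aberrant power, where the rolling
#' mean of the squared signal exceeds the channel median by more than
#' `power_k` robust (MAD-based) standard deviations. Flagged epochs are
#' padded by a guard interval on both sides.
#'
#' @param rec an `lfp_recording`.
#' @param rail_frac fraction of the channel max treated as saturation.
#' @param rail_min_dur_s minimum saturation duration.
#' @param power_k robust-SD multiplier for the power rule.
#' @param power_win_s rolling window for broadband power.
#' @param guard_s guard padding.
#' @return logical matrix (samples x channels), TRUE where masked.
#' @export
detect_artifacts <- function(rec, rail_frac = 0.999, rail_min_dur_s = 0.05,
                             power_k = 10, power_win_s = 0.1,
                             guard_s = 0.1) {
  fs <- rec$fs_hz
  win <- max(1L, as.integer(round(power_win_s * fs)))
  guard <- as.integer(round(guard_s * fs))
  min_run <- max(1L, as.integer(round(rail_min_dur_s * fs)))

  apply(rec$signals, 2, function(x) {
    n <- length(x)
    m <- rep(FALSE, n)
    # railing
    sat <- abs(x) >= rail_frac * max(abs(x))
    r <- rle(sat)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths >= min_run)) {
      m[starts[j]:ends[j]] <- TRUE
    }
    # aberrant broadband power (rolling mean of x^2)
    p <- as.numeric(stats::filter(x^2, rep(1 / win, win), sides = 2))
    p[is.na(p)] <- stats::median(p, na.rm = TRUE)
    thr <- stats::median(p) + power_k * stats::mad(p)
    m <- m | (p > thr)
    # guard dilation
    if (any(m) && guard > 0) {
      idx <- which(m)
      lo <- pmax(1, idx - guard); hi <- pmin(n, idx + guard)
      g <- rep(FALSE, n)
      for (j in seq_along(idx)) g[lo[j]:hi[j]] <- TRUE
      m <- g
    }
    m
  })
}

#' Peri-event band-power trace
#'
#' Collects band power in a window around each event, takes the median
#' across events at each time point, and expresses the result as
#' z-scored log power: the log-power series of each channel is
#' standardized to zero mean and unit variance over the whole session
#' (unmasked samples), which puts channels with different dynamic ranges
#' on a common scale. Masked samples are excluded; per-time event counts
#' are reported and time points with fewer than `min_events`
#' contributing events are `NA`.
#'
#' @param bp a `band_power_series`.
#' @param events event times in seconds on the session clock.
#' @param window numeric `c(pre, post)` in seconds relative to the event
#'   (pre is negative).
#' @param min_events minimum events per time point.
#' @param average_channels average across channels. With `zscore = TRUE`
#'   the z-scored log-power traces are averaged, giving every channel
#'   equal weight; with `zscore = FALSE` the raw power is averaged across
#'   channels before taking logs, so high-power channels dominate and can
#'   even flip the sign of a contrast carried by the majority of
#'   channels.
#' @param zscore standardize log power per channel before the median.
#' @return list with `time_s`, `trace` (time x channels, or a vector if
#'   averaged), `dispersion` (MAD across events), `n_events` per time.
#' @export
peri_event_trace <- function(bp, events, window = c(-3, 1),
                             min_events = 1L, average_channels = FALSE,
                             zscore = TRUE) {
  stopifnot(inherits(bp, "band_power_series"), window[1] < window[2])
  fs <- bp$fs_hz
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  time_s <- rel / fs
  pw <- bp$power
  if (average_channels && !zscore) {
    # raw-scale pooling: average power across channels, then log
    pw[bp$mask] <- NA
    pw <- cbind(rowMeans(pw, na.rm = TRUE))
    mask <- cbind(!is.finite(pw[, 1]))
  } else {
    mask <- bp$mask
  }
  logp <- log(pmax(pw, .Machine$double.xmin))
  logp[mask] <- NA
  if (zscore) {
    mu <- colMeans(logp, na.rm = TRUE)
    sd <- apply(logp, 2, stats::sd, na.rm = TRUE)
    logp <- sweep(sweep(logp, 2, mu), 2, sd, "/")
  }
  n <- nrow(logp)
  centers <- round(events * fs) + 1L
  nch <- ncol(logp)
  trace <- matrix(NA_real_, length(rel), nch)
  disp <- matrix(NA_real_, length(rel), nch)
  n_events <- matrix(0L, length(rel), nch)
  for (ch in seq_len(nch)) {
    ev_mat <- vapply(centers, function(c0) {
      idx <- c0 + rel
      ok <- idx >= 1 & idx <= n
      out <- rep(NA_real_, length(rel))
      out[ok] <- logp[idx[ok], ch]
      out
    }, numeric(length(rel)))
    cnt <- rowSums(!is.na(ev_mat))
    tr <- apply(ev_mat, 1, stats::median, na.rm = TRUE)
    dd <- apply(ev_mat, 1, stats::mad, na.rm = TRUE)
    tr[cnt < min_events] <- NA
    dd[cnt < min_events] <- NA
    trace[, ch] <- tr; disp[, ch] <- dd; n_events[, ch] <- cnt
  }
  ids <- if (nch == length(bp$channel_ids)) bp$channel_ids else "pooled"
  colnames(trace) <- colnames(disp) <- colnames(n_events) <- ids
  if (average_channels) {
    trace <- rowMeans(trace, na.rm = TRUE)
    disp <- rowMeans(disp, na.rm = TRUE)
  }
  list(time_s = time_s, trace = trace, dispersion = disp,
       n_events = n_events)
}

#' Default logarithmic frequency grid, 2.5-50 Hz
#' @param n number of frequencies (default 40).
#' @return numeric vector of frequencies in Hz.
#' @export
tfr_freqs <- function(n = 40) exp(seq(log(2.5), log(50), length.out = n))

#' Morlet wavelet time-frequency power
#'
#' Continuous wavelet transform with a complex Morlet of `w` cycles
#' (default 9): at frequency f the Gaussian envelope has standard
#' deviation `w / (2 pi f)` seconds. Wavelets are unit-energy normalized
#' and applied by FFT convolution with reflection padding; power is the
#' squared magnitude of the transform. Samples within one wavelet
#' half-width (3 envelope SDs) of either end are edge-flagged.
#'
#' @param x numeric signal (one channel).
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid (default [tfr_freqs()]).
#' @param w wavelet cycles parameter.
#' @return object of class `tfr_map`: list with `power` (freqs x time),
#'   `freqs`, `times`, `w`, `edge` (logical freqs x time).
#' @export
wavelet_tfr <- function(x, fs, freqs = tfr_freqs(), w = 9) {
  if (max(freqs) >= fs / 2) stop("frequency grid reaches Nyquist")
  n <- length(x)
  pad <- min(n, ceiling(3 * w / (2 * pi * min(freqs)) * fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq(n - pad + 1, n)]))
  # zero-pad to a highly composite FFT length
  np <- stats::nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, numeric(np - n - 2 * pad))
  fx <- stats::fft(xp)
  pw <- matrix(0, length(freqs), n)
  edge <- matrix(FALSE, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sd_t <- w / (2 * pi * f)
    half <- ceiling(3 * sd_t * fs)
    tt <- (-half:half) / fs
    psi <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    psi <- psi / sqrt(sum(Mod(psi)^2) / fs)           # unit energy
    kern <- complex(length.out = np)
    kern[1:(half + 1)] <- psi[(half + 1):(2 * half + 1)]
    kern[(np - half + 1):np] <- psi[1:half]
    conv <- stats::fft(fx * Conj(stats::fft(kern)), inverse = TRUE) / np
    s <- conv[pad + seq_len(n)] / sqrt(fs)
    pw[i, ] <- Mod(s)^2
    ne <- min(n, half)
    edge[i, c(seq_len(ne), seq(n - ne + 1, n))] <- TRUE
  }
  structure(list(power = pw, freqs = freqs, times = (seq_len(n) - 1) / fs,
                 w = w, edge = edge),
            class = "tfr_map")
}

#' Per-event time-frequency maps
#'
#' Computes the wavelet transform of the whole signal once and slices
#' fixed-length windows around each event, yielding one raw-power map per
#' event on a common (frequency, relative-time) grid. Events whose window
#' falls outside the recording are dropped.
#'
#' @inheritParams wavelet_tfr
#' @param events event times in seconds.
#' @param window numeric `c(pre, post)` seconds relative to the event.
#' @return list of `tfr_map` objects with `times` relative to the event.
#' @export
peri_event_tfr <- function(x, fs, events, window = c(-3, 1),
                           freqs = tfr_freqs(), w = 9) {
  tfr <- wavelet_tfr(x, fs, freqs, w)
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  n <- ncol(tfr$power)
  out <- list()
  for (ev in events) {
    idx <- round(ev * fs) + 1L + rel
    if (idx[1] < 1 || idx[length(idx)] > n) next
    out[[length(out) + 1]] <- structure(
      list(power = tfr$power[, idx, drop = FALSE], freqs = freqs,
           times = rel / fs, w = w, edge = tfr$edge[, idx, drop = FALSE]),
      class = "tfr_map")
  }
  out
}

#' Average a list of time-frequency maps
#' @param maps list of `tfr_map` objects on identical grids.
#' @return a `tfr_map` of the across-map mean power.
#' @export
tfr_mean <- function(maps) {
  stopifnot(length(maps) >= 1)
  pw <- Reduce(`+`, lapply(maps, `[[`, "power")) / length(maps)
  structure(list(power = pw, freqs = maps[[1]]$freqs,
                 times = maps[[1]]$times, w = maps[[1]]$w,
                 edge = maps[[1]]$edge),
            class = "tfr_map")
}

#' Decibel baseline normalization of time-frequency power
#'
#' Computes `I = 10 log10(P(f, t) / P0(f))` where the baseline spectrum
#' `P0(f)` is the mean power across all supplied maps (trials) within the
#' baseline interval, by default (-1.5, -0.5) s relative to the aligned
#' event. Where `P = P0` the normalized map is exactly 0 dB.
#'
#' @param x a `tfr_map` or a list of per-trial `tfr_map`s; for a list,
#'   the baseline is pooled over trials and every map is normalized by
#'   the same `P0(f)`, so the result is a list of per-trial dB maps.
#' @param baseline numeric `c(from, to)` in the maps' time units.
#' @param p0 optional externally computed baseline spectrum.
#' @return normalized `tfr_map` (or list thereof) with attribute `p0`.
#' @export
normalize_db <- function(x, baseline = c(-1.5, -0.5), p0 = NULL) {
  single <- inherits(x, "tfr_map")
  maps <- if (single) list(x) else x
  times <- maps[[1]]$times
  if (is.null(p0)) {
    sel <- times >= baseline[1] & times <= baseline[2]
    if (!any(sel)) stop("baseline interval outside the map time grid")
    p0 <- rowMeans(
      do.call(cbind, lapply(maps, function(m) rowMeans(m$power[, sel,
                                                               drop = FALSE])))
    )
  }
  out <- lapply(maps, function(m) {
    # as a log difference: P = P0 maps to exactly 0 dB
    m$power <- 10 * (log10(m$power) - log10(p0))
    attr(m, "p0") <- p0
    attr(m, "scale") <- "dB"
    m
  })
  if (single) out[[1]] else out
}

#' Condition-contrast map in decibels
#'
#' `I = 10 log10(P1 / P2)` between the mean raw-power maps of two
#' conditions; no baseline normalization is applied, so the map is
#' antisymmetric under swapping the conditions.
#'
#' @param a,b `tfr_map`s or lists of per-trial maps (averaged first).
#' @return a `tfr_map` in dB.
#' @export
contrast_db <- function(a, b) {
  if (!inherits(a, "tfr_map")) a <- tfr_mean(a)
  if (!inherits(b, "tfr_map")) b <- tfr_mean(b)
  stopifnot(all(dim(a$power) == dim(b$power)))
  # as a log difference, so swapping conditions flips the sign exactly
  a$power <- 10 * (log10(a$power) - log10(b$power))
  attr(a, "scale") <- "dB contrast"
  a
}
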