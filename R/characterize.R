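#' Periodogram of a firing-rate series
#'
#' Rectangular-window periodogram of the mean-subtracted series, one-sided
#' with DC excluded, normalized to the series' total power:
#' `PSD(f_j) = 2 |FFT(x - mean(x))_j|^2 / (n * sum((x - mean(x))^2))`, so
#' the values are the fraction of rate variance at each frequency and a
#' pure sinusoid concentrates PSD = 1 at its frequency (0 dB). Adding
#' broadband noise dilutes the fraction at the stimulus harmonics, which is
#' what the responsiveness index is meant to detect. Set
#' `normalize = FALSE` for the raw (power-scaled) periodogram.
#'
#' @param rate numeric vector of binned firing rates (spikes/s).
#' @param fs_hz sampling frequency of the series (1000 / bin width in ms).
#' @param normalize divide by total power (default TRUE).
#' @return data.frame with `freq_hz` and `psd`.
#' @export
rate_psd <- function(rate, fs_hz, normalize = TRUE) {
  n <- length(rate)
  if (n < 4) stop("rate series too short for a periodogram", call. = FALSE)
  x <- rate - mean(rate)
  p <- 2 * Mod(stats::fft(x))^2 / n
  if (normalize) {
    ss <- sum(x^2)                    # Parseval: sum_k |X_k|^2 = n * ss
    p <- if (ss > 0) p / ss else p * 0
  }
  half <- seq_len(n %/% 2)            # positive frequencies, DC excluded
  data.frame(freq_hz = half * fs_hz / n, psd = p[half + 1L])
}

#' Responsiveness index of a neuron
#'
#' Power of the binned firing rate at the stimulus frequency and its first
#' two harmonics, in decibels:
#' `R = 10 log10 max(PSD(f), PSD(2f), PSD(3f))` with `f` the stimulus
#' frequency (2 Hz for the canonical 200 ms ON / 300 ms OFF cycle). The
#' periodogram bin nearest each harmonic is used. Responsive,
#' stimulus-locked neurons concentrate power at these frequencies and score
#' high `R`.
#'
#' @param rate numeric vector of binned firing rates of one neuron.
#' @param fs_hz sampling frequency of `rate` in Hz.
#' @param f_hz stimulus frequency (default 2 Hz).
#' @param floor_db value returned (with a warning) when there is no power at
#'   any harmonic, e.g. for a constant rate.
#' @return list with `R_db`, `harmonic_max` (the max PSD value), `psd`.
#' @export
responsiveness_index <- function(rate, fs_hz, f_hz = 2.0, floor_db = -100) {
  check_positive(fs_hz, "fs_hz"); check_positive(f_hz, "f_hz")
  if (length(rate) * f_hz / fs_hz < 3) {
    stop("rate series shorter than 3 stimulus periods", call. = FALSE)
  }
  if (3 * f_hz > fs_hz / 2) {
    stop("third harmonic above the Nyquist frequency of the rate series",
         call. = FALSE)
  }
  spec <- rate_psd(rate, fs_hz)
  pick <- vapply(c(1, 2, 3) * f_hz, function(f) {
    spec$psd[which.min(abs(spec$freq_hz - f))]
  }, numeric(1))
  hm <- max(pick)
  if (hm <= 0) {
    warning("no power at the stimulus harmonics; returning floor")
    return(list(R_db = floor_db, harmonic_max = 0, psd = spec, floored = TRUE))
  }
  list(R_db = 10 * log10(hm), harmonic_max = hm, psd = spec, floored = FALSE)
}

#' Min-max normalize responsiveness indices across a population
#'
#' Maps the population's responsiveness values onto `[0, 1]`:
#' `(R - min) / (max - min)` (the default), so the least responsive neuron
#' maps to 0 and the most responsive to 1. `denominator = "max"` divides by
#' the maximum instead of the range.
#'
#' @param R_db numeric vector of per-neuron responsiveness indices (dB).
#' @param denominator `"range"` or `"max"`.
#' @export
normalize_responsiveness <- function(R_db, denominator = c("range", "max")) {
  denominator <- match.arg(denominator)
  rng <- range(R_db)
  if (diff(rng) == 0) {
    warning("all responsiveness values equal; returning zeros")
    return(rep(0, length(R_db)))
  }
  den <- if (denominator == "range") diff(rng) else rng[2]
  (R_db - rng[1]) / den
}

#' Transient-sustained ratio and temporal class
#'
#' `tsr = Spk_t / Spk_s`, where `Spk_t` is the mean number of spikes per
#' trial inside the transient windows (`window_ms` after stimulus onset and
#' after stimulus offset) and `Spk_s` the mean number of spikes per trial
#' over the entire trial (ON + OFF). A neuron is classified transient when
#' `tsr > 0.5`, sustained otherwise. A neuron firing uniformly over a
#' 500 ms trial scores `tsr = 200/500 = 0.4`.
#'
#' @param spikes a `spike_data` object.
#' @param markers trial markers (default: carried by `spikes`).
#' @param neuron column index of the neuron (default: all).
#' @param window_ms transient window length (default 100 ms).
#' @return data.frame with `neuron`, `spk_t`, `spk_s`, `tsr`,
#'   `temporal_class`.
#' @export
transient_sustained_ratio <- function(spikes, markers = spikes$markers,
                                      neuron = NULL, window_ms = 100) {
  stopifnot(inherits(spikes, "spike_data"))
  if (is.null(markers) || !nrow(markers)) stop("no trial markers", call. = FALSE)
  on_ms <- spikes$on_ms %||% 200
  trial_len <- spikes$trial_len_ms %||% 500
  neuron <- neuron %||% seq_len(ncol(spikes$trains))
  tt <- nrow(spikes$trains)
  res <- lapply(neuron, function(i) {
    tot <- 0; trans <- 0
    for (tr in seq_len(nrow(markers))) {
      a <- markers$onset_ms[tr]
      seg <- spikes$trains[(a + 1):min(a + trial_len, tt), i]
      tot <- tot + sum(seg)
      w1 <- seg[seq_len(min(window_ms, length(seg)))]
      w2 <- if (length(seg) > on_ms) {
        seg[(on_ms + 1):min(on_ms + window_ms, length(seg))]
      } else numeric(0)
      trans <- trans + sum(w1) + sum(w2)
    }
    if (tot == 0) {
      stop(sprintf("neuron %d fired no spikes; tsr undefined", i),
           call. = FALSE)
    }
    nt <- nrow(markers)
    data.frame(neuron = i, spk_t = trans / nt, spk_s = tot / nt,
               tsr = trans / tot,
               temporal_class = if (trans / tot > 0.5) "transient" else "sustained")
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike-triggered average and receptive field
#'
#' For each spike, the `lag_ms` window of stimulus frames preceding it is
#' extracted and averaged across spikes, giving a per-pixel STA trace
#' (`sta[l, p]` = mean intensity of pixel `p`, `l` ms before the spike).
#' Integrating the STA over time per pixel and min-max normalizing yields
#' the receptive-field matrix.
#'
#' @param spikes a `spike_data` object.
#' @param stim the driving [stim_sequence()].
#' @param neuron neuron column index.
#' @param lag_ms STA window length (default 500 ms, one trial).
#' @return list with `sta` (lag_ms x P; row 1 = 1 ms before the spike),
#'   `rf` (rows x cols matrix, min-max normalized), `rf_raw`, `n_spikes`.
#' @export
sta_receptive_field <- function(spikes, stim, neuron = 1, lag_ms = 500) {
  stopifnot(inherits(spikes, "spike_data"), inherits(stim, "stim_sequence"))
  lag_ms <- check_count(lag_ms, "lag_ms")
  spk <- which(spikes$trains[, neuron] == 1L)   # 1-based ms bins
  spk <- spk[spk > lag_ms]
  ns <- length(spk)
  if (ns == 0) stop("no usable spikes after the first lag window", call. = FALSE)
  if (ns < 100) warning("fewer than 100 spikes; STA will be noisy")
  frames <- stim_frames(stim)                   # ms t occupies row t (0-based t -> row t+1)
  p <- ncol(frames)
  # sta[l, p] = mean over spikes of frames[t_s - l, p]: a lagged
  # cross-correlation between each pixel's time course and the spike
  # vector, computed via zero-padded FFT
  tt <- nrow(frames)
  pad <- stats::nextn(tt + lag_ms, 2)
  sv <- numeric(pad); sv[spk] <- 1
  s_fft <- stats::fft(sv)
  sta <- matrix(0, lag_ms, p)
  for (px in seq_len(p)) {
    xv <- numeric(pad); xv[seq_len(tt)] <- frames[, px]
    cc <- Re(stats::fft(stats::fft(xv) * Conj(s_fft), inverse = TRUE)) / pad
    # cc[pad - l + 1] = sum_t x[t] * s[t + l] for lag l >= 1
    sta[, px] <- cc[pad - seq_len(lag_ms) + 1L] / ns
  }
  rf_raw <- colSums(sta)
  rng <- range(rf_raw)
  rf_norm <- if (diff(rng) > 0) (rf_raw - rng[1]) / diff(rng) else rf_raw * 0
  rf <- matrix(rf_norm, stim$grid[1], stim$grid[2], byrow = TRUE)
  list(sta = sta, rf = rf, rf_raw = rf_raw, n_spikes = ns,
       grid = stim$grid, on_ms = stim$on_ms)
}

#' Classify a neuron as spatial-ON or spatial-OFF
#'
#' Examines the STA trace of the pixel with the maximum receptive-field
#' response: a high STA value at short pre-spike lags (the stimulus was lit
#' just before the spikes fired) marks an ON neuron; a low value marks an
#' OFF neuron. "High"/"low" is judged against the mean of the full STA
#' window for that pixel. The short-lag window should not exceed the
#' typical response latency, otherwise offset-locked spikes (which closely
#' trail the lit period) leak into it.
#'
#' @param sta_result output of [sta_receptive_field()].
#' @param short_lag_ms extent of the short-lag window, ms.
#' @return `"ON"` or `"OFF"`.
#' @export
classify_on_off <- function(sta_result, short_lag_ms = 50) {
  sta <- sta_result$sta
  dev <- colSums(sta) - mean(colSums(sta))
  best <- which.max(abs(dev))       # strongest deviation: the driving pixel
  # excess of the best pixel's STA over the across-pixel average at each
  # lag: a shuffle control that removes the trial-phase structure shared by
  # all pixels and keeps only pattern-specific enrichment
  excess <- sta[, best] - rowMeans(sta)
  n_lag <- length(excess)
  short <- mean(excess[seq_len(min(short_lag_ms, n_lag))])
  mid <- mean(excess[min(short_lag_ms + 1L, n_lag):min(300L, n_lag)])
  # the comparison is antisymmetric in the STA sign: negating the traces
  # flips the label
  if (short >= 0.5 * mid) "ON" else "OFF"
}

#' Responsiveness-adjusted prediction correlation
#'
#' `adjusted = (corr + (1 - R_norm)) / 2`, mapping `[0,1] x [0,1]` into
#' `[0,1]`; it discounts the prediction correlation of highly responsive
#' neurons so model quality can be compared across response classes without
#' conflating it with stimulus locking. Negative correlations are clipped
#' to 0 with a warning (the measure assumes correlations in `[0, 1]`).
#'
#' @param corr prediction correlation(s) in `[0, 1]`.
#' @param R_norm normalized responsiveness value(s) in `[0, 1]` from
#'   [normalize_responsiveness()].
#' @export
adjusted_correlation <- function(corr, R_norm) {
  if (any(corr < 0)) {
    warning("negative correlations clipped to 0")
    corr <- pmax(corr, 0)
  }
  if (any(corr > 1) || any(R_norm < 0) || any(R_norm > 1)) {
    stop("corr must be in [0,1] and R_norm in [0,1]", call. = FALSE)
  }
  (corr + (1 - R_norm)) / 2
}

#' Full spatiotemporal profile of a population
#'
#' Convenience wrapper running [responsiveness_index()],
#' [transient_sustained_ratio()], [sta_receptive_field()] and
#' [classify_on_off()] for every neuron.
#'
#' @param spikes a `spike_data` object.
#' @param stim the driving stimulus.
#' @param w_ms rate bin width used for the responsiveness periodogram.
#' @param lag_ms STA window.
#' @return data.frame, one row per neuron: `R_db`, `R_norm`, `tsr`,
#'   `temporal_class`, `rf_row`, `rf_col`, `spatial_class`.
#' @export
profile_population <- function(spikes, stim, w_ms = 50, lag_ms = 500) {
  rm_ <- bin_rates(spikes, w_ms)
  f_hz <- 1000 / stim$trial_len_ms
  n <- ncol(spikes$trains)
  r_db <- vapply(seq_len(n), function(i) {
    responsiveness_index(rm_$rates[, i], fs_hz = 1000 / w_ms, f_hz = f_hz)$R_db
  }, numeric(1))
  tsr_tab <- transient_sustained_ratio(spikes)
  rf_row <- integer(n); rf_col <- integer(n); sclass <- character(n)
  for (i in seq_len(n)) {
    sta <- suppressWarnings(sta_receptive_field(spikes, stim, neuron = i,
                                                lag_ms = lag_ms))
    pk <- which(sta$rf == max(sta$rf), arr.ind = TRUE)[1, ]
    rf_row[i] <- pk[1]; rf_col[i] <- pk[2]
    sclass[i] <- classify_on_off(sta)
  }
  data.frame(
    neuron = seq_len(n), R_db = r_db,
    R_norm = normalize_responsiveness(r_db),
    tsr = tsr_tab$tsr, temporal_class = tsr_tab$temporal_class,
    rf_row = rf_row, rf_col = rf_col, spatial_class = sclass
  )
}
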