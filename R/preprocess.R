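#' Detect spikes in a raw extracellular trace
#'
#' Negative threshold crossings at `k` times the robustly estimated noise
#' standard deviation (median absolute value / 0.6745, so embedded spikes do
#' not inflate the threshold). Each detection is cut into a snippet from
#' `pre_ms` before to `post_ms` after the crossing sample; crossings closer
#' than `refractory_ms` are merged, keeping the larger excursion. Snippets
#' whose window falls outside the trace are dropped.
#'
#' Sample counts are rounded up: 0.75 ms at 25 kHz (18.75 samples) becomes
#' 19 pre-samples; 2 ms becomes 50 post-samples; a snippet is then
#' `pre + post + 1` samples long.
#'
#' @param trace numeric vector, band-passed extracellular signal.
#' @param fs sampling rate, Hz.
#' @param k threshold multiplier (default 3).
#' @param pre_ms,post_ms cut window around the crossing, ms.
#' @param refractory_ms merge window for nearby crossings.
#' @return A `waveform_set`: `snippets` (n_spikes x n_samples), `spike_times`
#'   (crossing sample indices), `threshold`, `noise_sd`, `fs`, `pre_n`,
#'   `post_n`.
#' @export
detect_spikes <- function(trace, fs = 25000, k = 3, pre_ms = 0.75,
                          post_ms = 2.0, refractory_ms = 1.0) {
  check_positive(fs, "fs"); check_positive(k, "k")
  noise_sd <- stats::median(abs(trace)) / 0.6745
  if (noise_sd == 0) stop("flat trace: noise SD is zero", call. = FALSE)
  thr <- k * noise_sd
  pre_n <- ceiling(pre_ms * fs / 1000)
  post_n <- ceiling(post_ms * fs / 1000)
  if (length(trace) <= pre_n + post_n) {
    stop("trace shorter than one snippet window", call. = FALSE)
  }
  below <- trace < -thr
  # first sample of each below-threshold run
  starts <- which(below & !c(FALSE, below[-length(below)]))
  if (length(starts)) {
    # merge crossings within the refractory window, keep larger excursion
    ref_n <- round(refractory_ms * fs / 1000)
    keep <- integer(0)
    cur <- starts[1]
    cur_min <- min(trace[cur:min(cur + ref_n, length(trace))])
    for (s in starts[-1]) {
      if (s - cur <= ref_n) {
        m <- min(trace[s:min(s + ref_n, length(trace))])
        if (m < cur_min) { cur <- s; cur_min <- m }
      } else {
        keep <- c(keep, cur)
        cur <- s
        cur_min <- min(trace[cur:min(cur + ref_n, length(trace))])
      }
    }
    starts <- c(keep, cur)
  }
  starts <- starts[starts - pre_n >= 1 & starts + post_n <= length(trace)]
  snippets <- matrix(0, length(starts), pre_n + post_n + 1L)
  for (i in seq_along(starts)) {
    snippets[i, ] <- trace[(starts[i] - pre_n):(starts[i] + post_n)]
  }
  structure(
    list(snippets = snippets, spike_times = starts, threshold = thr,
         noise_sd = noise_sd, fs = fs, pre_n = pre_n, post_n = post_n,
         channel_id = 1L),
    class = "waveform_set"
  )
}

#' Align waveform snippets at their trough
#'
#' Shifts every snippet so the sample of minimum voltage sits at a common
#' index (the median trough index of the set); vacated samples are padded
#' with the snippet's edge value and `spike_times` are shifted by the same
#' amount. After alignment the trough index is identical for all snippets.
#'
#' @param ws a `waveform_set` from [detect_spikes()].
#' @export
align_troughs <- function(ws) {
  stopifnot(inherits(ws, "waveform_set"))
  if (!nrow(ws$snippets)) return(ws)
  troughs <- apply(ws$snippets, 1, which.min)
  target <- as.integer(round(stats::median(troughs)))
  shifts <- troughs - target        # positive: trough late -> shift left
  ns <- ncol(ws$snippets)
  out <- ws$snippets
  for (i in which(shifts != 0)) {
    s <- shifts[i]; v <- ws$snippets[i, ]
    out[i, ] <- if (s > 0) c(v[(s + 1):ns], rep(v[ns], s))
                else c(rep(v[1], -s), v[1:(ns + s)])
  }
  ws$snippets <- out
  ws$spike_times <- ws$spike_times + shifts
  ws$trough_index <- target
  ws
}

#' Cluster waveforms into single units
#'
#' Projects trough-aligned snippets onto their first two principal
#' components and clusters the scores with K-means. The number of units is
#' supplied by the caller (mirroring the manual choice made during sorting).
#' Initialization uses a seeded k-means++ start so labels are deterministic
#' under a fixed seed.
#'
#' @param ws a `waveform_set` (align first with [align_troughs()]).
#' @param n_units number of clusters.
#' @param seed RNG seed.
#' @return list with `labels`, `scores` (n_spikes x 2), `centers`.
#' @export
sort_units <- function(ws, n_units, seed = 1) {
  stopifnot(inherits(ws, "waveform_set"))
  n_units <- check_count(n_units, "n_units")
  n_spk <- nrow(ws$snippets)
  if (n_units > n_spk) {
    stop("n_units exceeds the number of detected spikes", call. = FALSE)
  }
  pc <- stats::prcomp(ws$snippets, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (n_units == 1L) {
    return(list(labels = rep(1L, n_spk), scores = scores,
                centers = matrix(colMeans(scores), 1)))
  }
  km <- with_seed(seed, {
    centers <- kmeanspp_init(scores, n_units)
    stats::kmeans(scores, centers = centers, iter.max = 100)
  })
  list(labels = km$cluster, scores = scores, centers = km$centers)
}

# k-means++ seeding on the score matrix
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(x, 1, function(r) {
      min(colSums((t(x[idx, , drop = FALSE]) - r)^2))
    })
    if (sum(d2) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  x[idx, , drop = FALSE]
}

#' Bin spike trains into firing rates
#'
#' Bin `k` (1-based) covers the interval `((k-1) w, k w]` in ms; the rate is
#' the spike count in the bin divided by `w` in seconds (spikes/s). A
#' trailing partial bin shorter than `w` is dropped.
#'
#' @param spikes a `spike_data` object.
#' @param w_ms bin width in ms (10 and 50 are the conventional choices).
#' @return A `rate_matrix`: `rates` (n_bins x N, spikes/s), `w_ms`, `t0`.
#' @export
bin_rates <- function(spikes, w_ms) {
  stopifnot(inherits(spikes, "spike_data"))
  w_ms <- check_count(w_ms, "w_ms")
  tt <- nrow(spikes$trains)
  n_bins <- tt %/% w_ms
  if (n_bins < 1L) stop("recording shorter than one bin", call. = FALSE)
  grp <- rep(seq_len(n_bins), each = w_ms)
  counts <- rowsum(spikes$trains[seq_len(n_bins * w_ms), , drop = FALSE], grp)
  dimnames(counts) <- NULL
  structure(
    list(rates = counts / (w_ms / 1000), counts = counts, w_ms = w_ms,
         t0 = 0, markers = spikes$markers, trial_len_ms = spikes$trial_len_ms),
    class = "rate_matrix"
  )
}

#' Post-stimulus time histogram and raster
#'
#' Aligns spikes to trial onsets and tabulates counts in `bin_ms` bins,
#' averaged across trials (counts per trial per bin). Also returns the
#' raster: per-trial spike times relative to onset.
#'
#' @param spikes a `spike_data` object.
#' @param markers trial markers (defaults to those carried by `spikes`).
#' @param bin_ms histogram bin width (default 10 ms).
#' @param window_ms analysis window after onset (defaults to the trial
#'   length).
#' @return list with `psth` (n_bins x N matrix, mean counts/trial),
#'   `bin_centers_ms`, `raster` (list over neurons of lists over trials).
#' @export
psth <- function(spikes, markers = spikes$markers, bin_ms = 10,
                 window_ms = NULL) {
  stopifnot(inherits(spikes, "spike_data"))
  if (is.null(markers) || !nrow(markers)) stop("no trial markers", call. = FALSE)
  if (is.null(window_ms)) {
    window_ms <- if (!is.null(spikes$trial_len_ms)) spikes$trial_len_ms else 500
  }
  n_bins <- window_ms %/% bin_ms
  n <- ncol(spikes$trains)
  counts <- matrix(0, n_bins, n)
  raster <- rep(list(vector("list", nrow(markers))), n)
  for (tr in seq_len(nrow(markers))) {
    a <- markers$onset_ms[tr] + 1L
    b <- min(a + window_ms - 1L, nrow(spikes$trains))
    seg <- spikes$trains[a:b, , drop = FALSE]
    for (i in seq_len(n)) {
      rel <- which(seg[, i] == 1L) - 1L   # 0-based ms relative to onset
      raster[[i]][[tr]] <- rel
      if (length(rel)) {
        counts[, i] <- counts[, i] +
          tabulate(rel %/% bin_ms + 1L, nbins = n_bins)
      }
    }
  }
  list(psth = counts / nrow(markers),
       bin_centers_ms = (seq_len(n_bins) - 0.5) * bin_ms,
       raster = raster, bin_ms = bin_ms, n_trials = nrow(markers))
}
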