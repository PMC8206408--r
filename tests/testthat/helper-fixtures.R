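# Shared fixtures, built in code at test time.

# small checkerboard population with planted, recoverable phenotypes;
# memoised per session because several test files reuse it
planted_population <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    stim <- make_checkerboard(n_patterns = 32, pixels_per_pattern = 4,
                              trials = 25, seed = 77)
    specs <- lapply(1:8, function(i) neuron_spec(
      rf_center = c((i - 1) %% 4 + 1, ((i - 1) %% 8) + 1), rf_sigma = 0.8,
      polarity = if (i %% 2) "ON" else "OFF",
      kernel = if (i <= 5) "transient" else "sustained",
      snr = 0.8 + 0.02 * i
    ))
    spikes <- simulate_population(stim, specs, seed = 78)
    cache <<- list(stim = stim, specs = specs, spikes = spikes)
    cache
  }
})

# two-unit raw-trace fixture with well-spaced spikes
two_unit_trace <- function(n_per = 100, spacing_ms = 20, amp = 10, seed = 6) {
  ev <- data.frame(neuron_id = rep(1:2, n_per),
                   time_ms = seq(10, by = spacing_ms, length.out = 2 * n_per))
  sp <- spike_data_from_events(ev, 2, max(ev$time_ms) + 60)
  raw <- simulate_raw_trace(sp, template_amplitude = amp, noise_sd = 1,
                            seed = seed)
  labels <- rep(1:2, times = lengths(raw$spike_samples))
  times <- unlist(raw$spike_samples)
  list(raw = raw, truth_times = times, truth_labels = labels)
}

# label agreement up to permutation for 2 clusters
label_agreement2 <- function(labels, truth) {
  tab <- table(labels, truth)
  max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
}

# brute-force "same"-padded temporal convolution: the independent oracle
# for the conv layer (dot products written out directly)
conv_oracle <- function(x, w, b, f) {
  len <- nrow(x); cin <- ncol(x); k <- ncol(w)
  pad_l <- (f - 1) %/% 2
  out <- matrix(0, len, k)
  for (t in seq_len(len)) {
    for (j in seq_len(k)) {
      acc <- b[j]
      for (o in seq_len(f)) {
        src <- t + o - 1 - pad_l
        if (src >= 1 && src <= len) {
          for (c in seq_len(cin)) {
            acc <- acc + x[src, c] * w[(o - 1) * cin + c, j]
          }
        }
      }
      out[t, j] <- acc
    }
  }
  out
}

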