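#' Specify one synthetic LGN neuron
#'
#' Parameters of a linear-nonlinear-Poisson (LNP) model neuron used by
#' [simulate_population()]. The neuron carries a Gaussian spatial receptive
#' field (peak weight 1 at `rf_center`), a temporal kernel shaping its
#' response to luminance transitions, and a `snr` factor in `[0, 1]` scaling
#' how strongly its firing locks to the stimulus (0 = pure background
#' Poisson firing, 1 = fully stimulus-driven).
#'
#' @param rf_center `c(row, col)` receptive-field centre on the pixel grid.
#' @param rf_sigma Gaussian RF width in pixels.
#' @param polarity `"ON"` (driven by light onset) or `"OFF"` (light offset).
#' @param kernel `"transient"` (exponential decay, 50 ms time constant) or
#'   `"sustained"` (boxcar spanning the trial, giving maintained firing).
#' @param onset_gain,offset_gain response gains at the preferred and
#'   non-preferred luminance transition, spikes/s at kernel peak.
#' @param baseline background firing rate, spikes/s.
#' @param snr stimulus-locking factor in `[0, 1]`.
#' @param coupling optional numeric vector of weights (spikes/s per unit of
#'   a 10 ms exponential trace of the other neurons' spiking); length = the
#'   simulated population size, entry for the neuron itself ignored.
#' @return A `neuron_spec` list.
#' @export
neuron_spec <- function(rf_center = c(2, 4), rf_sigma = 0.75,
                        polarity = c("ON", "OFF"),
                        kernel = c("transient", "sustained"),
                        onset_gain = 120, offset_gain = 20, baseline = 4,
                        snr = 0.8, coupling = NULL) {
  polarity <- match.arg(polarity)
  kernel <- match.arg(kernel)
  stopifnot(onset_gain >= 0, offset_gain >= 0, baseline >= 0,
            snr >= 0, snr <= 1, length(rf_center) == 2)
  structure(
    list(rf_center = as.numeric(rf_center), rf_sigma = rf_sigma,
         polarity = polarity, kernel = kernel,
         onset_gain = onset_gain, offset_gain = offset_gain,
         baseline = baseline, snr = snr, coupling = coupling),
    class = "neuron_spec"
  )
}

#' Default synthetic LGN population preset
#'
#' Builds `n` neuron specs emulating the composition reported for rat LGN
#' recordings: populations of roughly a dozen neurons per animal, a 60/40
#' transient/sustained split, a 60/40 ON/OFF split, receptive-field centres
#' spread over the grid and stimulus locking `snr ~ Uniform(0.2, 1)`.
#'
#' @param n population size (default 12).
#' @param grid pixel grid the RF centres live on.
#' @param seed RNG seed.
#' @param snr_range range of the uniform stimulus-locking draw.
#' @param coupling_sd if positive, each neuron receives couplings drawn from
#'   `Normal(0, coupling_sd)` (self-weight zero), giving the population
#'   spike-history structure.
#' @return list of [neuron_spec()] objects.
#' @export
lgn_population <- function(n = 12, grid = c(4, 8), seed = 1,
                           snr_range = c(0.2, 1), coupling_sd = 0) {
  n <- check_count(n, "n")
  with_seed(seed, {
    n_trans <- round(0.6 * n)
    kernels <- sample(c(rep("transient", n_trans), rep("sustained", n - n_trans)))
    n_on <- round(0.6 * n)
    pols <- sample(c(rep("ON", n_on), rep("OFF", n - n_on)))
    snr <- stats::runif(n, snr_range[1], snr_range[2])
    lapply(seq_len(n), function(i) {
      cp <- NULL
      if (coupling_sd > 0) {
        cp <- stats::rnorm(n, 0, coupling_sd)
        cp[i] <- 0
      }
      neuron_spec(
        rf_center = c(sample(seq_len(grid[1]), 1), sample(seq_len(grid[2]), 1)),
        rf_sigma = stats::runif(1, 0.6, 1.1),
        polarity = pols[i], kernel = kernels[i],
        onset_gain = stats::runif(1, 80, 160),
        offset_gain = stats::runif(1, 10, 35),
        baseline = stats::runif(1, 2, 8),
        snr = snr[i], coupling = cp
      )
    })
  })
}

# Gaussian RF weights over the grid pixels (row-major order), peak 1.
rf_weights <- function(spec, grid) {
  rows <- rep(seq_len(grid[1]), each = grid[2])
  cols <- rep(seq_len(grid[2]), times = grid[1])
  d2 <- (rows - spec$rf_center[1])^2 + (cols - spec$rf_center[2])^2
  exp(-d2 / (2 * spec$rf_sigma^2))
}

# Temporal kernels carry a 30 ms response latency (retina-to-LGN conduction
# and integration): without it the stimulus value immediately preceding a
# spike is uninformative about polarity and ON/OFF classification from the
# STA degenerates. The sustained kernel is a boxcar of 0.9 x trial length
# (450 ms for the canonical 500 ms trial): any 200 ms boxcar puts exactly
# half its mass inside the transient windows [onset, onset+100) u
# [offset, offset+100) and parks sustained neurons on the tsr = 0.5 class
# boundary, while a near-trial-spanning boxcar gives tsr ~ 0.4 (the
# uniform-firing value) with a wide margin.
lgn_latency_ms <- 30L

temporal_kernel <- function(kind, trial_len_ms = 500) {
  lat <- rep(0, lgn_latency_ms)
  if (kind == "transient") {
    c(lat, exp(-(0:269) / 50))   # peak 1, ~50 ms decay
  } else {
    c(lat, rep(1, round(0.9 * trial_len_ms)))
  }
}

#' Simulate an LNP population driven by a stimulus sequence
#'
#' Each neuron's intensity is
#' `lambda_i(t) = baseline + snr * (onset_gain * (k_i * e_on)(t) +
#' offset_gain * (k_i * e_off)(t))` where `e_on`/`e_off` are impulse trains
#' at the trial luminance transitions weighted by the RF-weighted pattern
#' amplitude, and `k_i` is the neuron's temporal kernel. For OFF-polarity
#' neurons the onset and offset roles are swapped (the rectified negative
#' temporal derivative of the RF drive plays the role of the onset drive).
#' Spikes are drawn Bernoulli(`lambda * 1 ms`) per millisecond, which
#' approximates a Poisson process for `lambda * dt << 1`; the product is
#' clipped at 1 with a warning. With nonzero `coupling` weights the
#' simulation runs sequentially, adding each neuron's coupling-weighted
#' 10 ms exponential trace of the population's past spiking.
#'
#' @param stim a [stim_sequence()].
#' @param specs list of [neuron_spec()] objects.
#' @param seed RNG seed; output is bit-reproducible.
#' @param return_rate also return the noiseless intensity matrix (spikes/s).
#' @return A `spike_data` object: `trains` (T x N integer 0/1 matrix at 1 ms
#'   resolution), `markers` (shared with the stimulus), `on_ms`, `off_ms`,
#'   `grid`, and (optionally) `lambda`.
#' @export
simulate_population <- function(stim, specs, seed = 1, return_rate = FALSE) {
  stopifnot(inherits(stim, "stim_sequence"), length(specs) >= 1)
  n <- length(specs)
  tt <- stim$total_ms
  lambda <- matrix(0, tt, n)
  onsets <- stim$markers$onset_ms + 1L          # 1-based ms index
  offsets <- stim$markers$onset_ms + stim$on_ms + 1L
  offsets <- offsets[offsets <= tt]
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    w <- rf_weights(sp, stim$grid)
    amp <- as.numeric(stim$patterns %*% w)[stim$markers$pattern]
    ev_on <- numeric(tt); ev_off <- numeric(tt)
    if (sp$polarity == "ON") {
      ev_on[onsets] <- amp
      ev_off[offsets] <- amp[seq_along(offsets)]
    } else {
      ev_on[offsets] <- amp[seq_along(offsets)]
      ev_off[onsets] <- amp
    }
    k <- temporal_kernel(sp$kernel, stim$trial_len_ms)
    drive <- sp$onset_gain * causal_conv(ev_on, k) +
      sp$offset_gain * causal_conv(ev_off, k)
    lambda[, i] <- sp$baseline + sp$snr * drive
  }
  prob <- lambda / 1000
  if (any(prob > 1)) {
    warning("lambda * dt exceeded 1 for some bins; clipped")
    prob[prob > 1] <- 1
  }
  coupled <- any(vapply(specs, function(s) !is.null(s$coupling) &&
                          any(s$coupling != 0), logical(1)))
  trains <- with_seed(seed, {
    if (!coupled) {
      matrix(as.integer(stats::runif(tt * n) < prob), tt, n)
    } else {
      cmat <- t(vapply(specs, function(s) {
        if (is.null(s$coupling)) numeric(n) else s$coupling
      }, numeric(n)))                       # cmat[i, j]: j's trace -> i
      diag(cmat) <- 0
      u <- matrix(stats::runif(tt * n), tt, n)
      out <- matrix(0L, tt, n)
      h <- numeric(n)
      decay <- exp(-1 / 10)
      for (t in seq_len(tt)) {
        p <- prob[t, ] + pmax(cmat %*% h, 0) / 1000
        s <- as.integer(u[t, ] < pmin(p, 1))
        out[t, ] <- s
        h <- h * decay + s
      }
      out
    }
  })
  res <- structure(
    list(trains = trains, neuron_ids = seq_len(n), markers = stim$markers,
         on_ms = stim$on_ms, off_ms = stim$off_ms,
         trial_len_ms = stim$trial_len_ms, total_ms = tt, grid = stim$grid),
    class = "spike_data"
  )
  if (return_rate) res$lambda <- lambda
  res
}

# causal convolution: out[t] = sum_k x[t - k + 1] * kern[k]; zero-padded to
# a power of two so the FFT length never hits a slow prime factorization
causal_conv <- function(x, kern) {
  n <- length(x)
  pad <- stats::nextn(n + length(kern), 2)
  xf <- stats::fft(c(x, numeric(pad - n)))
  kf <- stats::fft(c(kern, numeric(pad - length(kern))))
  out <- Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / pad
  out[abs(out) < 1e-10] <- 0
  out
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike_data: %d neuron(s), %d ms, %d spikes total\n",
              ncol(x$trains), x$total_ms, sum(x$trains)))
  invisible(x)
}

#' Construct spike_data from an event table
#'
#' @param events data.frame with columns `neuron_id`, `time_ms` (1-based
#'   millisecond bin).
#' @param n_neurons,total_ms dimensions of the binary train matrix.
#' @param markers optional trial marker data.frame.
#' @param on_ms,off_ms,grid optional stimulus metadata carried along.
#' @export
spike_data_from_events <- function(events, n_neurons, total_ms,
                                   markers = NULL, on_ms = NULL, off_ms = NULL,
                                   grid = NULL) {
  trains <- matrix(0L, total_ms, n_neurons)
  if (nrow(events)) {
    if (any(events$time_ms < 1 | events$time_ms > total_ms) ||
        any(events$neuron_id < 1 | events$neuron_id > n_neurons)) {
      stop("event outside the declared dimensions", call. = FALSE)
    }
    trains[cbind(events$time_ms, events$neuron_id)] <- 1L
  }
  structure(
    list(trains = trains, neuron_ids = seq_len(n_neurons), markers = markers,
         on_ms = on_ms, off_ms = off_ms,
         trial_len_ms = if (!is.null(on_ms)) on_ms + off_ms else NULL,
         total_ms = total_ms, grid = grid),
    class = "spike_data"
  )
}

# default biphasic (trough-dominant) extracellular template; `shape` varies
# the trough width and the recovery lobe so different units are separable in
# PC space.
spike_template <- function(fs = 25000, shape = 1) {
  t <- seq(0, 1.5e-3, by = 1 / fs)
  trough <- -exp(-((t - 4e-4) / (1e-4 * (1 + 0.4 * (shape - 1))))^2)
  bump <- (0.25 + 0.2 * shape) *
    exp(-((t - (6 + 3 * shape) * 1e-4) / (1.5e-4 * shape))^2)
  v <- trough + bump
  v / max(abs(v))
}

#' Synthesize a raw extracellular trace from spike trains
#'
#' Embeds a biphasic, trough-dominant spike template at every spike time on
#' top of Gaussian noise, emulating a band-passed extracellular recording
#' sampled at `fs`. Neurons sharing the channel get distinct template
#' shapes so the downstream PCA/K-means sorting stage has structure to
#' recover.
#'
#' @param spikes a `spike_data` object (1 ms resolution).
#' @param template_amplitude peak template amplitude (same units as
#'   `noise_sd`); recycled over neurons.
#' @param noise_sd Gaussian noise standard deviation.
#' @param fs sampling rate, Hz (default 25 kHz).
#' @param seed RNG seed.
#' @return list with `trace` (numeric vector), `fs`, `spike_samples` (list
#'   per neuron of template-onset sample indices), `templates`.
#' @export
simulate_raw_trace <- function(spikes, template_amplitude = 8, noise_sd = 1,
                               fs = 25000, seed = 1) {
  stopifnot(inherits(spikes, "spike_data"))
  n <- ncol(spikes$trains)
  amp <- rep_len(template_amplitude, n)
  per_ms <- fs / 1000
  n_samp <- ceiling(spikes$total_ms * per_ms)
  templates <- lapply(seq_len(n), function(i) spike_template(fs, shape = i))
  trace <- with_seed(seed, stats::rnorm(n_samp, 0, noise_sd))
  spike_samples <- vector("list", n)
  for (i in seq_len(n)) {
    tms <- which(spikes$trains[, i] == 1L)
    ss <- floor((tms - 1) * per_ms) + 1L
    tpl <- templates[[i]] * amp[i]
    ss <- ss[ss + length(tpl) - 1L <= n_samp]
    for (s in ss) {
      idx <- s:(s + length(tpl) - 1L)
      trace[idx] <- trace[idx] + tpl
    }
    spike_samples[[i]] <- ss
  }
  list(trace = trace, fs = fs, spike_samples = spike_samples,
       templates = templates, noise_sd = noise_sd)
}
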