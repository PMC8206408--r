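#' Cross-validation fold assignment over trials
#'
#' Two schemes mirror the two stimulation protocols. `per_pixel_trials`
#' holds out, within every pattern (pixel), a disjoint 1/k block of its
#' trials per fold, so each fold trains on 80% of each pixel's trials for
#' k = 5. `per_pattern` partitions the distinct patterns into k near-equal
#' groups (sizes differ by at most 1, e.g. 7/7/6/6/6 for 32 patterns) and
#' holds out all trials of a group per fold, so test patterns are never
#' seen during training.
#'
#' @param markers trial marker data.frame (`trial`, `pattern`, `rep`).
#' @param scheme `"per_pixel_trials"` or `"per_pattern"`.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the shuffles.
#' @return integer vector: the fold in which each trial is a *test* trial.
#' @export
split_folds <- function(markers, scheme = c("per_pixel_trials", "per_pattern"),
                        k = 5, seed = 1) {
  scheme <- match.arg(scheme)
  k <- check_count(k, "k")
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fold <- integer(nrow(markers))
  with_seed(seed, {
    if (scheme == "per_pixel_trials") {
      for (p in unique(markers$pattern)) {
        idx <- which(markers$pattern == p)
        if (length(idx) < k) {
          stop(sprintf("pattern %d has fewer trials (%d) than folds (%d)",
                       p, length(idx), k), call. = FALSE)
        }
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      pats <- unique(markers$pattern)
      if (length(pats) < k) {
        stop("fewer patterns than folds", call. = FALSE)
      }
      grp <- sample(rep_len(seq_len(k), length(pats)))
      fold <- grp[match(markers$pattern, pats)]
    }
  })
  fold
}

#' Per-neuron correlation between actual and predicted rates
#'
#' Pearson correlation computed per neuron per test trial, then averaged
#' across trials (and folds, when pooled by the caller). Trials in which
#' either series has zero variance (e.g. no spikes) have no defined
#' correlation; they are skipped and counted, not imputed.
#'
#' @param actual,predicted matrices (bins x N) on the same bin grid.
#' @param trial_of_bin integer vector assigning each bin row to a trial; if
#'   `NULL` the whole series is treated as one trial.
#' @return list with `per_neuron` (mean correlation per neuron),
#'   `per_trial` (trials x N matrix, NA where skipped), `n_skipped`.
#' @export
prediction_correlation <- function(actual, predicted, trial_of_bin = NULL) {
  stopifnot(all(dim(actual) == dim(predicted)))
  if (is.null(trial_of_bin)) trial_of_bin <- rep(1L, nrow(actual))
  trials <- unique(trial_of_bin)
  n <- ncol(actual)
  per_trial <- matrix(NA_real_, length(trials), n)
  for (ti in seq_along(trials)) {
    rows <- which(trial_of_bin == trials[ti])
    if (length(rows) < 2) next
    a <- actual[rows, , drop = FALSE]
    p <- predicted[rows, , drop = FALSE]
    for (i in seq_len(n)) {
      if (stats::sd(a[, i]) > 0 && stats::sd(p[, i]) > 0) {
        per_trial[ti, i] <- stats::cor(a[, i], p[, i])
      }
    }
  }
  list(per_neuron = colMeans(per_trial, na.rm = TRUE),
       per_trial = per_trial,
       n_skipped = colSums(is.na(per_trial)))
}

#' Actual-by-predicted correlation matrix
#'
#' Entry `(i, j)` is the Pearson correlation between the actual rate of
#' neuron `i` and the predicted rate of neuron `j` over the concatenated
#' test bins. A model that learns each neuron's intrinsic firing (rather
#' than a population common mode) produces a diagonal-dominant matrix.
#'
#' @inheritParams prediction_correlation
#' @export
correlation_matrix <- function(actual, predicted) {
  stopifnot(all(dim(actual) == dim(predicted)))
  stats::cor(actual, predicted)
}

#' Peak firing-rate agreement
#'
#' For every neuron and stimulation pattern, the peak (maximum) of the
#' trial-averaged rate within the post-onset window (the stimulus ON
#' period) is extracted from the actual and the predicted series; agreement
#' is summarized by the least-squares r-squared of predicted on actual.
#'
#' @param actual,predicted matrices (bins x N).
#' @param markers trial markers for the bins' recording.
#' @param w_ms bin width of the rate matrices, ms.
#' @param bin_index optional bin indices (on the full recording grid) of
#'   the rows of `actual`; defaults to `1:nrow(actual)`.
#' @param peak_window_ms window after onset to search for the peak
#'   (default 200 ms, the ON duration).
#' @param trial_len_ms trial block length (default 500).
#' @return list with `pairs` (data.frame neuron, pattern, actual,
#'   predicted), `r2`, `slope`.
#' @export
peak_rate_analysis <- function(actual, predicted, markers, w_ms,
                               bin_index = NULL, peak_window_ms = 200,
                               trial_len_ms = 500) {
  bin_index <- bin_index %||% seq_len(nrow(actual))
  n <- ncol(actual)
  rows_of <- function(onset_ms) {
    first <- onset_ms %/% w_ms + 1L
    last <- (onset_ms + peak_window_ms - 1L) %/% w_ms + 1L
    which(bin_index >= first & bin_index <= last)
  }
  out <- list()
  for (p in unique(markers$pattern)) {
    tr <- markers[markers$pattern == p, , drop = FALSE]
    acc_a <- matrix(NA_real_, 0, n); acc_p <- matrix(NA_real_, 0, n)
    len <- NULL
    a_sum <- NULL; p_sum <- NULL; n_tr <- 0
    for (j in seq_len(nrow(tr))) {
      rows <- rows_of(tr$onset_ms[j])
      if (!length(rows)) next
      a <- actual[rows, , drop = FALSE]
      pr <- predicted[rows, , drop = FALSE]
      if (is.null(a_sum)) {
        len <- nrow(a); a_sum <- a * 0; p_sum <- a * 0
      }
      if (nrow(a) != len) next
      a_sum <- a_sum + a; p_sum <- p_sum + pr; n_tr <- n_tr + 1
    }
    if (n_tr == 0) next
    out[[length(out) + 1L]] <- data.frame(
      neuron = seq_len(n), pattern = p,
      actual = apply(a_sum / n_tr, 2, max),
      predicted = apply(p_sum / n_tr, 2, max)
    )
  }
  pairs <- do.call(rbind, out)
  fit <- stats::lm(predicted ~ actual, data = pairs)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits are fine
  list(pairs = pairs, r2 = r2, slope = unname(stats::coef(fit)[2]))
}

#' Trial-to-trial variability agreement
#'
#' Per neuron, the standard deviation across trials of the trial-mean
#' firing rate (default), or of every within-trial bin (`mode =
#' "binwise"`), for the actual and predicted series.
#'
#' @inheritParams peak_rate_analysis
#' @param mode `"trial_mean"` or `"binwise"`.
#' @return list with `pairs` (data.frame neuron, actual_sd, predicted_sd)
#'   and `r2`.
#' @export
trial_variability <- function(actual, predicted, markers, w_ms,
                              bin_index = NULL, trial_len_ms = 500,
                              mode = c("trial_mean", "binwise")) {
  mode <- match.arg(mode)
  bin_index <- bin_index %||% seq_len(nrow(actual))
  n <- ncol(actual)
  bins_per_trial <- trial_len_ms %/% w_ms
  a_tr <- list(); p_tr <- list()
  for (j in seq_len(nrow(markers))) {
    first <- markers$onset_ms[j] %/% w_ms + 1L
    rows <- which(bin_index >= first & bin_index < first + bins_per_trial)
    if (length(rows) != bins_per_trial) next
    a_tr[[length(a_tr) + 1L]] <- actual[rows, , drop = FALSE]
    p_tr[[length(p_tr) + 1L]] <- predicted[rows, , drop = FALSE]
  }
  if (length(a_tr) < 2) stop("need at least 2 complete trials", call. = FALSE)
  sd_of <- function(lst) {
    if (mode == "trial_mean") {
      # keep (trials x N) orientation even for a single neuron
      means <- t(matrix(vapply(lst, colMeans, numeric(n)), nrow = n))
      apply(means, 2, stats::sd)
    } else {
      arr <- simplify2array(lst)             # bins x N x trials
      apply(arr, c(1, 2), stats::sd) |> colMeans()
    }
  }
  pairs <- data.frame(neuron = seq_len(n), actual_sd = sd_of(a_tr),
                      predicted_sd = sd_of(p_tr))
  r2 <- if (nrow(pairs) >= 2 && isTRUE(stats::sd(pairs$actual_sd) > 0)) {
    summary(stats::lm(predicted_sd ~ actual_sd, data = pairs))$r.squared
  } else NA_real_
  list(pairs = pairs, r2 = r2)
}

#' Maximum-likelihood Beta fit of a correlation histogram
#'
#' Correlation values are shrunk into the open interval (0, 1) by `eps` at
#' the boundaries, then Beta(alpha, beta) is fitted by maximizing the
#' log-likelihood (BFGS on the log-parameters, moment-matching start).
#'
#' @param correlations numeric vector of correlation coefficients in
#'   `[0, 1]`.
#' @param eps boundary shrink.
#' @return list with `alpha`, `beta`, `loglik`.
#' @export
fit_beta <- function(correlations, eps = 1e-4) {
  x <- correlations
  if (length(x) < 2 || stats::sd(x) == 0) {
    stop("degenerate input: need at least 2 distinct values", call. = FALSE)
  }
  if (any(x < 0) || any(x > 1)) {
    stop("correlations must lie in [0, 1]", call. = FALSE)
  }
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- stats::var(x)
  c0 <- max(m * (1 - m) / v - 1, 0.1)
  start <- log(c(max(m * c0, 0.1), max((1 - m) * c0, 0.1)))
  nll <- function(par) {
    -sum(stats::dbeta(x, exp(par[1]), exp(par[2]), log = TRUE))
  }
  opt <- stats::optim(start, nll, method = "BFGS")
  list(alpha = exp(opt$par[1]), beta = exp(opt$par[2]),
       loglik = -opt$value, convergence = opt$convergence)
}

#' Cross-validated evaluation of an encoder
#'
#' Runs the full protocol: split trials into folds, train one model per
#' fold on the training bins, predict the test bins, and pool per-neuron
#' correlations across trials and folds. Also assembles the correlation
#' matrix, peak-rate and trial-variability regressions over the pooled test
#' bins.
#'
#' @param stim a [stim_sequence()].
#' @param rates a `rate_matrix` of the population on the same time axis.
#' @param cfg an [encoder_config()] (or a function `function(fold_samples)`
#'   returning predictions, for custom models).
#' @param scheme,k,seed fold scheme, count and RNG seed
#'   (see [split_folds()]).
#' @param model `"cnn"` or `"glm"`.
#' @param glm_ridge ridge penalty when `model = "glm"`.
#' @param epochs optional training-epoch override for the CNN.
#' @return An `eval_report`: `per_neuron_corr`, `corr_matrix`, `peak`,
#'   `variability`, `beta_fit`, `fold_assignments`, `folds` (per-fold
#'   details), `model`, `seed`.
#' @export
evaluate_encoder <- function(stim, rates, cfg, scheme = "per_pattern", k = 5,
                             seed = 1, model = c("cnn", "glm"),
                             glm_ridge = 1e-4, epochs = NULL) {
  model <- match.arg(model)
  fold <- split_folds(stim$markers, scheme, k = k, seed = seed)
  samples <- assemble_samples(stim, rates, cfg)
  w <- cfg$w_ms
  trial_of_bin <- (samples$bin_index - 1L) %/% (stim$trial_len_ms %/% w) + 1L
  fold_of_sample <- fold[trial_of_bin]
  n <- ncol(samples$target)
  per_trial_all <- NULL
  actual_pool <- NULL; pred_pool <- NULL; bins_pool <- integer(0)
  fold_details <- list()
  for (f in seq_len(k)) {
    train_idx <- which(fold_of_sample != f)
    test_idx <- which(fold_of_sample == f)
    if (!length(train_idx) || !length(test_idx)) next
    if (model == "cnn") {
      fit <- build_encoder(cfg)
      fit <- train_encoder(fit, subset_samples(samples, train_idx),
                           epochs = epochs)
      pred <- predict(fit, subset_samples(samples, test_idx))
    } else {
      des <- glm_design(stim_intensity(stim, w),
                        matrix(as.integer(round(rates$counts)),
                               nrow(rates$counts)), w, cfg$L)
      # the GLM design needs one more leading bin than the CNN window;
      # restrict both index sets to bins the design covers
      keep <- match(samples$bin_index, des$bin_index)
      train_idx <- train_idx[!is.na(keep[train_idx])]
      test_idx <- test_idx[!is.na(keep[test_idx])]
      xtr <- des$X[keep[train_idx], , drop = FALSE]
      gfit <- fit_glm_encoder(list(X = xtr,
                                   counts = des$counts[keep[train_idx], , drop = FALSE],
                                   w_ms = w, L = cfg$L, P = des$P, N = des$N),
                              ridge = glm_ridge)
      pred <- predict(gfit, des$X[keep[test_idx], , drop = FALSE])
    }
    act <- samples$target[test_idx, , drop = FALSE]
    pc <- prediction_correlation(act, pred, trial_of_bin[test_idx])
    per_trial_all <- rbind(per_trial_all, pc$per_trial)
    actual_pool <- rbind(actual_pool, act)
    pred_pool <- rbind(pred_pool, pred)
    bins_pool <- c(bins_pool, samples$bin_index[test_idx])
    fold_details[[f]] <- list(fold = f, n_train = length(train_idx),
                              n_test = length(test_idx),
                              per_neuron = pc$per_neuron)
  }
  per_neuron <- colMeans(per_trial_all, na.rm = TRUE)
  pk <- peak_rate_analysis(actual_pool, pred_pool, stim$markers, w,
                           bin_index = bins_pool,
                           peak_window_ms = stim$on_ms,
                           trial_len_ms = stim$trial_len_ms)
  tv <- trial_variability(actual_pool, pred_pool, stim$markers, w,
                          bin_index = bins_pool,
                          trial_len_ms = stim$trial_len_ms)
  bf <- tryCatch(fit_beta(pmin(pmax(per_neuron, 0), 1)),
                 error = function(e) NULL)
  structure(
    list(per_neuron_corr = per_neuron,
         corr_matrix = correlation_matrix(actual_pool, pred_pool),
         peak = pk, variability = tv, beta_fit = bf,
         fold_assignments = fold, folds = fold_details,
         model = model, scheme = scheme, k = k, seed = seed,
         n_neurons = n, w_ms = w),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %s, %s scheme, %d folds, w = %d ms\n",
              toupper(x$model), x$scheme, x$k, x$w_ms))
  cat(sprintf("  per-neuron correlation: mean %.3f (range %.3f..%.3f, N = %d)\n",
              mean(x$per_neuron_corr), min(x$per_neuron_corr),
              max(x$per_neuron_corr), x$n_neurons))
  invisible(x)
}

#' Checkerboard-to-shapes generalization protocol
#'
#' Trains the encoder on the full checkerboard recording (no trial is held
#' out) and evaluates it, without retraining, on a shapes recording whose
#' stimulus is projected onto the model's coarse grid. The report's
#' `train_exposure` audit field records that the test patterns were never
#' seen during training.
#'
#' @param train_stim checkerboard [stim_sequence()].
#' @param train_rates `rate_matrix` recorded under `train_stim`.
#' @param test_stim full-resolution shapes [stim_sequence()] (projected
#'   internally via [project_to_grid()]) or an already-projected sequence.
#' @param test_rates `rate_matrix` recorded under the shapes stimulus.
#' @param cfg an [encoder_config()].
#' @param threshold projection binarization threshold.
#' @param epochs optional epoch override.
#' @return An `eval_report` with `train_exposure` audit metadata.
#' @export
generalization_eval <- function(train_stim, train_rates, test_stim,
                                test_rates, cfg, threshold = 0.25,
                                epochs = NULL) {
  proj <- if (all(test_stim$grid == cfg$grid)) {
    test_stim
  } else {
    project_to_grid(test_stim, cfg$grid, threshold)
  }
  model <- build_encoder(cfg)
  train_samples <- assemble_samples(train_stim, train_rates, cfg)
  model <- train_encoder(model, train_samples, epochs = epochs)
  test_samples <- assemble_samples(proj, test_rates, cfg)
  pred <- predict(model, test_samples)
  act <- test_samples$target
  w <- cfg$w_ms
  trial_of_bin <- (test_samples$bin_index - 1L) %/%
    (proj$trial_len_ms %/% w) + 1L
  pc <- prediction_correlation(act, pred, trial_of_bin)
  pk <- peak_rate_analysis(act, pred, proj$markers, w,
                           bin_index = test_samples$bin_index,
                           peak_window_ms = proj$on_ms,
                           trial_len_ms = proj$trial_len_ms)
  structure(
    list(per_neuron_corr = pc$per_neuron,
         corr_matrix = correlation_matrix(act, pred),
         peak = pk, variability = NULL, beta_fit = NULL,
         fold_assignments = NULL, folds = NULL,
         model = "cnn", scheme = "generalization", k = 0, seed = cfg$seed,
         n_neurons = ncol(act), w_ms = w,
         train_exposure = list(trained_on = "checkerboard_full",
                               test_patterns_seen_in_training = 0L)),
    class = "eval_report"
  )
}
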