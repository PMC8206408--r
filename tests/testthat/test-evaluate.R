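test_that("per-pixel-trial folds hold out disjoint 20-trial blocks", {
  stim <- make_single_pixel(grid = c(2, 2), trials_per_pixel = 100)
  fold <- split_folds(stim$markers, "per_pixel_trials", k = 5, seed = 1)
  for (p in unique(stim$markers$pattern)) {
    f <- fold[stim$markers$pattern == p]
    expect_equal(as.integer(table(f)), rep(20L, 5))    # 20 test trials per fold
  }
  expect_equal(sort(unique(fold)), 1:5)            # disjoint cover by construction
})

test_that("per-pattern folds partition 32 patterns into near-equal groups", {
  stim <- make_checkerboard(trials = 2, seed = 2)
  fold <- split_folds(stim$markers, "per_pattern", k = 5, seed = 3)
  per_pattern_fold <- tapply(fold, stim$markers$pattern, unique)
  expect_true(all(lengths(per_pattern_fold) == 1))  # all trials of a pattern together
  sizes <- sort(as.integer(table(unlist(per_pattern_fold))), decreasing = TRUE)
  expect_equal(sizes, c(7L, 7L, 6L, 6L, 6L))
  expect_error(split_folds(stim$markers, "per_pattern", k = 1), "at least 2")
  expect_error(split_folds(stim$markers[stim$markers$pattern <= 3, ],
                           "per_pattern", k = 5), "fewer patterns")
})

test_that("prediction correlation matches the textbook formula", {
  a <- matrix(c(3, 1, 4, 1, 5), 5, 1)
  # identity and anti-identity
  expect_equal(prediction_correlation(a, a)$per_neuron, 1)
  expect_equal(prediction_correlation(a, -a + 10)$per_neuron, -1)
  # printed 5-bin toy pair against a hand-rolled cov/(sd*sd)
  b <- matrix(c(2, 7, 1, 8, 2), 5, 1)
  manual <- {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  expect_lt(abs(prediction_correlation(a, b)$per_neuron - manual), 1e-12)

  # zero-variance trials are skipped and counted, not imputed
  act <- matrix(c(1, 1, 1, 2, 5, 3), 6, 1)
  prd <- matrix(rnorm(6), 6, 1)
  pc <- prediction_correlation(act, prd, trial_of_bin = rep(1:2, each = 3))
  expect_equal(pc$n_skipped[1], 1)
  expect_equal(pc$per_neuron[1], cor(act[4:6, 1], prd[4:6, 1]))
})

test_that("correlation matrix is equivariant and diagonal-dominant for a
           faithful model", {
  set.seed(4)
  act <- matrix(rnorm(200 * 3), 200, 3)
  expect_equal(diag(correlation_matrix(act, act)), rep(1, 3))
  prd <- act + matrix(rnorm(200 * 3, 0, 0.4), 200, 3)
  cm <- correlation_matrix(act, prd)
  expect_gt(mean(diag(cm)), mean(cm[row(cm) != col(cm)]))
  # permuted predictions permute the columns
  perm <- c(2, 3, 1)
  expect_equal(correlation_matrix(act, prd[, perm]), cm[, perm])
})

test_that("peak-rate analysis reproduces closed-form r-squared", {
  onset <- seq(0, by = 500, length.out = 8)
  markers <- data.frame(trial = 1:8, pattern = rep(1:2, 4), onset_ms = onset)
  set.seed(5)
  act <- matrix(rexp(80 * 2, 0.1), 80, 2)       # 8 trials x 10 bins, w = 50
  pk1 <- peak_rate_analysis(act, act, markers, w_ms = 50)
  expect_equal(pk1$r2, 1)
  pk2 <- peak_rate_analysis(act, 2 * act, markers, w_ms = 50)
  expect_equal(pk2$r2, 1)                        # r2 is scale-invariant
  expect_equal(pk2$slope, 2)

  # 4-point toy set: r2 = 1 - SSres/SStot by hand
  x <- c(1, 2, 3, 5); y <- c(1.2, 1.8, 3.4, 4.6)
  fit <- lm(y ~ x)
  manual <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  expect_lt(abs(summary(fit)$r.squared - manual), 1e-12)
})

test_that("trial variability SD matches a direct computation", {
  onset <- seq(0, by = 500, length.out = 3)
  markers <- data.frame(trial = 1:3, pattern = 1L, onset_ms = onset)
  # 3 hand-set trials of 10 bins each, one neuron
  tr <- list(rep(2, 10), rep(5, 10), rep(11, 10))
  act <- matrix(unlist(tr), 30, 1)
  tv <- trial_variability(act, act, markers, w_ms = 50)
  expect_lt(abs(tv$pairs$actual_sd - sd(c(2, 5, 11))), 1e-12)
  expect_equal(tv$pairs$actual_sd, tv$pairs$predicted_sd)

  # identical trials: SD 0
  same <- matrix(rep(c(1, 3, 2, 4, 1, 0, 2, 3, 1, 2), 3), 30, 1)
  tvs <- trial_variability(same, same, markers, w_ms = 50)
  expect_equal(tvs$pairs$actual_sd, 0)
})

test_that("Beta fitting recovers parameters by maximum likelihood", {
  set.seed(6)
  x <- rbeta(1e4, 7.45, 2.48)
  fit <- fit_beta(x)
  expect_lt(abs(fit$alpha - 7.45) / 7.45, 0.1)
  expect_lt(abs(fit$beta - 2.48) / 2.48, 0.1)

  u <- runif(1e4)
  fu <- fit_beta(u)
  expect_lt(abs(fu$alpha - 1), 0.1)
  expect_lt(abs(fu$beta - 1), 0.1)

  expect_error(fit_beta(rep(0.5, 100)), "degenerate")
})

test_that("cross-validated evaluation runs end to end for both models", {
  stim <- make_checkerboard(n_patterns = 16, pixels_per_pattern = 8,
                            trials = 8, seed = 7)
  specs <- lgn_population(4, seed = 8, snr_range = c(0.6, 1))
  sp <- simulate_population(stim, specs, seed = 9)
  rates <- bin_rates(sp, 50)
  cfg <- encoder_config(variant = "V-FH", w_ms = 50, n_neurons = 4,
                        epochs = 25, seed = 10)
  rep_cnn <- evaluate_encoder(stim, rates, cfg, scheme = "per_pattern",
                              k = 5, seed = 11, model = "cnn")
  expect_length(rep_cnn$per_neuron_corr, 4)
  expect_true(all(abs(rep_cnn$per_neuron_corr) <= 1))
  expect_equal(dim(rep_cnn$corr_matrix), c(4, 4))
  expect_gt(mean(rep_cnn$per_neuron_corr), 0)
  # fold assignments cover all trials
  expect_equal(sort(unique(rep_cnn$fold_assignments)), 1:5)

  rep_glm <- evaluate_encoder(stim, rates, cfg, scheme = "per_pattern",
                              k = 5, seed = 11, model = "glm")
  expect_length(rep_glm$per_neuron_corr, 4)
  expect_true(all(is.finite(rep_glm$per_neuron_corr)))
})

test_that("prediction correlation tracks stimulus locking across a population", {
  # end-to-end property: neurons differing only in snr; their held-out
  # prediction correlation should rank-order with snr. Averaged over three
  # independently simulated populations to damp single-draw noise.
  centers <- cbind(rep(2:3, 6), rep(c(2, 3, 4, 5, 6, 7), each = 2))
  rhos <- vapply(1:3, function(ps) {
    stim <- make_checkerboard(n_patterns = 32, pixels_per_pattern = 4,
                              trials = 20, seed = 1000 + ps)
    specs <- lapply(1:12, function(i) {
      neuron_spec(rf_center = centers[i, ], snr = 0.2 + 0.8 * (i - 0.5) / 12)
    })
    sp <- simulate_population(stim, specs, seed = 2000 + ps)
    rates <- bin_rates(sp, 50)
    cfg <- encoder_config(variant = "V-FH", w_ms = 50, n_neurons = 12,
                          epochs = 50, seed = 3000 + ps)
    samples <- assemble_samples(stim, rates, cfg)
    fold <- split_folds(stim$markers, "per_pattern", k = 5, seed = 4000 + ps)
    tob <- (samples$bin_index - 1) %/% 10 + 1
    test_i <- which(fold[tob] == 1)
    train_i <- which(fold[tob] != 1)
    m <- train_encoder(build_encoder(cfg),
                       lgnencoder:::subset_samples(samples, train_i))
    pred <- predict(m, lgnencoder:::subset_samples(samples, test_i))
    pc <- prediction_correlation(samples$target[test_i, ], pred, tob[test_i])
    snr <- vapply(specs, `[[`, numeric(1), "snr")
    cor(pc$per_neuron, snr, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.6)
})

test_that("checkerboard-trained model generalizes to projected shapes", {
  train_stim <- make_checkerboard(n_patterns = 16, pixels_per_pattern = 8,
                                  trials = 10, seed = 12)
  shapes <- make_shapes(canvas = c(80, 160), n_patterns = 10, trials = 4,
                        seed = 13)
  specs <- lgn_population(4, seed = 14, snr_range = c(0.7, 1))
  sp_train <- simulate_population(train_stim, specs, seed = 15)
  proj <- project_to_grid(shapes)
  sp_test <- simulate_population(proj, specs, seed = 16)
  cfg <- encoder_config(variant = "V-FH", w_ms = 50, n_neurons = 4,
                        epochs = 40, seed = 17)
  rep_gen <- generalization_eval(train_stim, bin_rates(sp_train, 50),
                                 shapes, bin_rates(sp_test, 50), cfg)
  # audit: no test pattern seen during training
  expect_equal(rep_gen$train_exposure$test_patterns_seen_in_training, 0L)
  expect_gt(mean(rep_gen$per_neuron_corr), 0)

  # in-distribution performance bound: same model evaluated on held-out
  # checkerboard patterns does at least as well on average
  rep_in <- evaluate_encoder(train_stim, bin_rates(sp_train, 50), cfg,
                             scheme = "per_pattern", k = 5, seed = 18,
                             model = "cnn", epochs = 40)
  expect_gt(mean(rep_in$per_neuron_corr), mean(rep_gen$per_neuron_corr))
})
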