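test_that("prelu follows its definition", {
  expect_equal(prelu(2, 0.7), 2)
  expect_equal(prelu(-2, 0.1), -0.2)
  expect_equal(prelu(c(-1, 0, 3), 0), c(0, 0, 3))   # alpha = 0 is ReLU
})

test_that("conv layer matches the brute-force oracle for every filter length", {
  set.seed(51)
  for (f in 3:8) {
    x <- matrix(rnorm(5 * 3), 5, 3)
    w <- matrix(rnorm(f * 3 * 4), f * 3, 4)
    b <- rnorm(4)
    xa <- array(x, c(1, 5, 3))
    got <- lgnencoder:::conv1d_forward(xa, w, b, f)$y[1, , ]
    expect_lt(max(abs(got - conv_oracle(x, w, b, f))), 1e-6)
  }
  # and with a batch dimension
  f <- 5
  xb <- array(rnorm(3 * 10 * 2), c(3, 10, 2))
  w <- matrix(rnorm(f * 2 * 6), f * 2, 6)
  b <- rnorm(6)
  got <- lgnencoder:::conv1d_forward(xb, w, b, f)$y
  for (i in 1:3) {
    expect_lt(max(abs(got[i, , ] - conv_oracle(xb[i, , ], w, b, f))), 1e-6)
  }
})

test_that("backward pass matches finite differences", {
  set.seed(52)
  cfg <- encoder_config(variant = "V-FH", w_ms = 50, grid = c(2, 2),
                        n_neurons = 3, filter_len = 3, seed = 53)
  model <- build_encoder(cfg)
  v <- array(rnorm(2 * 10 * 4), c(2, 10, 4))
  h <- array(rnorm(2 * 9 * 3), c(2, 9, 3))
  y <- matrix(rnorm(2 * 3), 2, 3)
  loss_of <- function(m) {
    pred <- lgnencoder:::encoder_forward(m, v, h)$pred
    sqrt(mean((pred - y)^2))
  }
  fw <- lgnencoder:::encoder_forward(model, v, h, keep_cache = TRUE)
  resid <- fw$pred - y
  l0 <- sqrt(mean(resid^2))
  grads <- lgnencoder:::encoder_backward(model, fw, resid / (length(resid) * l0))
  eps <- 1e-6
  paths <- lgnencoder:::param_paths(model)
  for (p in paths[c(1, 3, 7, 9, 10, 12)]) {     # spot-check a spread of params
    val <- lgnencoder:::get_path(model, p)
    g <- lgnencoder:::grad_for_path(grads, p)
    idx <- 1
    bumped <- val; bumped[idx] <- bumped[idx] + eps
    m2 <- lgnencoder:::set_path(model, p, bumped)
    num <- (loss_of(m2) - l0) / eps
    expect_lt(abs(num - g[idx]), 1e-4)
  }
})

test_that("architecture contract: layer counts and pooled shapes", {
  m50 <- build_encoder(encoder_config(w_ms = 50, n_neurons = 12))
  expect_equal(m50$n_layers, 9)
  expect_equal(m50$visual_out, c(5, 32))   # 10 bins pooled to 5, P filters
  expect_equal(m50$history_out, c(4, 12))  # 9 bins pooled to 4
  expect_equal(m50$cfg$L * m50$cfg$w_ms, 500)

  m10 <- build_encoder(encoder_config(w_ms = 10, n_neurons = 12))
  expect_equal(m10$n_layers, 17)
  expect_equal(m10$visual_out, c(6, 32))   # 50 -> 25 -> 12 -> 6
  expect_equal(m10$history_out, c(6, 12))  # 49 -> 24 -> 12 -> 6
  expect_equal(m10$cfg$L * m10$cfg$w_ms, 500)

  # too many blocks: pooled length reaches zero
  expect_error(build_encoder(encoder_config(w_ms = 50, n_neurons = 4,
                                            conv_blocks = 4)), "pooled")
  expect_error(encoder_config(w_ms = 50, n_neurons = 4, filter_len = 9),
               "filter_len")
})

test_that("sample assembly windows are shaped and counted exactly", {
  cfg <- encoder_config(w_ms = 50, n_neurons = 12, seed = 1)
  intens <- matrix(runif(10 * 32), 10, 32)
  rates <- matrix(runif(10 * 12), 10, 12)
  s1 <- assemble_samples(intens, rates, cfg)
  expect_equal(dim(s1$visual), c(1, 10, 32))     # exactly L bins -> 1 sample
  expect_equal(dim(s1$history), c(1, 9, 12))
  expect_equal(dim(s1$target), c(1, 12))
  expect_equal(s1$target[1, ], rates[10, ])
  # visual window is bins k-L+1..k in ascending time
  expect_equal(s1$visual[1, , ], intens)
  expect_equal(s1$history[1, , ], rates[1:9, ])

  intens2 <- matrix(runif(25 * 32), 25, 32)
  rates2 <- matrix(runif(25 * 12), 25, 12)
  s2 <- assemble_samples(intens2, rates2, cfg)
  expect_equal(dim(s2$visual)[1], 25 - 10 + 1)   # n_bins - L + 1 samples
  expect_error(assemble_samples(intens[1:5, ], rates[1:5, ], cfg), "window|bins")
})

test_that("training is seeded, monotone on zero targets, and memorizes", {
  cfg <- encoder_config(variant = "V-FH", w_ms = 50, grid = c(2, 4),
                        n_neurons = 16, epochs = 30, batch_size = 10,
                        seed = 55)
  set.seed(54)
  intens <- matrix(runif(40 * 8), 40, 8)
  rates <- matrix(runif(40 * 16) * 40, 40, 16)
  samples <- assemble_samples(intens, rates, cfg)

  m1 <- train_encoder(build_encoder(cfg), samples)
  m2 <- train_encoder(build_encoder(cfg), samples)
  expect_identical(m1$loss_trace, m2$loss_trace)   # same seed, same trace

  # zero targets: loss decays toward 0; the smoothed (10-epoch block mean)
  # trace is monotone even where single Adam steps jitter at the floor
  zs <- samples; zs$target <- samples$target * 0
  mz <- train_encoder(build_encoder(cfg), zs, epochs = 60)
  expect_lt(tail(mz$loss_trace, 1), 0.05 * mz$loss_trace[1])
  blocks <- colMeans(matrix(mz$loss_trace, 10))
  expect_true(all(diff(blocks) < 1e-3))

  # capacity model memorizes 50 samples to < 5% of the target SD
  cfg_m <- encoder_config(variant = "V-FH", w_ms = 50, grid = c(2, 4),
                          n_neurons = 16, epochs = 4000, batch_size = 50,
                          lr = 5e-3, seed = 11)
  set.seed(9)
  intens_m <- matrix(runif(59 * 8), 59, 8)
  rates_m <- matrix(runif(59 * 16) * 40, 59, 16)
  sm <- assemble_samples(intens_m, rates_m, cfg_m)
  mm <- train_encoder(build_encoder(cfg_m), sm)
  rmse <- sqrt(mean((predict(mm, sm) - sm$target)^2))
  expect_lt(rmse, 0.05 * sd(sm$target))
})

test_that("training aborts with diagnostics on non-finite loss", {
  cfg <- encoder_config(variant = "V", w_ms = 50, grid = c(2, 2),
                        n_neurons = 2, epochs = 5, seed = 3)
  set.seed(56)
  samples <- assemble_samples(matrix(runif(40 * 4), 40, 4),
                              matrix(runif(40 * 2), 40, 2), cfg)
  samples$target[3, 1] <- NaN
  expect_error(train_encoder(build_encoder(cfg), samples), "loss")
})

test_that("predictions are finite and learn a noiseless mapping", {
  stim <- make_checkerboard(n_patterns = 8, pixels_per_pattern = 4,
                            trials = 6, seed = 2)
  specs <- lgn_population(4, seed = 3, snr_range = c(0.9, 1))
  sp <- simulate_population(stim, specs, seed = 4, return_rate = TRUE)
  binlam <- rowsum(sp$lambda, rep(seq_len(nrow(sp$lambda) / 50), each = 50)) / 50
  cfg <- encoder_config(variant = "V-FH", w_ms = 50, n_neurons = 4,
                        filter_len = 5, epochs = 60, seed = 7)
  samples <- assemble_samples(stim, binlam, cfg)
  model <- train_encoder(build_encoder(cfg), samples)
  pred <- predict(model, samples)
  expect_true(all(is.finite(pred)))
  cors <- vapply(1:4, function(i) cor(pred[, i], samples$target[, i]),
                 numeric(1))
  expect_true(all(cors > 0.8))

  # all-zero inputs still give a finite forward pass
  zero <- samples
  zero$visual[] <- 0; zero$history[] <- 0
  expect_true(all(is.finite(predict(model, zero))))
})

test_that("CNN approaches the GLM on GLM-generated data", {
  set.seed(5)
  grid <- c(2, 4); P <- 8; N <- 4; L <- 5; w <- 50
  stim <- make_checkerboard(grid = grid, n_patterns = 8,
                            pixels_per_pattern = 4, trials = 60, seed = 81)
  intens <- stim_intensity(stim, w)
  beta0 <- log(c(0.8, 1.1, 0.6, 0.9))
  beta_v <- array(rnorm(P * (L + 1) * N, 0, 0.3), c(P, L + 1, N))
  beta_h <- array(runif(N * L * N, -0.08, 0.01), c(N, L, N))
  simd <- simulate_glm_population(intens, beta0, beta_v, beta_h, w, seed = 82)
  nb <- nrow(intens)
  test_bins <- (floor(nb * 0.8) + 1):nb
  train_bins <- (L + 1):floor(nb * 0.8)
  des <- glm_design(intens, simd$counts, w, L)
  tr <- match(train_bins, des$bin_index); te <- match(test_bins, des$bin_index)
  gfit <- fit_glm_encoder(list(X = des$X[tr, ], counts = des$counts[tr, ],
                               w_ms = w, L = L, P = P, N = N), ridge = 1e-4)
  gpred <- predict(gfit, des$X[te, ])
  rates <- simd$counts / (w / 1000)
  gcorr <- mean(vapply(1:N, function(i) {
    cor(gpred[, i], rates[test_bins, i])
  }, numeric(1)))

  cfg <- encoder_config(variant = "V-FH", w_ms = w, grid = grid,
                        n_neurons = N, epochs = 150, seed = 83)
  samples <- assemble_samples(intens, rates, cfg)
  s_tr <- which(samples$bin_index %in% train_bins)
  s_te <- which(samples$bin_index %in% test_bins)
  m <- train_encoder(build_encoder(cfg),
                     lgnencoder:::subset_samples(samples, s_tr))
  cpred <- predict(m, lgnencoder:::subset_samples(samples, s_te))
  ccorr <- mean(vapply(1:N, function(i) {
    cor(cpred[, i], samples$target[s_te, i])
  }, numeric(1)))
  expect_gte(ccorr, gcorr - 0.05)
})
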