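#' Parametric ReLU
#'
#' `prelu(x, alpha) = x` for `x > 0` and `alpha * x` otherwise. `alpha` is a
#' learnable negative-slope parameter (one shared scalar per layer in the
#' encoder); `alpha = 0` reduces to the ordinary ReLU.
#'
#' @param x numeric input (any shape).
#' @param alpha negative-part slope.
#' @export
prelu <- function(x, alpha) {
  ifelse(x > 0, x, alpha * x)
}

#' Configuration of the convolutional firing-rate encoder
#'
#' The encoder predicts the binned firing rate of all `N` neurons at bin `k`
#' from (a) the visual stimulus over the last `L` bins (`L x P` matrix,
#' bins `k-L+1 ... k`) and (b) the population firing history over the
#' previous `L-1` bins (`(L-1) x N`, bins `k-L+1 ... k-1`), where
#' `L = 500 / w_ms`. Three variants exist: `"V-FH"` (both branches), `"V"`
#' (visual only) and `"FH"` (history only).
#'
#' @param variant `"V-FH"`, `"V"` or `"FH"`.
#' @param w_ms firing-rate bin width; 50 ms gives `L = 10` and one
#'   conv+pool block per branch, 10 ms gives `L = 50` and three cascaded
#'   blocks.
#' @param grid stimulus pixel grid (`P = prod(grid)`).
#' @param n_neurons population size `N`.
#' @param filter_len temporal filter length, 3-8.
#' @param epochs,batch_size,lr,beta1,beta2 training recipe (Adam on the
#'   RMSE loss; defaults lr 0.001, moments 0.9/0.999).
#' @param conv_blocks conv+pool blocks per branch; default tied to `w_ms`.
#' @param pool_size,pool_stride max-pooling geometry (2 and 2: no overlap).
#' @param seed RNG seed for initialization and batch shuffling.
#' @param clamp_negative clamp negative predicted rates to zero at predict
#'   time (the PReLU output unit permits negative values; off by default,
#'   predictions are reported as-is).
#' @return An `encoder_config` list with derived fields `L`, `P`,
#'   `conv_blocks`.
#' @export
encoder_config <- function(variant = c("V-FH", "V", "FH"), w_ms = 50,
                           grid = c(4, 8), n_neurons, filter_len = 5,
                           epochs = 200, batch_size = 64, lr = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, conv_blocks = NULL,
                           pool_size = 2, pool_stride = 2, seed = 1,
                           clamp_negative = FALSE) {
  variant <- match.arg(variant)
  if (500 %% w_ms != 0) stop("w_ms must divide 500", call. = FALSE)
  if (filter_len < 3 || filter_len > 8) {
    stop("filter_len must be in 3..8", call. = FALSE)
  }
  n_neurons <- check_count(n_neurons, "n_neurons")
  l <- 500 %/% w_ms
  conv_blocks <- conv_blocks %||% if (w_ms == 50) 1L else 3L
  structure(
    list(variant = variant, w_ms = w_ms, L = l, grid = as.integer(grid),
         P = prod(grid), N = n_neurons, filter_len = as.integer(filter_len),
         conv_blocks = as.integer(conv_blocks), pool_size = pool_size,
         pool_stride = pool_stride, epochs = epochs, batch_size = batch_size,
         lr = lr, beta1 = beta1, beta2 = beta2, seed = seed,
         clamp_negative = clamp_negative),
    class = "encoder_config"
  )
}

xavier_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# one branch: conv_blocks x [conv1d(same) -> PReLU -> maxpool(2,2)]
build_branch <- function(len, channels, n_filters, cfg) {
  layers <- list()
  for (b in seq_len(cfg$conv_blocks)) {
    f <- cfg$filter_len
    w <- xavier_uniform(f * channels, f * n_filters, c(f * channels, n_filters))
    layers[[length(layers) + 1L]] <- list(
      type = "conv", W = w, b = numeric(n_filters), f = f,
      in_ch = channels, out_ch = n_filters
    )
    layers[[length(layers) + 1L]] <- list(type = "prelu", alpha = 0.25)
    out_len <- (len - cfg$pool_size) %/% cfg$pool_stride + 1L
    if (out_len < 1L) {
      stop("pooled length reaches zero; too many conv blocks for this input",
           call. = FALSE)
    }
    layers[[length(layers) + 1L]] <- list(type = "pool", size = cfg$pool_size,
                                          stride = cfg$pool_stride)
    len <- out_len
    channels <- n_filters
  }
  list(layers = layers, out_len = len, out_ch = channels)
}

#' Build the convolutional encoder
#'
#' Assembles the dual-branch topology: per branch, `conv_blocks`
#' repetitions of length-preserving 1D temporal convolution (filters span
#' the full channel depth; number of filters = `P` for the visual branch,
#' `N` for the history branch) + PReLU + non-overlapping max-pooling, then
#' flattening; the branch feature vectors are concatenated and passed
#' through a 2-layer fully connected readout whose hidden and output layers
#' each hold `N` PReLU units. Weights are Xavier-uniform, biases zero,
#' PReLU slopes 0.25. Counting conv, pool and flatten per branch plus the
#' concatenation and the two dense layers gives 9 layers at `w = 50` ms and
#' 17 at `w = 10` ms.
#'
#' @param cfg an [encoder_config()].
#' @return An `encoder_model` with fields `visual`, `history` (layer
#'   lists), `fc1`, `fc2`, `n_layers`, `feature_len`, and shape metadata.
#' @export
build_encoder <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  with_seed(cfg$seed, {
    use_v <- cfg$variant %in% c("V-FH", "V")
    use_h <- cfg$variant %in% c("V-FH", "FH")
    visual <- if (use_v) build_branch(cfg$L, cfg$P, cfg$P, cfg) else NULL
    history <- if (use_h) build_branch(cfg$L - 1L, cfg$N, cfg$N, cfg) else NULL
    feat <- 0L
    if (use_v) feat <- feat + visual$out_len * visual$out_ch
    if (use_h) feat <- feat + history$out_len * history$out_ch
    fc1 <- list(W = xavier_uniform(feat, cfg$N, c(feat, cfg$N)),
                b = numeric(cfg$N), alpha = 0.25)
    fc2 <- list(W = xavier_uniform(cfg$N, cfg$N, c(cfg$N, cfg$N)),
                b = numeric(cfg$N), alpha = 0.25)
    per_branch <- 2L * cfg$conv_blocks + 1L        # conv+pool per block, flatten
    n_layers <- per_branch * (use_v + use_h) + 1L + 2L  # concat + 2 FC
    structure(
      list(cfg = cfg, visual = visual$layers, history = history$layers,
           visual_out = if (use_v) c(visual$out_len, visual$out_ch),
           history_out = if (use_h) c(history$out_len, history$out_ch),
           fc1 = fc1, fc2 = fc2, feature_len = feat, n_layers = n_layers,
           trained = FALSE),
      class = "encoder_model"
    )
  })
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("CNN-%s encoder: w = %d ms (L = %d), P = %d, N = %d\n",
              x$cfg$variant, x$cfg$w_ms, x$cfg$L, x$cfg$P, x$cfg$N))
  cat(sprintf("  %d layers, filter length %d, %d conv block(s)/branch, %s\n",
              x$n_layers, x$cfg$filter_len, x$cfg$conv_blocks,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- tensor ops; batch tensors are arrays (B, L, C) -------------------------

# zero-padded "same" 1D convolution along dim 2; W is (f*C_in, C_out) with
# row block o holding the weights for temporal offset o (o = 1..f).
conv1d_forward <- function(x, w, b, f) {
  d <- dim(x); bsz <- d[1]; len <- d[2]; cin <- d[3]
  pad_l <- (f - 1L) %/% 2L
  xp <- array(0, c(bsz, len + f - 1L, cin))
  xp[, pad_l + seq_len(len), ] <- x
  xcol <- array(0, c(bsz, len, f * cin))
  for (o in seq_len(f)) {
    xcol[, , ((o - 1L) * cin + 1L):(o * cin)] <- xp[, o:(o + len - 1L), , drop = FALSE]
  }
  xmat <- xcol; dim(xmat) <- c(bsz * len, f * cin)
  y <- xmat %*% w
  y <- sweep(y, 2, b, "+")
  dim(y) <- c(bsz, len, ncol(w))
  list(y = y, xmat = xmat)
}

conv1d_backward <- function(dy, cache, w, f, in_dim) {
  bsz <- in_dim[1]; len <- in_dim[2]; cin <- in_dim[3]
  dym <- dy; dim(dym) <- c(bsz * len, ncol(w))
  dw <- crossprod(cache$xmat, dym)
  db <- colSums(dym)
  dxcol <- dym %*% t(w)               # (B*L, f*cin)
  dim(dxcol) <- c(bsz, len, f * cin)
  pad_l <- (f - 1L) %/% 2L
  dxp <- array(0, c(bsz, len + f - 1L, cin))
  for (o in seq_len(f)) {
    dxp[, o:(o + len - 1L), ] <- dxp[, o:(o + len - 1L), , drop = FALSE] +
      dxcol[, , ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
  }
  dx <- dxp[, pad_l + seq_len(len), , drop = FALSE]
  list(dx = dx, dW = dw, db = db)
}

pool_forward <- function(x, size, stride) {
  d <- dim(x); len <- d[2]
  out_len <- (len - size) %/% stride + 1L
  i1 <- (seq_len(out_len) - 1L) * stride + 1L
  a <- x[, i1, , drop = FALSE]
  b <- x[, i1 + 1L, , drop = FALSE]
  first <- a >= b                     # ties keep the earlier sample
  list(y = pmax(a, b), first = first, i1 = i1, in_dim = d)
}

pool_backward <- function(dy, cache) {
  dx <- array(0, cache$in_dim)
  dx[, cache$i1, ] <- dy * cache$first
  dx[, cache$i1 + 1L, ] <- dx[, cache$i1 + 1L, , drop = FALSE] +
    dy * !cache$first
  dx
}

branch_forward <- function(x, layers) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      cv <- conv1d_forward(x, ly$W, ly$b, ly$f)
      caches[[i]] <- list(xmat = cv$xmat, in_dim = dim(x))
      x <- cv$y
    } else if (ly$type == "prelu") {
      caches[[i]] <- list(x = x)
      x <- prelu(x, ly$alpha)
    } else {
      pc <- pool_forward(x, ly$size, ly$stride)
      caches[[i]] <- pc
      x <- pc$y
    }
  }
  list(out = x, caches = caches)
}

branch_backward <- function(dy, layers, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      g <- conv1d_backward(dy, caches[[i]], ly$W, ly$f, caches[[i]]$in_dim)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dy <- g$dx
    } else if (ly$type == "prelu") {
      x <- caches[[i]]$x
      grads[[i]] <- list(dalpha = sum(dy * x * (x <= 0)))
      dy <- dy * ((x > 0) + ly$alpha * (x <= 0))
    } else {
      dy <- pool_backward(dy, caches[[i]])
    }
  }
  list(dx = dy, grads = grads)
}

encoder_forward <- function(model, visual, history, keep_cache = FALSE) {
  cfg <- model$cfg
  feats <- list(); caches <- list()
  if (!is.null(model$visual)) {
    bf <- branch_forward(visual, model$visual)
    v <- bf$out; dim(v) <- c(dim(visual)[1], prod(dim(v)[2:3]))
    feats$v <- v; caches$v <- bf$caches; caches$v_dim <- dim(bf$out)
  }
  if (!is.null(model$history)) {
    bf <- branch_forward(history, model$history)
    h <- bf$out; dim(h) <- c(dim(history)[1], prod(dim(h)[2:3]))
    feats$h <- h; caches$h <- bf$caches; caches$h_dim <- dim(bf$out)
  }
  z <- do.call(cbind, feats)
  a1 <- sweep(z %*% model$fc1$W, 2, model$fc1$b, "+")
  y1 <- prelu(a1, model$fc1$alpha)
  a2 <- sweep(y1 %*% model$fc2$W, 2, model$fc2$b, "+")
  y2 <- prelu(a2, model$fc2$alpha)
  if (!keep_cache) return(list(pred = y2))
  list(pred = y2, z = z, a1 = a1, y1 = y1, a2 = a2, caches = caches,
       v_cols = if (!is.null(feats$v)) ncol(feats$v) else 0L)
}

encoder_backward <- function(model, fw, dpred) {
  da2 <- dpred * ((fw$a2 > 0) + model$fc2$alpha * (fw$a2 <= 0))
  g_fc2 <- list(dW = crossprod(fw$y1, da2), db = colSums(da2),
                dalpha = sum(dpred * fw$a2 * (fw$a2 <= 0)))
  dy1 <- da2 %*% t(model$fc2$W)
  da1 <- dy1 * ((fw$a1 > 0) + model$fc1$alpha * (fw$a1 <= 0))
  g_fc1 <- list(dW = crossprod(fw$z, da1), db = colSums(da1),
                dalpha = sum(dy1 * fw$a1 * (fw$a1 <= 0)))
  dz <- da1 %*% t(model$fc1$W)
  out <- list(fc1 = g_fc1, fc2 = g_fc2)
  if (!is.null(model$visual)) {
    dv <- dz[, seq_len(fw$v_cols), drop = FALSE]
    dim(dv) <- fw$caches$v_dim
    out$visual <- branch_backward(dv, model$visual, fw$caches$v)$grads
  }
  if (!is.null(model$history)) {
    dh <- dz[, (fw$v_cols + 1L):ncol(dz), drop = FALSE]
    dim(dh) <- fw$caches$h_dim
    out$history <- branch_backward(dh, model$history, fw$caches$h)$grads
  }
  out
}

# ---- samples ----------------------------------------------------------------

#' Assemble encoder training samples from stimulus and rates
#'
#' One sample per bin `k >= L` of a continuous recording: the visual window
#' (bins `k-L+1 ... k`, ascending in time), the history window (bins
#' `k-L+1 ... k-1`) and the target rate vector at bin `k`. Pixel intensity
#' per bin is the mean of the stimulus' 1 ms values over the bin (see
#' [stim_intensity()]).
#'
#' @param stim a [stim_sequence()], or a precomputed intensity matrix
#'   (`n_bins x P`).
#' @param rates a `rate_matrix` from [bin_rates()], or a plain
#'   `n_bins x N` matrix.
#' @param cfg an [encoder_config()] (provides `L` and `w_ms`).
#' @return A `sample_batch`: `visual` (S x L x P), `history`
#'   (S x (L-1) x N), `target` (S x N), `bin_index`.
#' @export
assemble_samples <- function(stim, rates, cfg) {
  l <- cfg$L
  intens <- if (inherits(stim, "stim_sequence")) {
    stim_intensity(stim, cfg$w_ms)
  } else as.matrix(stim)
  r <- if (inherits(rates, "rate_matrix")) rates$rates else as.matrix(rates)
  n_bins <- min(nrow(intens), nrow(r))
  if (n_bins < l) stop("fewer bins than the window length L", call. = FALSE)
  ks <- l:n_bins
  s <- length(ks)
  visual <- array(0, c(s, l, ncol(intens)))
  history <- array(0, c(s, l - 1L, ncol(r)))
  for (j in seq_len(l)) {
    visual[, j, ] <- intens[ks - l + j, , drop = FALSE]
    if (j < l) history[, j, ] <- r[ks - l + j, , drop = FALSE]
  }
  structure(
    list(visual = visual, history = history,
         target = r[ks, , drop = FALSE], bin_index = ks),
    class = "sample_batch"
  )
}

subset_samples <- function(samples, idx) {
  structure(
    list(visual = samples$visual[idx, , , drop = FALSE],
         history = samples$history[idx, , , drop = FALSE],
         target = samples$target[idx, , drop = FALSE],
         bin_index = samples$bin_index[idx]),
    class = "sample_batch"
  )
}

# ---- Adam -------------------------------------------------------------------

# Collect references to every trainable array in the model as a flat list of
# (path, value); update in place via assignment by path.
param_paths <- function(model) {
  paths <- list()
  add <- function(p) paths[[length(paths) + 1L]] <<- p
  for (br in c("visual", "history")) {
    if (is.null(model[[br]])) next
    for (i in seq_along(model[[br]])) {
      ly <- model[[br]][[i]]
      if (ly$type == "conv") {
        add(c(br, i, "W")); add(c(br, i, "b"))
      } else if (ly$type == "prelu") add(c(br, i, "alpha"))
    }
  }
  for (fc in c("fc1", "fc2")) {
    add(c(fc, "W")); add(c(fc, "b")); add(c(fc, "alpha"))
  }
  paths
}

get_path <- function(x, path) {
  for (p in path) x <- x[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  x
}

set_path <- function(x, path, value) {
  p <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  if (length(path) == 1L) {
    x[[p]] <- value
  } else {
    x[[p]] <- set_path(x[[p]], path[-1], value)
  }
  x
}

grad_for_path <- function(grads, path) {
  key <- paste0("d", path[length(path)])
  if (path[1] %in% c("fc1", "fc2")) return(grads[[path[1]]][[key]])
  grads[[path[1]]][[as.integer(path[2])]][[key]]
}

#' Train the convolutional encoder
#'
#' Minimizes the root-mean-square error between predicted and target rate
#' vectors with Adam (learning rate, moment decays and initialization per
#' the config). Batches are reshuffled every epoch under the config seed, so
#' two runs with the same seed give identical loss traces.
#'
#' @param model an `encoder_model` from [build_encoder()].
#' @param samples a `sample_batch` from [assemble_samples()].
#' @param epochs,batch_size,verbose overrides / progress flag.
#' @return the fitted model, with `$loss_trace` (mean batch RMSE per epoch).
#' @export
train_encoder <- function(model, samples, epochs = NULL, batch_size = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "encoder_model"), inherits(samples, "sample_batch"))
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  n <- dim(samples$visual)[1]
  paths <- param_paths(model)
  m_state <- lapply(paths, function(p) get_path(model, p) * 0)
  v_state <- m_state
  step <- 0L
  loss_trace <- numeric(epochs)
  with_seed(derive_seed(cfg$seed, 17L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        vb <- samples$visual[idx, , , drop = FALSE]
        hb <- samples$history[idx, , , drop = FALSE]
        tb <- samples$target[idx, , drop = FALSE]
        fw <- encoder_forward(model, vb, hb, keep_cache = TRUE)
        resid <- fw$pred - tb
        loss <- sqrt(mean(resid^2))
        if (!is.finite(loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d; lower the learning rate", ep),
               call. = FALSE)
        }
        losses <- c(losses, loss)
        dpred <- if (loss > 0) resid / (length(resid) * loss) else resid * 0
        grads <- encoder_backward(model, fw, dpred)
        step <- step + 1L
        for (pi in seq_along(paths)) {
          g <- grad_for_path(grads, paths[[pi]])
          m_state[[pi]] <- cfg$beta1 * m_state[[pi]] + (1 - cfg$beta1) * g
          v_state[[pi]] <- cfg$beta2 * v_state[[pi]] + (1 - cfg$beta2) * g^2
          mhat <- m_state[[pi]] / (1 - cfg$beta1^step)
          vhat <- v_state[[pi]] / (1 - cfg$beta2^step)
          upd <- get_path(model, paths[[pi]]) -
            cfg$lr * mhat / (sqrt(vhat) + 1e-8)
          model <- set_path(model, paths[[pi]], upd)
        }
      }
      loss_trace[ep] <- mean(losses)
      if (verbose && (ep %% 10 == 0 || ep == 1)) {
        message(sprintf("epoch %3d  RMSE %.5f", ep, loss_trace[ep]))
      }
    }
  })
  model$loss_trace <- loss_trace
  model$trained <- TRUE
  model
}

#' Predict firing rates with a fitted encoder
#'
#' @param object an `encoder_model`.
#' @param samples a `sample_batch`.
#' @param ... unused.
#' @return matrix (samples x N) of predicted rates (spikes/s); negative
#'   values are clamped to zero only when the config requests it.
#' @export
predict.encoder_model <- function(object, samples, ...) {
  stopifnot(inherits(samples, "sample_batch"))
  pred <- encoder_forward(object, samples$visual, samples$history)$pred
  if (isTRUE(object$cfg$clamp_negative)) pred <- pmax(pred, 0)
  pred
}
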