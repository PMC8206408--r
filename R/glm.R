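#' Build the GLM design matrix
#'
#' Covariates for the log-linear conditional intensity of each neuron at
#' bin `t` on the width-`w` grid: lagged pixel intensities
#' `I_p(t - m w)` for `m = 0..L` (the current bin included) and lagged
#' population spike counts `S_n(t - m w)` for `m = 1..L`. The visual and
#' history lag ranges are deliberately asymmetric. Rows with incomplete lag
#' coverage (the first `L` bins) are dropped.
#'
#' @param stim a [stim_sequence()] or a precomputed intensity matrix
#'   (`n_bins x P`).
#' @param spikes a `spike_data` object, a `rate_matrix`, or an
#'   `n_bins x N` matrix of binned spike counts.
#' @param w_ms bin width in ms.
#' @param L number of lags (each of width `w_ms`; `L * w_ms` = history
#'   depth in ms).
#' @return list with `X` (rows x (P(L+1) + N L) named covariate matrix),
#'   `counts` (rows x N spike counts), `bin_index`, `w_ms`, `L`, `P`, `N`.
#' @export
glm_design <- function(stim, spikes, w_ms, L) {
  L <- check_count(L, "L")
  intens <- if (inherits(stim, "stim_sequence")) {
    stim_intensity(stim, w_ms)
  } else as.matrix(stim)
  counts <- if (inherits(spikes, "spike_data")) {
    bin_rates(spikes, w_ms)$counts
  } else if (inherits(spikes, "rate_matrix")) {
    spikes$counts
  } else as.matrix(spikes)
  n_bins <- min(nrow(intens), nrow(counts))
  if (n_bins != nrow(intens) && n_bins != nrow(counts)) {
    stop("mismatched stimulus and spike time bases", call. = FALSE)
  }
  if (n_bins <= L) stop("not enough bins for L lags", call. = FALSE)
  p <- ncol(intens); n <- ncol(counts)
  ts <- (L + 1L):n_bins
  xv <- do.call(cbind, lapply(0:L, function(m) intens[ts - m, , drop = FALSE]))
  colnames(xv) <- paste0("v_p", rep(seq_len(p), L + 1L),
                         "_m", rep(0:L, each = p))
  xh <- do.call(cbind, lapply(1:L, function(m) counts[ts - m, , drop = FALSE]))
  colnames(xh) <- paste0("h_n", rep(seq_len(n), L),
                         "_m", rep(1:L, each = n))
  list(X = cbind(xv, xh), counts = counts[ts, , drop = FALSE],
       bin_index = ts, w_ms = w_ms, L = L, P = p, N = n)
}

# Poisson negative IRLS core for one response vector. Newton with
# step-halving so the log-likelihood never decreases; optional L2 ridge on
# the non-intercept coefficients.
poisson_irls <- function(X, y, ridge = 0, max_iter = 100, tol = 1e-10,
                         eta_clip = 30) {
  xa <- cbind(`(Intercept)` = 1, X)
  k <- ncol(xa)
  beta <- numeric(k)
  beta[1] <- log(mean(y) + 1e-12)
  pen <- diag(c(0, rep(ridge, k - 1L)), k)
  ll <- function(b) {
    eta <- pmin(pmax(drop(xa %*% b), -eta_clip), eta_clip)
    sum(y * eta - exp(eta)) - 0.5 * ridge * sum(b[-1]^2)
  }
  ll_old <- ll(beta)
  ll_path <- ll_old
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(xa %*% beta), -eta_clip), eta_clip)
    mu <- exp(eta)
    grad <- drop(crossprod(xa, y - mu)) - ridge * c(0, beta[-1])
    h <- crossprod(xa * mu, xa) + pen
    dir <- tryCatch(solve(h + 1e-10 * diag(k), grad),
                    error = function(e) grad / (max(diag(h)) + 1))
    step <- 1
    repeat {
      cand <- beta + step * dir
      ll_new <- ll(cand)
      if (ll_new >= ll_old - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    if (ll_new < ll_old) { ll_new <- ll_old; cand <- beta }  # give up on this step
    delta <- max(abs(cand - beta))
    beta <- cand
    ll_path <- c(ll_path, ll_new)
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1) && delta < 1e-6) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  list(beta = stats::setNames(beta, colnames(xa)), loglik = ll_old,
       loglik_path = ll_path, converged = converged, iterations = it)
}

#' Fit the Poisson GLM encoder
#'
#' Per-neuron Poisson regression with log link on the design of
#' [glm_design()], maximizing the Poisson log-likelihood of the binned
#' spike counts by Newton's method (with step-halving, so the likelihood
#' path is monotone), optionally with a small L2 ridge for collinear
#' stimuli. Non-convergence is flagged per neuron, never silent.
#'
#' @param design output of [glm_design()].
#' @param ridge L2 penalty on non-intercept weights (default 0; use ~1e-4
#'   for strongly collinear designs).
#' @param max_iter,tol Newton iteration controls.
#' @return A `glm_params` object: `beta0` (N), `beta` (covariates x N),
#'   `loglik`, `converged` (per neuron), plus design metadata.
#' @export
fit_glm_encoder <- function(design, ridge = 0, max_iter = 100, tol = 1e-10) {
  y <- design$counts
  if (any(y < 0) || any(y != round(y))) {
    stop("spike counts must be non-negative integers", call. = FALSE)
  }
  n <- ncol(y)
  fits <- lapply(seq_len(n), function(i) {
    poisson_irls(design$X, y[, i], ridge = ridge, max_iter = max_iter,
                 tol = tol)
  })
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(conv)) {
    warning(sprintf("GLM did not converge for neuron(s): %s",
                    paste(which(!conv), collapse = ", ")))
  }
  beta <- vapply(fits, function(f) f$beta[-1], numeric(ncol(design$X)))
  structure(
    list(beta0 = vapply(fits, function(f) f$beta[1], numeric(1)),
         beta = beta,
         loglik = vapply(fits, `[[`, numeric(1), "loglik"),
         loglik_path = lapply(fits, `[[`, "loglik_path"),
         converged = conv, w_ms = design$w_ms, L = design$L,
         P = design$P, N = design$N, covariates = colnames(design$X)),
    class = "glm_params"
  )
}

#' @export
print.glm_params <- function(x, ...) {
  cat(sprintf("Poisson GLM encoder: N = %d neurons, %d covariates (P = %d, L = %d, w = %d ms)\n",
              x$N, nrow(x$beta), x$P, x$L, x$w_ms))
  cat(sprintf("  converged: %d/%d\n", sum(x$converged), x$N))
  invisible(x)
}

#' Simulate binned spike counts from known GLM parameters
#'
#' Runs the log-linear conditional intensity forward in time on the `w`
#' grid, drawing Poisson counts bin by bin (each bin's history covariates
#' use the counts just drawn). Used for parameter-recovery tests and as a
#' generative model whose structure the GLM fit can represent exactly.
#'
#' @param stim a [stim_sequence()] or intensity matrix (`n_bins x P`).
#' @param beta0 length-N background log-rates.
#' @param beta_v array `(P, L+1, N)` of visual weights (lag m = 0..L).
#' @param beta_h array `(N, L, N)` of history weights (lag m = 1..L);
#'   `beta_h[n, m, i]` weights neuron n's count at lag m in neuron i's
#'   intensity.
#' @param w_ms bin width, ms.
#' @param seed RNG seed.
#' @param eta_clip clip bound on the log intensity.
#' @return list with `counts` (n_bins x N) and `lambda` (expected counts).
#' @export
simulate_glm_population <- function(stim, beta0, beta_v, beta_h, w_ms,
                                    seed = 1, eta_clip = 30) {
  intens <- if (inherits(stim, "stim_sequence")) {
    stim_intensity(stim, w_ms)
  } else as.matrix(stim)
  n <- length(beta0)
  l <- dim(beta_h)[2]
  stopifnot(dim(beta_v)[1] == ncol(intens), dim(beta_v)[2] == l + 1,
            dim(beta_v)[3] == n, dim(beta_h)[1] == n, dim(beta_h)[3] == n)
  n_bins <- nrow(intens)
  counts <- matrix(0L, n_bins, n)
  lambda <- matrix(0, n_bins, n)
  with_seed(seed, {
    for (t in seq_len(n_bins)) {
      eta <- beta0
      for (m in 0:l) {
        if (t - m < 1) break
        eta <- eta + drop(crossprod(beta_v[, m + 1L, , drop = FALSE][, 1, ],
                                    intens[t - m, ]))
      }
      for (m in seq_len(l)) {
        if (t - m < 1) break
        eta <- eta + drop(crossprod(beta_h[, m, , drop = FALSE][, 1, ],
                                    counts[t - m, ]))
      }
      lam <- exp(pmin(pmax(eta, -eta_clip), eta_clip))
      lambda[t, ] <- lam
      counts[t, ] <- stats::rpois(n, lam)
    }
  })
  list(counts = counts, lambda = lambda)
}

#' Predict firing rates from a fitted GLM
#'
#' Conditional intensity `lambda = exp(beta0 + X beta)` per bin (expected
#' spike count), converted to spikes/s by dividing by the bin width. The
#' linear predictor is clipped at `eta_clip` to guard against overflow.
#'
#' @param object a `glm_params` fit.
#' @param design a design from [glm_design()] (its `X` is used).
#' @param eta_clip clip bound on the log intensity.
#' @param ... unused.
#' @return matrix (bins x N) of predicted rates in spikes/s.
#' @export
predict.glm_params <- function(object, design, eta_clip = 30, ...) {
  x <- if (is.list(design) && !is.null(design$X)) design$X else as.matrix(design)
  eta <- sweep(x %*% object$beta, 2, object$beta0, "+")
  lam <- exp(pmin(pmax(eta, -eta_clip), eta_clip))
  lam / (object$w_ms / 1000)
}
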