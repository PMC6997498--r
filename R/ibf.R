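#' Fit the SVD basis-function generative model of a tuning-curve ensemble
#'
#' Decomposes the N x F matrix of trial-averaged tuning curves (N neurons,
#' F grid frequencies) by singular value decomposition and retains the K
#' directions with the largest singular values. Each observed curve is then
#' a weighted sum of K orthogonal frequency basis functions; the per-neuron
#' weights (coefficients) and their per-component empirical distributions
#' are stored so the model can be used generatively. The frequency vectors
#' are additionally smoothed with a centered moving average (edge
#' replication); coefficients are computed against the unsmoothed,
#' orthonormal basis and curves are assembled with the smoothed copy.
#'
#' Each basis vector is oriented so that its largest-magnitude entry is
#' positive (the SVD sign ambiguity).
#'
#' @param rate_matrix N x F matrix of tuning curves (rows = neurons).
#' @param K number of basis functions to retain (1 <= K <= effective rank).
#' @param smooth_width moving-average width for the smoothed basis
#'   (default 3 points).
#' @param freq_log2 optional log2-frequency axis of the F columns.
#' @param group_label optional condition label carried with the model.
#' @return An object of class `basis_model`: `K`, `basis` (F x K,
#'   orthonormal), `basis_smoothed`, `coefficients` (N x K),
#'   `singular_values` (all), `explained_variance` (cumulative fraction per
#'   K), `freq_log2`, `group_label`, `n_neurons`.
#' @export
fit_ibf <- function(rate_matrix, K, smooth_width = 3, freq_log2 = NULL,
                    group_label = NULL) {
  rate_matrix <- as.matrix(rate_matrix)
  N <- nrow(rate_matrix); Fn <- ncol(rate_matrix)
  if (K < 1) stop("K must be >= 1")
  if (K > min(N, Fn)) stop("K must be <= min(n_neurons, n_frequencies)")
  if (anyNA(rate_matrix) || any(!is.finite(rate_matrix)))
    stop("rate matrix must be finite")
  sv <- svd(rate_matrix)
  rank_eff <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
  if (K > rank_eff)
    stop(sprintf("K = %d exceeds the effective rank %d of the rate matrix",
                 K, rank_eff))
  # orient every component so its largest-magnitude entry is positive
  for (l in seq_len(ncol(sv$v))) {
    if (sv$v[which.max(abs(sv$v[, l])), l] < 0) {
      sv$v[, l] <- -sv$v[, l]
      sv$u[, l] <- -sv$u[, l]
    }
  }
  basis <- sv$v[, seq_len(K), drop = FALSE]
  coeff <- sv$u[, seq_len(K), drop = FALSE] %*%
    diag(sv$d[seq_len(K)], nrow = K)
  smoothed <- apply(basis, 2, .moving_average, width = smooth_width)
  smoothed <- matrix(smoothed, nrow = Fn)
  structure(list(K = K, basis = basis, basis_smoothed = smoothed,
                 coefficients = coeff, singular_values = sv$d,
                 explained_variance = cumsum(sv$d ^ 2) / sum(sv$d ^ 2),
                 freq_log2 = freq_log2, group_label = group_label,
                 n_neurons = N),
            class = "basis_model")
}

#' @export
print.basis_model <- function(x, ...) {
  cat(sprintf("basis_model: K = %d (of %d neurons x %d frequencies), explained variance %.1f%%\n",
              x$K, x$n_neurons, nrow(x$basis),
              100 * x$explained_variance[x$K]))
  invisible(x)
}

#' Reconstruct tuning curves from a fitted basis model
#'
#' @param model a [fit_ibf()] model.
#' @param smoothed assemble curves with the smoothed basis (the model's
#'   generative convention); `FALSE` gives the exact rank-K SVD projection.
#' @return N x F matrix of reconstructed curves.
#' @export
reconstruct_curves <- function(model, smoothed = FALSE) {
  stopifnot(inherits(model, "basis_model"))
  model$coefficients %*%
    t(if (smoothed) model$basis_smoothed else model$basis)
}

#' Choose the number of basis functions by held-out trials
#'
#' Splits trials into train/test portions, fits the basis model on
#' train-trial mean curves, and scores each candidate K by the mean squared
#' error between the model-reconstructed curves and the test-trial mean
#' curves. The selected K minimizes the average test MSE (ties toward the
#' smaller K). Both diagnostic curves (explained variance and test MSE vs.
#' K) are returned.
#'
#' @param counts N x F x T array of trial spike counts (>= 2 trials).
#' @param k_candidates candidate numbers of basis functions.
#' @param train_frac fraction of trials used for fitting (default 0.8).
#' @param n_splits random splits averaged per candidate (default 25).
#' @param smooth_width passed to [fit_ibf()].
#' @param seed RNG seed for the splits.
#' @return list: `k_star`, `k_candidates`, `test_mse` (per candidate),
#'   `explained_variance` (full-data cumulative fraction per candidate).
#' @export
select_k <- function(counts, k_candidates = 1:13, train_frac = 0.8,
                     n_splits = 25, smooth_width = 3, seed = 1) {
  stopifnot(length(dim(counts)) == 3)
  N <- dim(counts)[1]; Tn <- dim(counts)[3]
  if (Tn < 2) stop("need at least 2 trials per condition to split")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates < 1)) stop("candidates must be >= 1")
  n_train <- max(1, min(Tn - 1, round(train_frac * Tn)))
  set.seed(seed)
  mse <- matrix(NA_real_, n_splits, length(k_candidates))
  for (s in seq_len(n_splits)) {
    tr <- sample.int(Tn, n_train)
    train_mean <- apply(counts[, , tr, drop = FALSE], c(1, 2), mean)
    test_mean <- apply(counts[, , -tr, drop = FALSE], c(1, 2), mean)
    sv <- svd(train_mean)
    for (j in seq_along(k_candidates)) {
      K <- k_candidates[j]
      if (K > length(sv$d)) next
      recon <- sv$u[, 1:K, drop = FALSE] %*%
        diag(sv$d[1:K], nrow = K) %*% t(
          matrix(apply(sv$v[, 1:K, drop = FALSE], 2, .moving_average,
                       width = smooth_width), nrow = nrow(sv$v)))
      mse[s, j] <- mean((recon - test_mean) ^ 2)
    }
  }
  test_mse <- colMeans(mse)
  full_mean <- apply(counts, c(1, 2), mean)
  d2 <- svd(full_mean, nu = 0, nv = 0)$d ^ 2
  ev <- cumsum(d2) / sum(d2)
  ok <- which(!is.na(test_mse))
  # ties (within numerical tolerance) break toward the smaller K
  best <- min(test_mse[ok])
  k_star <- k_candidates[ok[which(test_mse[ok] <= best * (1 + 1e-9) + 1e-300)[1]]]
  list(k_star = k_star, k_candidates = k_candidates, test_mse = test_mse,
       explained_variance = ev[pmin(k_candidates, length(ev))])
}

#' Sample new model neurons from a fitted basis model
#'
#' Draws each coefficient independently from its per-component empirical
#' distribution (bootstrap resampling of the observed coefficients - the
#' limiting case of histogram sampling as bin width shrinks; a binned
#' variant with Freedman-Diaconis bins and within-bin jitter is available),
#' then assembles rate curves with the smoothed basis. The factorized
#' sampling deliberately discards cross-component correlations. Negative
#' curve values are floored at 0 and counted.
#'
#' @param model a [fit_ibf()] model.
#' @param n number of model neurons (>= 1).
#' @param seed RNG seed.
#' @param binned use binned histogram sampling instead of the bootstrap.
#' @return An object of class `model_ensemble`: `curves` (n x F, floored at
#'   0), `coefficients` (n x K), `freq_log2`, `n_floored`, `provenance`.
#' @export
sample_neurons <- function(model, n, seed = 1, binned = FALSE) {
  stopifnot(inherits(model, "basis_model"))
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  K <- model$K
  coeff <- matrix(NA_real_, n, K)
  for (l in seq_len(K)) {
    obs <- model$coefficients[, l]
    if (binned && length(unique(obs)) > 1) {
      h <- hist(obs, breaks = "FD", plot = FALSE)
      bin <- sample.int(length(h$counts), n, replace = TRUE, prob = h$counts)
      coeff[, l] <- runif(n, h$breaks[bin], h$breaks[bin + 1])
    } else {
      coeff[, l] <- obs[sample.int(length(obs), n, replace = TRUE)]
    }
  }
  curves <- coeff %*% t(model$basis_smoothed)
  n_floored <- sum(curves < 0)
  curves[curves < 0] <- 0
  structure(list(curves = curves, coefficients = coeff,
                 freq_log2 = model$freq_log2, n_floored = n_floored,
                 provenance = list(group_label = model$group_label,
                                   K = K, seed = seed, n = n)),
            class = "model_ensemble")
}

#' Simulate Poisson trial counts at one stimulus frequency
#'
#' Single-trial variability is modelled as independent Poisson counts with
#' means given by each neuron's rate curve, evaluated at a grid frequency
#' or linearly interpolated on the octave axis.
#'
#' @param rates either a numeric vector of per-neuron mean counts, or a
#'   `model_ensemble` together with `f_log2`.
#' @param n_trials number of trials.
#' @param seed RNG seed.
#' @param f_log2 stimulus position on the log2 axis (required for a
#'   `model_ensemble`).
#' @return Integer matrix, neurons x trials.
#' @export
simulate_trials <- function(rates, n_trials, seed = 1, f_log2 = NULL) {
  if (inherits(rates, "model_ensemble")) {
    if (is.null(f_log2)) stop("f_log2 is required for a model ensemble")
    rates <- model_rates_at(rates, f_log2)
  }
  rates <- as.numeric(rates)
  if (any(!is.finite(rates))) stop("rates must be finite")
  if (any(rates < 0)) stop("negative rate encountered")
  set.seed(seed)
  matrix(rpois(length(rates) * n_trials, rates), nrow = length(rates))
}

#' Evaluate model-neuron rate curves at a frequency
#'
#' @param ensemble a `model_ensemble` (or any list with `curves` and
#'   `freq_log2`).
#' @param f_log2 position(s) on the log2-frequency axis; grid points return
#'   the stored values, intermediate points are linearly interpolated.
#' @return Matrix neurons x length(f_log2) of mean counts (vector when a
#'   single frequency is requested).
#' @export
model_rates_at <- function(ensemble, f_log2) {
  x <- ensemble$freq_log2
  if (is.null(x)) stop("ensemble carries no frequency axis")
  out <- t(apply(ensemble$curves, 1, function(r)
    approx(x, r, xout = f_log2, rule = 2)$y))
  if (length(f_log2) == 1) as.numeric(out) else out
}
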