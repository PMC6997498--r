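#' Poisson Fisher information along the frequency axis
#'
#' For a Poisson neuron the Fisher information about the stimulus is
#' I(f) = r'(f)^2 / r(f), with the derivative taken on the log2 (octave)
#' stimulus axis, so units are octave^-2. Derivatives use central
#' differences (one-sided at the grid ends) and rates are floored at
#' `floor_eps` before division. The total information of a
#' noise-independent population is the exact sum of the per-neuron values.
#'
#' @param rate_curves N x F matrix of mean counts per response window
#'   (rows = neurons), or a `model_ensemble`.
#' @param x log2-frequency axis of the F columns (taken from the ensemble
#'   when omitted).
#' @param floor_eps rate floor (default 1e-6 counts/window).
#' @return An object of class `fi_profile`: `x`, `per_neuron` (N x F),
#'   `total` (length F).
#' @export
fisher_information <- function(rate_curves, x = NULL, floor_eps = 1e-6) {
  if (inherits(rate_curves, "model_ensemble")) {
    if (is.null(x)) x <- rate_curves$freq_log2
    rate_curves <- rate_curves$curves
  }
  rate_curves <- as.matrix(rate_curves)
  if (any(!is.finite(rate_curves))) stop("rates must be finite")
  Fn <- ncol(rate_curves)
  stopifnot(!is.null(x), length(x) == Fn, Fn >= 2)
  deriv <- matrix(NA_real_, nrow(rate_curves), Fn)
  deriv[, 1] <- (rate_curves[, 2] - rate_curves[, 1]) / (x[2] - x[1])
  deriv[, Fn] <- (rate_curves[, Fn] - rate_curves[, Fn - 1]) / (x[Fn] - x[Fn - 1])
  if (Fn > 2) {
    for (k in 2:(Fn - 1))
      deriv[, k] <- (rate_curves[, k + 1] - rate_curves[, k - 1]) /
        (x[k + 1] - x[k - 1])
  }
  per_neuron <- deriv ^ 2 / pmax(rate_curves, floor_eps)
  structure(list(x = x, per_neuron = per_neuron,
                 total = colSums(per_neuron)),
            class = "fi_profile")
}

#' Convert a classifier error rate to discriminability d'
#'
#' Equal-prior, symmetric-criterion convention: d' = 2 z(1 - error). When
#' the number of test observations is supplied, the error is clipped to
#' \[1/(2N), 1 - 1/(2N)\] first so perfect classification stays finite.
#'
#' @param error mean test error in \[0, 1\].
#' @param n_obs total number of test observations behind the error
#'   estimate (optional).
#' @return d' (unitless).
#' @export
dprime_from_error <- function(error, n_obs = NULL) {
  stopifnot(error >= 0, error <= 1)
  if (!is.null(n_obs))
    error <- pmin(pmax(error, 1 / (2 * n_obs)), 1 - 1 / (2 * n_obs))
  2 * qnorm(1 - error)
}

#' Linear-decoder discrimination of two nearby frequencies
#'
#' Per iteration, fresh independent Poisson spike-count vectors are drawn
#' for the two stimulus classes, split into training and test trials, and
#' a linear soft-margin SVM (slack cost `cost`) is trained on the
#' per-neuron standardized counts (training-set statistics only). The mean
#' test error over iterations is returned, with early stopping once the
#' running mean error is stable.
#'
#' @param rates1,rates2 per-neuron mean counts at the two frequencies.
#' @param trials_per_class trials generated per class per iteration
#'   (default 20 = 16 train + 4 test, the tone-protocol convention).
#' @param n_train,n_test train/test split per class.
#' @param max_iter maximum iterations (default 500).
#' @param cost SVM slack cost (default 1).
#' @param tol,tol_window early stopping: stop when the running mean error
#'   changes by less than `tol` over `tol_window` iterations.
#' @param seed RNG seed.
#' @return An object of class `decoding_result`: `mean_error`, `accuracy`,
#'   `dprime`, `errors` (per iteration), `n_iter`, `n_neurons`,
#'   `degenerate` (all-zero count vectors throughout; chance reported).
#' @export
decode_pair <- function(rates1, rates2, trials_per_class = 20,
                        n_train = 16, n_test = 4, max_iter = 500,
                        cost = 1, tol = 1e-3, tol_window = 50, seed = 1) {
  rates1 <- as.numeric(rates1); rates2 <- as.numeric(rates2)
  stopifnot(length(rates1) == length(rates2),
            all(rates1 >= 0), all(rates2 >= 0),
            n_train + n_test <= trials_per_class, n_train >= 2, n_test >= 1)
  set.seed(seed)
  N <- length(rates1)
  errors <- numeric(0)
  degenerate_iters <- 0L
  for (it in seq_len(max_iter)) {
    x1 <- matrix(rpois(N * trials_per_class, rates1), ncol = N, byrow = TRUE)
    x2 <- matrix(rpois(N * trials_per_class, rates2), ncol = N, byrow = TRUE)
    tr <- sample.int(trials_per_class, n_train)
    te <- sample(setdiff(seq_len(trials_per_class), tr), n_test)
    xtr <- rbind(x1[tr, , drop = FALSE], x2[tr, , drop = FALSE])
    xte <- rbind(x1[te, , drop = FALSE], x2[te, , drop = FALSE])
    ytr <- factor(rep(c(1, 2), each = n_train))
    yte <- rep(c(1, 2), each = n_test)
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0] <- 1
    xtr <- scale(xtr, center = mu, scale = sdv)
    xte <- scale(xte, center = mu, scale = sdv)
    err <- if (all(xtr == 0)) {
      degenerate_iters <- degenerate_iters + 1L
      0.5
    } else {
      fit <- tryCatch(
        e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) { degenerate_iters <- degenerate_iters + 1L; 0.5 }
      else mean(as.integer(predict(fit, xte)) != yte)
    }
    errors <- c(errors, err)
    if (it >= 2 * tol_window) {
      prev <- mean(errors[seq_len(it - tol_window)])
      if (abs(mean(errors) - prev) < tol) break
    }
  }
  mean_error <- mean(errors)
  structure(list(mean_error = mean_error, accuracy = 1 - mean_error,
                 dprime = dprime_from_error(mean_error,
                                            n_obs = 2 * n_test * length(errors)),
                 errors = errors, n_iter = length(errors), n_neurons = N,
                 degenerate = degenerate_iters == length(errors)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result: error %.3f (d' = %.2f), %d neurons, %d iterations%s\n",
              x$mean_error, x$dprime, x$n_neurons, x$n_iter,
              if (x$degenerate) " [degenerate: chance]" else ""))
  invisible(x)
}

#' Decoder performance as a function of population size
#'
#' For each requested population size N, samples N model neurons (fresh
#' draws from a `basis_model`, or a random subset of a `model_ensemble` /
#' curve matrix) and runs [decode_pair()] between two frequencies on the
#' octave axis.
#'
#' @param model a `basis_model`, `model_ensemble`, or N x F curve matrix
#'   (the last two require `freq_log2`).
#' @param f1_log2,f2_log2 the two stimulus positions (log2 kHz).
#' @param n_values population sizes (non-empty, >= 1).
#' @param n_iter decoding iterations per size.
#' @param seed RNG seed.
#' @param freq_log2 frequency axis when `model` is a plain matrix.
#' @param ... passed to [decode_pair()].
#' @return data.frame: n_neurons, accuracy, mean_error, dprime.
#' @export
performance_vs_n <- function(model, f1_log2, f2_log2, n_values,
                             n_iter = 50, seed = 1, freq_log2 = NULL, ...) {
  if (length(n_values) == 0) stop("n_values must be non-empty")
  if (any(n_values < 1)) stop("population sizes must be >= 1")
  out <- vector("list", length(n_values))
  for (j in seq_along(n_values)) {
    n <- n_values[j]
    sub_seed <- seed + j
    ens <- if (inherits(model, "basis_model")) {
      sample_neurons(model, n, seed = sub_seed)
    } else if (inherits(model, "model_ensemble")) {
      set.seed(sub_seed)
      idx <- sample.int(nrow(model$curves), n,
                        replace = n > nrow(model$curves))
      list(curves = model$curves[idx, , drop = FALSE],
           freq_log2 = model$freq_log2)
    } else {
      set.seed(sub_seed)
      idx <- sample.int(nrow(model), n, replace = n > nrow(model))
      list(curves = as.matrix(model)[idx, , drop = FALSE],
           freq_log2 = freq_log2)
    }
    r1 <- model_rates_at(ens, f1_log2)
    r2 <- model_rates_at(ens, f2_log2)
    dec <- decode_pair(r1, r2, max_iter = n_iter, seed = sub_seed, ...)
    out[[j]] <- data.frame(n_neurons = n, accuracy = dec$accuracy,
                           mean_error = dec$mean_error, dprime = dec$dprime)
  }
  do.call(rbind, out)
}
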