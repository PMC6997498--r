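#' Lifetime sparseness of a neuron's syllable responses
#'
#' S = (1 - \[(sum r_i / n)^2 / (sum r_i^2 / n)\]) / (1 - 1/n), expressed in
#' percent: 0% is a dense code (equal response to every syllable), 100% is
#' maximally sparse (a single responsive syllable).
#'
#' @param r per-syllable trial-mean response rates (n >= 2, all >= 0).
#' @return S in percent, or NA (with a warning) when all responses are 0.
#' @export
lifetime_sparseness <- function(r) {
  r <- as.numeric(r)
  n <- length(r)
  if (n < 2) stop("need at least 2 syllables")
  if (any(r < 0)) stop("responses must be non-negative")
  if (all(r == 0)) {
    warning("all responses are zero: lifetime sparseness undefined")
    return(NA_real_)
  }
  100 * (1 - (mean(r) ^ 2 / mean(r ^ 2))) / (1 - 1 / n)
}

#' Population sparseness per syllable
#'
#' 100 minus the percentage of neurons with a significant response to each
#' syllable.
#'
#' @param sig_matrix logical neurons x syllables matrix (e.g. from
#'   [syllable_significance()]).
#' @return Numeric vector, one value in \[0, 100\] per syllable.
#' @export
population_sparseness <- function(sig_matrix) {
  sig_matrix <- as.matrix(sig_matrix)
  if (nrow(sig_matrix) == 0) stop("need at least one neuron")
  100 - 100 * colMeans(sig_matrix)
}

#' Fano factor of trial spike counts
#'
#' Unbiased sample variance over sample mean of the response-window
#' counts; 1 for a Poisson process.
#'
#' @param counts per-trial spike counts (>= 2 trials).
#' @return variance/mean, or NA (with a warning) when the mean is 0.
#' @export
fano_factor <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("need at least 2 trials")
  m <- mean(counts)
  if (m == 0) {
    warning("zero mean count: Fano factor undefined")
    return(NA_real_)
  }
  var(counts) / m
}

#' Response-similarity matrix across stimulus variants
#'
#' For each pair of stimulus variants, computes per neuron the Pearson
#' correlation between the two variants' response vectors and averages
#' across neurons. In `"rates"` mode (default) the vectors are per-syllable
#' trial-mean rates; in `"psth"` mode they are the trial-mean counts laid
#' out on the call's time axis (zeros in inter-syllable gaps), a coarse
#' count-level PSTH. Neurons with zero variance for a pair are excluded
#' from that pair's mean and counted.
#'
#' @param set a [generate_vocal_responses()] object.
#' @param mode `"rates"` or `"psth"`.
#' @param gap_bins in psth mode, number of silent bins inserted between
#'   syllables.
#' @return An object of class `similarity_matrix`: `r` (S x S, symmetric,
#'   unit diagonal), `n_excluded` (S x S), `per_neuron` (N x S x S),
#'   `speeding_factors`, `mode`.
#' @export
similarity_matrix <- function(set, mode = c("rates", "psth"), gap_bins = 1) {
  stopifnot(inherits(set, "syllable_response_set"))
  mode <- match.arg(mode)
  S <- dim(set$responses)[2]
  if (S < 2) stop("need at least 2 stimulus variants")
  N <- dim(set$responses)[1]; J <- dim(set$responses)[3]
  trial_means <- apply(set$responses, c(1, 2, 3), mean)  # N x S x J
  vec_for <- function(i, s) {
    v <- trial_means[i, s, ]
    if (mode == "rates") v
    else as.vector(rbind(v, matrix(0, gap_bins, J)))  # syllable + gap bins
  }
  rmat <- diag(1, S)
  nexc <- matrix(0L, S, S)
  per_neuron <- array(NA_real_, dim = c(N, S, S))
  for (a in seq_len(S - 1)) for (b in (a + 1):S) {
    rs <- vapply(seq_len(N), function(i) {
      va <- vec_for(i, a); vb <- vec_for(i, b)
      if (sd(va) == 0 || sd(vb) == 0) NA_real_ else cor(va, vb)
    }, numeric(1))
    per_neuron[, a, b] <- per_neuron[, b, a] <- rs
    nexc[a, b] <- nexc[b, a] <- sum(is.na(rs))
    rmat[a, b] <- rmat[b, a] <- mean(rs, na.rm = TRUE)
  }
  for (i in seq_len(N)) per_neuron[i, , ][cbind(1:S, 1:S)] <- 1
  structure(list(r = rmat, n_excluded = nexc, per_neuron = per_neuron,
                 speeding_factors = set$speeding_factors, mode = mode),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s mode), variants s = %s\n", x$mode,
              paste(x$speeding_factors, collapse = ", ")))
  m <- round(x$r, 3)
  dimnames(m) <- list(x$speeding_factors, x$speeding_factors)
  print(m)
  invisible(x)
}

#' Population decoding of vocalization identity vs. syllable count
#'
#' Linear soft-margin SVM discriminating two stimulus variants from
#' pseudo-population spike-count vectors. For each cumulative syllable
#' count k the feature vector concatenates each neuron's counts in
#' syllables 1..k. Accuracy is estimated by leave-one-out cross-validation:
#' each iteration holds out one trial per class, trains on the remaining
#' 15, and tests on the held-out pair; iterations resample the held-out
#' trial and the neuron subset pairing.
#'
#' @param set a [generate_vocal_responses()] object.
#' @param variant_a,variant_b stimulus indices (or speeding-factor values)
#'   to discriminate.
#' @param n_neurons pseudo-population size (default 37); must not exceed
#'   the neurons available.
#' @param n_iter iterations (default 1000).
#' @param cumulative_syllables syllable counts at which to report accuracy
#'   (default 1..J).
#' @param cost SVM slack cost.
#' @param seed RNG seed.
#' @return data.frame of class `vocal_decoding`: n_syllables, accuracy,
#'   se (binomial standard error over iterations).
#' @export
decode_vocal_pair <- function(set, variant_a, variant_b, n_neurons = 37,
                              n_iter = 1000, cumulative_syllables = NULL,
                              cost = 1, seed = 1) {
  stopifnot(inherits(set, "syllable_response_set"))
  to_idx <- function(v) {
    if (v %in% seq_len(dim(set$responses)[2]) && v == round(v) && v >= 1) v
    else match(v, set$speeding_factors)
  }
  a <- to_idx(variant_a); b <- to_idx(variant_b)
  if (is.na(a) || is.na(b) || a == b) stop("invalid stimulus variants")
  N <- dim(set$responses)[1]; J <- dim(set$responses)[3]
  Tn <- dim(set$responses)[4]
  if (n_neurons > N)
    stop(sprintf("requested %d neurons but only %d available", n_neurons, N))
  if (is.null(cumulative_syllables)) cumulative_syllables <- seq_len(J)
  set.seed(seed)
  acc <- matrix(NA_real_, n_iter, length(cumulative_syllables))
  for (it in seq_len(n_iter)) {
    neurons <- sample.int(N, n_neurons)
    # shuffle trial pairings: neurons were not recorded simultaneously
    perm_a <- sample.int(Tn); perm_b <- sample.int(Tn)
    xa <- set$responses[neurons, a, , perm_a, drop = FALSE]  # n x 1 x J x T
    xb <- set$responses[neurons, b, , perm_b, drop = FALSE]
    test_t <- sample.int(Tn, 1)
    for (j in seq_along(cumulative_syllables)) {
      k <- cumulative_syllables[j]
      feat <- function(x, trials) {
        t(vapply(trials, function(tt)
          as.vector(x[, 1, seq_len(k), tt]), numeric(n_neurons * k)))
      }
      xtr <- rbind(feat(xa, setdiff(seq_len(Tn), test_t)),
                   feat(xb, setdiff(seq_len(Tn), test_t)))
      xte <- rbind(feat(xa, test_t), feat(xb, test_t))
      ytr <- factor(rep(c(1, 2), each = Tn - 1))
      mu <- colMeans(xtr); sdv <- apply(xtr, 2, sd); sdv[sdv == 0] <- 1
      xtr <- scale(xtr, center = mu, scale = sdv)
      xte <- scale(xte, center = mu, scale = sdv)
      fit <- tryCatch(
        e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE),
        error = function(e) NULL)
      acc[it, j] <- if (is.null(fit)) 0.5
        else mean(as.integer(predict(fit, xte)) == c(1, 2))
    }
  }
  out <- data.frame(n_syllables = cumulative_syllables,
                    accuracy = colMeans(acc),
                    se = apply(acc, 2, sd) / sqrt(n_iter))
  class(out) <- c("vocal_decoding", "data.frame")
  out
}

#' Sparseness report for a vocal response set
#'
#' Per-neuron lifetime sparseness (original call), per-syllable population
#' sparseness, and per-neuron Fano factors, bundled for group comparison.
#'
#' @param set a [generate_vocal_responses()] object.
#' @param alpha significance level for the per-syllable responsiveness
#'   test.
#' @return list of class `sparseness_report`: `lifetime` (per neuron, %),
#'   `population` (per syllable, %), `fano` (per neuron, mean across
#'   responsive syllables), `group_label`.
#' @export
sparseness_report <- function(set, alpha = 0.05) {
  stopifnot(inherits(set, "syllable_response_set"))
  orig <- which(set$speeding_factors == 1)
  N <- dim(set$responses)[1]; J <- dim(set$responses)[3]
  trial_means <- apply(set$responses[, orig, , , drop = FALSE], c(1, 3), mean)
  lifetime <- suppressWarnings(
    vapply(seq_len(N), function(i) lifetime_sparseness(trial_means[i, ]),
           numeric(1)))
  sig <- syllable_significance(set, stimulus = orig, alpha = alpha)
  fano <- vapply(seq_len(N), function(i) {
    js <- which(sig[i, ])
    if (length(js) == 0) return(NA_real_)
    mean(vapply(js, function(j)
      suppressWarnings(fano_factor(set$responses[i, orig, j, ])),
      numeric(1)), na.rm = TRUE)
  }, numeric(1))
  structure(list(lifetime = lifetime, population = population_sparseness(sig),
                 fano = fano, group_label = set$group_label),
            class = "sparseness_report")
}
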