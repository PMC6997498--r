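#' Generate syllable-resolved responses to a vocalization and its variants
#'
#' Emulates trial-resolved spike counts of a neural population responding to
#' a multi-syllable vocalization played at several "speeding factors"
#' (s = 1 is the original call; smaller s is a stronger temporal
#' manipulation). Two knobs control the population code:
#'
#' * `p_responsive` - the fraction of (neuron, syllable) pairs that respond
#'   at all; lower values give a sparser code (higher lifetime and
#'   population sparseness).
#' * `target_correlations` - the desired Pearson correlation, across a
#'   neuron's syllable-mean rates, between each variant and the original
#'   call. The original call's rate field is a zero-inflated gamma (a
#'   Bernoulli responsiveness mask times gamma-distributed magnitudes);
#'   each variant's field is the mixture `w*z_1 + (1-w)*z_s` of the
#'   original field `z_1` and an independent copy `z_s`, with `w` chosen
#'   so that the latent correlation `w / sqrt(w^2 + (1-w)^2)` equals the
#'   target. Correlations between two modulated variants follow the
#'   one-factor structure (the product of their correlations with the
#'   original). Responsiveness (and hence the sparseness statistics) is
#'   exact for the original call; modulated variants are slightly denser
#'   because independent zeros rarely coincide.
#'
#' Trial counts are independent Poisson draws around the per-(neuron,
#' stimulus, syllable) mean; finite trial counts attenuate measured
#' correlations slightly below the calibration target.
#'
#' @param n_neurons number of neurons.
#' @param group_label `"naive"` or `"expert"`; selects default sparseness and
#'   correlation calibrations (expert: sparser, more decorrelated).
#' @param speeding_factors stimulus variants, in (0, 1]; must include 1.
#' @param target_correlations per-variant target Pearson correlation with the
#'   original call (entry for s = 1 must be 1). `NULL` uses group defaults.
#' @param p_responsive fraction of responsive (neuron, syllable) pairs;
#'   `NULL` uses group defaults (naive 0.45, expert 0.30).
#' @param rate_mean mean evoked count per syllable window for responsive
#'   pairs (default 0.7, i.e. ~7 Hz over a 100-ms window, the scale typical
#'   of layer 2/3 vocalization responses).
#' @param rate_shape gamma shape of the across-(neuron, syllable) rate
#'   distribution (small values give the long-tailed rate spread typical of
#'   cortical populations).
#' @param baseline spontaneous count per window, added to every pair
#'   (default 0.15, ~1.5 Hz).
#' @param n_syllables syllables per call (default 12).
#' @param n_trials repetitions per stimulus (default 16).
#' @param syllable_period_ms syllable onset-to-onset spacing used for the
#'   window schedule.
#' @param seed integer RNG seed.
#' @return An object of class `syllable_response_set`: `responses`
#'   (N x S x J x T integer array: neuron, stimulus, syllable, trial),
#'   `speeding_factors`, `syllable_windows_ms` (J x 2 onset/offset),
#'   `spont_counts` (N x T), `mean_rates` (N x S x J latent means),
#'   `responsive_mask` (N x J), `group_label` and the calibration parameters.
#' @export
generate_vocal_responses <- function(n_neurons,
                                     group_label = c("naive", "expert"),
                                     speeding_factors = c(1, 0.9, 0.81, 0.66),
                                     target_correlations = NULL,
                                     p_responsive = NULL,
                                     rate_mean = 0.7,
                                     rate_shape = 3,
                                     baseline = 0.15,
                                     n_syllables = 12,
                                     n_trials = 16,
                                     syllable_period_ms = 250,
                                     seed = 1) {
  group_label <- match.arg(group_label)
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  if (any(speeding_factors <= 0 | speeding_factors > 1))
    stop("speeding factors must lie in (0, 1]")
  if (!any(speeding_factors == 1))
    stop("speeding_factors must include the original call (s = 1)")
  if (is.null(p_responsive))
    p_responsive <- if (group_label == "naive") 0.55 else 0.40
  if (is.null(target_correlations)) {
    # calibration knobs: expert responses are more decorrelated across
    # variants than naive ones; values interpolated on |1 - s|
    base <- if (group_label == "naive") c(at0 = 0.85, slope = 0.9)
            else c(at0 = 0.70, slope = 0.9)
    target_correlations <- ifelse(speeding_factors == 1, 1,
                                  pmax(0.05, base["at0"] -
                                         base["slope"] * (1 - speeding_factors)))
  }
  if (any(target_correlations < -1 | target_correlations > 1))
    stop("correlation profile must lie within [-1, 1]")
  if (any(target_correlations < 0))
    stop("negative target correlations are not supported by this generator")
  if (abs(target_correlations[speeding_factors == 1] - 1) > 1e-12)
    stop("the original call (s = 1) must have target correlation 1")

  set.seed(seed)
  N <- n_neurons; S <- length(speeding_factors); J <- n_syllables; Tn <- n_trials

  # mixture weight giving latent correlation rho = w / sqrt(w^2 + (1-w)^2)
  weights <- vapply(seq_len(S), function(k) {
    rho <- target_correlations[k]
    if (speeding_factors[k] == 1 || rho >= 1 - 1e-12) return(1)
    if (rho == 0) return(0)
    t <- rho / sqrt(1 - rho ^ 2)
    t / (1 + t)
  }, numeric(1))

  zfield <- function() {
    mask <- matrix(runif(N * J) < p_responsive, N, J)
    mask * matrix(rgamma(N * J, shape = rate_shape,
                         scale = rate_mean / rate_shape), N, J)
  }
  z1 <- zfield()
  mean_rates <- array(0, dim = c(N, S, J))
  for (k in seq_len(S)) {
    w <- weights[k]
    mean_rates[, k, ] <- baseline +
      (if (w == 1) z1 else w * z1 + (1 - w) * zfield())
  }
  mask <- z1 > 0
  responses <- array(rpois(N * S * J * Tn, rep(mean_rates, Tn)),
                     dim = c(N, S, J, Tn))
  spont_counts <- matrix(rpois(N * Tn, baseline), N, Tn)
  onsets <- (seq_len(J) - 1) * syllable_period_ms
  windows <- cbind(onset_ms = onsets, offset_ms = onsets + 100)

  structure(list(responses = responses, speeding_factors = speeding_factors,
                 syllable_windows_ms = windows, spont_counts = spont_counts,
                 mean_rates = mean_rates, responsive_mask = mask,
                 group_label = group_label,
                 params = list(p_responsive = p_responsive, rate_mean = rate_mean,
                               rate_shape = rate_shape, baseline = baseline,
                               target_correlations = target_correlations,
                               weights = weights, n_trials = Tn, seed = seed)),
            class = "syllable_response_set")
}

#' @export
print.syllable_response_set <- function(x, ...) {
  cat(sprintf(
    "syllable_response_set: %d %s neurons, %d variants (s = %s), %d syllables, %d trials\n",
    dim(x$responses)[1], x$group_label, dim(x$responses)[2],
    paste(x$speeding_factors, collapse = ", "), dim(x$responses)[3],
    dim(x$responses)[4]))
  invisible(x)
}

#' Per-syllable responsiveness mask from trial counts
#'
#' Applies the two-sample t-test of syllable-window counts against the
#' spontaneous-window counts, per (neuron, syllable), for one stimulus
#' variant. Used for population sparseness.
#'
#' @param set a `syllable_response_set`.
#' @param stimulus variant index (default the original call, s = 1).
#' @param alpha significance level.
#' @return Logical N x J matrix.
#' @export
syllable_significance <- function(set, stimulus = which(set$speeding_factors == 1),
                                  alpha = 0.05) {
  stopifnot(inherits(set, "syllable_response_set"))
  N <- dim(set$responses)[1]; J <- dim(set$responses)[3]
  sig <- matrix(FALSE, N, J)
  for (i in seq_len(N)) {
    for (j in seq_len(J)) {
      p <- responsiveness_test(set$responses[i, stimulus, j, ],
                               set$spont_counts[i, ])$p_value
      sig[i, j] <- p < alpha
    }
  }
  sig
}

#' Time-warp a syllable waveform by a speeding factor
#'
#' Re-maps the syllable's time axis with a local playback speed that ramps
#' linearly from `s` at syllable onset to `2 - s` at offset, and rebuilds
#' the waveform by cubic interpolation from the original samples. Because
#' the ramp integrates to 1, total syllable duration is preserved; for
#' s = 0.6 the syllable starts 0.4 slower and ends 0.4 faster than the
#' original.
#'
#' @param waveform numeric vector of samples (finite).
#' @param s speeding factor in (0, 1]; s = 1 returns the input unchanged.
#' @return Numeric vector of the same length as `waveform`.
#' @export
warp_syllable <- function(waveform, s) {
  if (!is.numeric(waveform) || !all(is.finite(waveform)))
    stop("waveform must be a finite numeric vector")
  if (length(s) != 1 || s <= 0 || s > 1)
    stop("speeding factor s must lie in (0, 1]")
  n <- length(waveform)
  if (n < 2 || s == 1) return(waveform)
  u <- (seq_len(n) - 1) / (n - 1)             # normalized output time
  # position read from the original signal: integral of the speed ramp
  psi <- (n - 1) * (s * u + (1 - s) * u ^ 2)
  stats::spline(x = seq_len(n) - 1, y = waveform, xout = psi,
                method = "fmm")$y
}
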