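#' Specification for a synthetic tuning-curve ensemble
#'
#' Describes the statistical structure of a population of frequency-tuned
#' neurons: how best frequencies (BFs) are distributed on the octave axis,
#' how heterogeneous the tuning shapes are (asymmetry, occasional second
#' mode), and the firing-rate scales. The defaults encode the two study
#' conditions: `"naive"` populations have BFs spread broadly over the grid,
#' `"expert"` populations have BFs concentrated toward the 7.1-10 kHz
#' training band.
#'
#' @param n_neurons number of neurons (>= 0).
#' @param group_label `"naive"` or `"expert"`; selects the default BF mixture.
#' @param bf_components optional data.frame with columns `center_oct`,
#'   `spread_oct`, `weight` describing a Gaussian mixture on the log2 axis
#'   from which BFs are drawn. When `NULL`, group defaults are used.
#' @param width_oct mean and sd of the (log-normal) tuning half-width in
#'   octaves.
#' @param skew_range range of the right/left width ratio; values away from 1
#'   produce asymmetric tuning curves.
#' @param p_bimodal probability that a neuron carries a second, weaker mode.
#' @param peak_rate_hz mean evoked rate at BF (Hz, at the best level).
#' @param spontaneous_rate_hz baseline rate (Hz).
#' @param n_trials trials per frequency-level combination.
#' @param window_ms response-window length used to convert rates to expected
#'   spike counts (ms).
#' @param training_band_khz the trained frequency interval, default 7.1-10 kHz.
#' @param p_pv fraction of neurons labelled PV+ (metadata only).
#' @param neurons_per_site neurons sharing a recording-site label, used to
#'   define "neighboring" pairs for signal correlations.
#' @param seed integer RNG seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_neurons,
                          group_label = c("naive", "expert"),
                          bf_components = NULL,
                          width_oct = c(0.45, 0.12),
                          skew_range = c(0.6, 1.8),
                          p_bimodal = 0.25,
                          peak_rate_hz = 40,
                          spontaneous_rate_hz = 1,
                          n_trials = 20,
                          window_ms = 100,
                          training_band_khz = c(7.1, 10),
                          p_pv = 0,
                          neurons_per_site = 4,
                          seed = 1) {
  group_label <- match.arg(group_label)
  if (n_neurons < 0) stop("n_neurons must be >= 0")
  if (peak_rate_hz < 0 || spontaneous_rate_hz < 0)
    stop("rates must be non-negative")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (training_band_khz[1] <= 0 || training_band_khz[2] <= training_band_khz[1])
    stop("training band must be an increasing positive interval")
  if (is.null(bf_components)) {
    band_center <- mean(log2(training_band_khz))
    bf_components <- if (group_label == "naive") {
      # broad coverage of the grid, as seen in untrained animals
      data.frame(center_oct = log2(sqrt(3 * 40)), spread_oct = 1.3, weight = 1)
    } else {
      # concentration toward the training band after learning, with a broad
      # remainder (calibration knob: the shift direction is what matters)
      data.frame(center_oct = c(band_center, log2(sqrt(3 * 40))),
                 spread_oct = c(0.35, 1.3),
                 weight = c(0.7, 0.3))
    }
  }
  stopifnot(all(c("center_oct", "spread_oct", "weight") %in% names(bf_components)),
            all(bf_components$weight >= 0), sum(bf_components$weight) > 0)
  structure(list(n_neurons = as.integer(n_neurons), group_label = group_label,
                 bf_components = bf_components, width_oct = width_oct,
                 skew_range = skew_range, p_bimodal = p_bimodal,
                 peak_rate_hz = peak_rate_hz,
                 spontaneous_rate_hz = spontaneous_rate_hz,
                 n_trials = as.integer(n_trials), window_ms = window_ms,
                 training_band_khz = training_band_khz, p_pv = p_pv,
                 neurons_per_site = as.integer(neurons_per_site),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# two-sided (split-width) Gaussian bump on the octave axis; mode at mu
.skew_bump <- function(x, mu, w_left, w_right) {
  w <- ifelse(x < mu, w_left, w_right)
  exp(-0.5 * ((x - mu) / w) ^ 2)
}

#' Generate a synthetic tuning-curve ensemble with Poisson trial noise
#'
#' Draws one heterogeneous tuning curve per neuron (a skewed bump on the
#' octave axis, optionally with a second weaker mode, BF drawn from the
#' spec's mixture), a monotone level-gain profile per neuron, and independent
#' Poisson spike counts per trial. Spontaneous (pre-stimulus window) counts
#' are generated alongside so that responsiveness tests and FRA significance
#' masks can be computed exactly as for recorded cells.
#'
#' @param spec an [ensemble_spec()].
#' @param grid a [stimulus_grid()].
#' @return An object of class `tuning_ensemble` with fields:
#'   `grid`; `neurons` (data.frame: neuron_id, group, cell_class, site,
#'   bf_true_khz); `rate_curves` (N x F matrix of level-averaged expected
#'   counts per response window); `counts` (N x F x L x T integer array);
#'   `spont_counts` (N x (L*T) matrix of pre-stimulus window counts);
#'   `window_ms`; `spec`.
#' @export
generate_tuning_ensemble <- function(spec, grid) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(grid, "stimulus_grid"))
  band <- log2(spec$training_band_khz)
  if (band[1] < min(grid$log2_axis) || band[2] > max(grid$log2_axis))
    stop("training band lies outside the grid span")
  set.seed(spec$seed)
  N <- spec$n_neurons
  x <- grid$log2_axis
  Fn <- length(x); L <- length(grid$levels_db); Tn <- spec$n_trials
  win_s <- spec$window_ms / 1000
  peak_count <- spec$peak_rate_hz * win_s
  spont_count <- spec$spontaneous_rate_hz * win_s

  neurons <- data.frame(neuron_id = character(0), group = character(0),
                        cell_class = character(0), site = character(0),
                        bf_true_khz = numeric(0))
  rate_curves <- matrix(0, N, Fn)
  counts <- array(0L, dim = c(N, Fn, L, Tn))
  spont_counts <- matrix(0L, N, L * Tn)
  comp <- spec$bf_components
  pw <- comp$weight / sum(comp$weight)

  if (N > 0) {
    for (i in seq_len(N)) {
      k <- sample.int(nrow(comp), 1, prob = pw)
      mu <- rnorm(1, comp$center_oct[k], comp$spread_oct[k])
      mu <- min(max(mu, min(x)), max(x))
      w0 <- exp(rnorm(1, log(spec$width_oct[1]),
                      spec$width_oct[2] / spec$width_oct[1]))
      skew <- runif(1, spec$skew_range[1], spec$skew_range[2])
      shape <- .skew_bump(x, mu, w0, w0 * skew)
      if (runif(1) < spec$p_bimodal) {
        mu2 <- runif(1, min(x), max(x))
        shape <- shape + runif(1, 0.2, 0.6) * .skew_bump(x, mu2, w0, w0)
      }
      shape <- shape / max(shape)
      evoked <- peak_count * shape
      # monotone level gain: threshold-like growth with sound level
      thr <- runif(1, 40, 55)
      gain <- plogis((grid$levels_db - thr) / 8)
      gain <- gain / max(gain)
      mean_counts <- outer(evoked, gain) + spont_count        # F x L
      counts[i, , , ] <- array(rpois(Fn * L * Tn, rep(mean_counts, Tn)),
                               dim = c(Fn, L, Tn))
      spont_counts[i, ] <- rpois(L * Tn, spont_count)
      rate_curves[i, ] <- rowMeans(mean_counts)
      neurons[i, ] <- list(sprintf("%s_n%03d", spec$group_label, i),
                           spec$group_label,
                           if (runif(1) < spec$p_pv) "PV+" else "PV-",
                           sprintf("site%02d",
                                   (i - 1) %/% spec$neurons_per_site + 1),
                           2 ^ x[which.max(rate_curves[i, ])])
    }
  }
  structure(list(grid = grid, neurons = neurons, rate_curves = rate_curves,
                 counts = counts, spont_counts = spont_counts,
                 window_ms = spec$window_ms, spec = spec),
            class = "tuning_ensemble")
}

#' @export
print.tuning_ensemble <- function(x, ...) {
  cat(sprintf("tuning_ensemble: %d %s neurons, %d x %d grid, %d trials\n",
              nrow(x$neurons), x$spec$group_label,
              length(x$grid$frequencies_khz), length(x$grid$levels_db),
              x$spec$n_trials))
  invisible(x)
}
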