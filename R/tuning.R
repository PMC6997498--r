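#' Peri-stimulus time histogram
#'
#' @param spike_times_by_trial list of numeric vectors of spike times (ms,
#'   relative to stimulus onset), one per trial.
#' @param t_min_ms,t_max_ms histogram range (ms).
#' @param bin_ms bin width; 1 ms by default, matching millisecond-rounded
#'   spike times.
#' @return An object of class `psth`: `bin_edges_ms`, `mean_counts`
#'   (mean spike count per bin per trial), `n_trials`, `bin_ms`.
#' @export
compute_psth <- function(spike_times_by_trial, t_min_ms = -100,
                         t_max_ms = 400, bin_ms = 1) {
  stopifnot(is.list(spike_times_by_trial), length(spike_times_by_trial) >= 1,
            t_max_ms > t_min_ms, bin_ms > 0)
  edges <- seq(t_min_ms, t_max_ms, by = bin_ms)
  counts <- vapply(spike_times_by_trial, function(tt) {
    tt <- tt[tt >= t_min_ms & tt < t_max_ms]
    hist(tt, breaks = edges, plot = FALSE, right = FALSE)$counts
  }, numeric(length(edges) - 1))
  structure(list(bin_edges_ms = edges,
                 mean_counts = rowMeans(as.matrix(counts)),
                 n_trials = length(spike_times_by_trial), bin_ms = bin_ms),
            class = "psth")
}

#' Response-window selection from a PSTH
#'
#' Scans all 100-ms windows starting at each bin edge at or after stimulus
#' onset and returns the one with the maximal summed PSTH count (the
#' maximal response integral). Ties are broken toward the earliest window;
#' an all-zero PSTH returns the earliest window, flagged.
#'
#' @param psth a [compute_psth()] object.
#' @param onset_ms stimulus onset (ms); candidate windows start here or
#'   later.
#' @param width_ms window length (default 100 ms).
#' @return list: `onset_ms`, `width_ms`, `integral`, `tied` (multiple
#'   windows share the maximum), `all_zero`.
#' @export
find_response_window <- function(psth, onset_ms = 0, width_ms = 100) {
  stopifnot(inherits(psth, "psth"))
  edges <- psth$bin_edges_ms
  nb <- round(width_ms / psth$bin_ms)
  starts <- which(edges >= onset_ms - 1e-9)
  starts <- starts[starts + nb - 1 <= length(psth$mean_counts)]
  if (length(starts) == 0) stop("PSTH does not cover a full window after onset")
  cs <- c(0, cumsum(psth$mean_counts))
  integrals <- cs[starts + nb] - cs[starts]
  best <- which.max(integrals)               # earliest maximum
  list(onset_ms = edges[starts[best]], width_ms = width_ms,
       integral = integrals[best],
       tied = sum(abs(integrals - integrals[best]) < 1e-12) > 1,
       all_zero = all(psth$mean_counts == 0))
}

#' Evoked-response significance test
#'
#' Pooled-variance two-sample t-test of response-window spike counts
#' against matched pre-stimulus (spontaneous) window counts.
#'
#' @param evoked_counts,spontaneous_counts numeric vectors of per-trial
#'   spike counts (>= 2 trials each).
#' @param alpha significance level (default 0.05).
#' @return list: `p_value`, `is_responsive`.
#' @export
responsiveness_test <- function(evoked_counts, spontaneous_counts,
                                alpha = 0.05) {
  if (length(evoked_counts) < 2 || length(spontaneous_counts) < 2)
    stop("need at least 2 trials per sample")
  p <- if (sd(evoked_counts) == 0 && sd(spontaneous_counts) == 0) {
    if (mean(evoked_counts) == mean(spontaneous_counts)) 1 else 0
  } else {
    t.test(evoked_counts, spontaneous_counts, var.equal = TRUE)$p.value
  }
  list(p_value = p, is_responsive = p < alpha)
}

#' Frequency-response area for one neuron
#'
#' Builds the matrix of trial-averaged response-window counts over the
#' frequency x level grid and a Bonferroni-corrected significance mask:
#' each combination is tested against the spontaneous counts at level
#' alpha / (n_freq * n_level).
#'
#' @param counts numeric array F x L x T of response-window spike counts.
#' @param spont_counts per-trial spontaneous window counts.
#' @param grid the [stimulus_grid()] the counts were recorded on.
#' @param alpha family-wise significance level (default 0.05).
#' @param window_ms response-window length (ms), carried as metadata.
#' @return An object of class `fra`: `mean_counts` (F x L), `p_values`,
#'   `mask` (logical F x L), `window_ms`, `grid`.
#' @export
build_fra <- function(counts, spont_counts, grid, alpha = 0.05,
                      window_ms = 100) {
  stopifnot(inherits(grid, "stimulus_grid"), length(dim(counts)) == 3)
  Fn <- length(grid$frequencies_khz); L <- length(grid$levels_db)
  if (dim(counts)[1] != Fn || dim(counts)[2] != L)
    stop("counts array does not match the grid")
  if (anyNA(counts)) {
    miss <- which(apply(counts, c(1, 2), anyNA), arr.ind = TRUE)
    stop("missing frequency/level combinations: ",
         paste(sprintf("(%.3g kHz, %g dB)", grid$frequencies_khz[miss[, 1]],
                       grid$levels_db[miss[, 2]]), collapse = ", "))
  }
  pmat <- matrix(NA_real_, Fn, L)
  for (f in seq_len(Fn)) for (l in seq_len(L))
    pmat[f, l] <- responsiveness_test(counts[f, l, ], spont_counts)$p_value
  structure(list(mean_counts = apply(counts, c(1, 2), mean),
                 p_values = pmat,
                 mask = pmat < alpha / (Fn * L),
                 window_ms = window_ms, grid = grid),
            class = "fra")
}

#' Single-neuron tuning summary
#'
#' Extracts the standard per-cell statistics from an FRA (and optionally a
#' PSTH): best frequency (the tone with the strongest level-averaged
#' response; ties go to the lower frequency), selectivity (% of
#' frequency-level combinations with a significant response), evoked rate
#' at BF, mean rate over the training band, spontaneous rate, and response
#' latency (time of the smoothed PSTH peak).
#'
#' @param fra a [build_fra()] object.
#' @param psth optional [compute_psth()] object for latency.
#' @param spont_counts optional per-trial spontaneous counts for the
#'   spontaneous rate.
#' @param training_band_khz band for the in-band rate summary (default
#'   7-10 kHz).
#' @param latency_smooth_ms moving-average width applied to the PSTH before
#'   peak-picking (default 5 ms), which avoids single-spike peaks.
#' @return data.frame with one row: bf_khz, selectivity_pct,
#'   evoked_rate_bf_hz, rate_training_band_hz, spontaneous_hz, latency_ms,
#'   is_responsive.
#' @export
summarize_neuron <- function(fra, psth = NULL, spont_counts = NULL,
                             training_band_khz = c(7, 10),
                             latency_smooth_ms = 5) {
  stopifnot(inherits(fra, "fra"))
  win_s <- fra$window_ms / 1000
  curve <- rowMeans(fra$mean_counts)          # level-averaged tuning curve
  bf_idx <- which.max(curve)                  # ties -> lowest frequency
  freqs <- fra$grid$frequencies_khz
  in_band <- freqs >= training_band_khz[1] & freqs <= training_band_khz[2]
  lat <- NA_real_
  if (!is.null(psth)) {
    sm <- .moving_average(psth$mean_counts,
                          max(1, round(latency_smooth_ms / psth$bin_ms)))
    post <- which(psth$bin_edges_ms[-length(psth$bin_edges_ms)] >= 0)
    lat <- psth$bin_edges_ms[post[which.max(sm[post])]] + psth$bin_ms / 2
  }
  data.frame(bf_khz = freqs[bf_idx],
             selectivity_pct = 100 * mean(fra$mask),
             evoked_rate_bf_hz = mean(fra$mean_counts[bf_idx, ]) / win_s,
             rate_training_band_hz =
               if (any(in_band)) mean(fra$mean_counts[in_band, ]) / win_s
               else NA_real_,
             spontaneous_hz =
               if (is.null(spont_counts)) NA_real_
               else mean(spont_counts) / win_s,
             latency_ms = lat,
             is_responsive = any(fra$mask))
}

#' Signal correlation between two FRAs
#'
#' Pearson correlation over all frequency-level entries of the two
#' trial-averaged response matrices. Returns NA (with a warning) when
#' either FRA has zero variance.
#'
#' @param fra_a,fra_b [build_fra()] objects on the same grid.
#' @return Pearson r in \[-1, 1\], or NA.
#' @export
signal_correlation <- function(fra_a, fra_b) {
  stopifnot(inherits(fra_a, "fra"), inherits(fra_b, "fra"))
  if (!identical(dim(fra_a$mean_counts), dim(fra_b$mean_counts)))
    stop("FRAs are on different grids")
  a <- as.vector(fra_a$mean_counts); b <- as.vector(fra_b$mean_counts)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance FRA: signal correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

# centered moving average with edge replication
.moving_average <- function(v, width) {
  if (width <= 1) return(v)
  half <- (width - 1) %/% 2
  vp <- c(rep(v[1], half), v, rep(v[length(v)], width - 1 - half))
  as.numeric(stats::filter(vp, rep(1 / width, width), sides = 2))[
    (half + 1):(half + length(v))]
}

#' Summarize every neuron of a synthetic ensemble
#'
#' Convenience wrapper applying [build_fra()] and [summarize_neuron()] to
#' each neuron of a [generate_tuning_ensemble()] object.
#'
#' @param ensemble a `tuning_ensemble`.
#' @param training_band_khz band for the in-band rate summary.
#' @param alpha FRA family-wise significance level.
#' @return data.frame with one row per neuron (neuron metadata plus the
#'   [summarize_neuron()] columns).
#' @export
summarize_ensemble <- function(ensemble, training_band_khz = c(7, 10),
                               alpha = 0.05) {
  stopifnot(inherits(ensemble, "tuning_ensemble"))
  N <- nrow(ensemble$neurons)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    fra <- build_fra(ensemble$counts[i, , , , drop = TRUE],
                     ensemble$spont_counts[i, ], ensemble$grid,
                     alpha = alpha, window_ms = ensemble$window_ms)
    out[[i]] <- cbind(ensemble$neurons[i, , drop = FALSE],
                      summarize_neuron(fra, spont_counts = ensemble$spont_counts[i, ],
                                       training_band_khz = training_band_khz))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise signal correlations of neighboring neurons
#'
#' Computes [signal_correlation()] for every pair of neurons sharing a
#' recording-site label (the synthetic stand-in for anatomical proximity).
#'
#' @param ensemble a `tuning_ensemble`.
#' @param alpha FRA significance level (masks are not used for r, but FRAs
#'   are built with it).
#' @return data.frame: neuron_a, neuron_b, site, r.
#' @export
pairwise_signal_correlations <- function(ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "tuning_ensemble"))
  fras <- lapply(seq_len(nrow(ensemble$neurons)), function(i)
    build_fra(ensemble$counts[i, , , , drop = TRUE],
              ensemble$spont_counts[i, ], ensemble$grid,
              alpha = alpha, window_ms = ensemble$window_ms))
  out <- list()
  for (site in unique(ensemble$neurons$site)) {
    idx <- which(ensemble$neurons$site == site)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      out[[length(out) + 1]] <- data.frame(
        neuron_a = ensemble$neurons$neuron_id[i],
        neuron_b = ensemble$neurons$neuron_id[j],
        site = site,
        r = suppressWarnings(signal_correlation(fras[[i]], fras[[j]])))
    }
  }
  if (length(out) == 0)
    return(data.frame(neuron_a = character(0), neuron_b = character(0),
                      site = character(0), r = numeric(0)))
  do.call(rbind, out)
}
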