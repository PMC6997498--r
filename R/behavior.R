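# rate clipped away from 0/1 so the probit transform stays finite;
# standard 1/(2N) correction for extreme proportions
.clip_rate <- function(k, n) {
  pmin(pmax(k / n, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Signal-detection sensitivity (d-prime) from trial counts
#'
#' d' = z(hit rate) - z(FA rate), where z is the inverse cumulative standard
#' normal. Rates are clipped to \[1/(2N), 1 - 1/(2N)\] before the transform
#' so perfect scores remain finite.
#'
#' @param hits,misses number of lick / no-lick responses to the target.
#' @param fas,crs number of lick / no-lick responses to the non-target.
#' @return An object of class `dprime_result`: `hit_rate`, `fa_rate`
#'   (post-clipping), `dprime`, `n_target`, `n_nontarget`, `clipped`.
#' @examples
#' dprime(50, 50, 50, 50)$dprime  # equal rates: 0
#' @export
dprime <- function(hits, misses, fas, crs) {
  if (any(c(hits, misses, fas, crs) < 0)) stop("counts must be non-negative")
  n_t <- hits + misses
  n_n <- fas + crs
  if (n_t < 1 || n_n < 1) stop("need at least one target and one non-target trial")
  hr <- .clip_rate(hits, n_t)
  fr <- .clip_rate(fas, n_n)
  structure(list(hit_rate = hr, fa_rate = fr,
                 dprime = qnorm(hr) - qnorm(fr),
                 n_target = n_t, n_nontarget = n_n,
                 clipped = (hr != hits / n_t) || (fr != fas / n_n)),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.3f (hit %.3f, FA %.3f; %d target, %d non-target%s)\n",
              x$dprime, x$hit_rate, x$fa_rate, x$n_target, x$n_nontarget,
              if (x$clipped) ", clipped" else ""))
  invisible(x)
}

.log_counts <- function(log) {
  stopifnot(inherits(log, "data.frame"))
  list(hits = sum(log$outcome == "hit"), misses = sum(log$outcome == "miss"),
       fas = sum(log$outcome == "fa"), crs = sum(log$outcome == "cr"))
}

#' Blockwise learning curve from a behavior log
#'
#' Splits the (non-catch) trials of a log into consecutive non-overlapping
#' bins and computes hit rate, FA rate and d' per bin.
#'
#' @param log a `behavior_log` (or any data.frame with an `outcome` column).
#' @param bin_trials trials per bin (default 20). A bin missing either trial
#'   class gets `NA` d'.
#' @return data.frame with one row per bin: bin, trial_start, trial_end,
#'   n_target, n_nontarget, hit_rate, fa_rate, dprime.
#' @export
learning_curve <- function(log, bin_trials = 20) {
  if (nrow(log) == 0) stop("empty behavior log")
  if (bin_trials < 1) stop("bin_trials must be >= 1")
  log <- log[log$stimulus_kind != "catch", , drop = FALSE]
  n <- nrow(log)
  bins <- split(seq_len(n), ceiling(seq_len(n) / bin_trials))
  out <- do.call(rbind, lapply(seq_along(bins), function(b) {
    idx <- bins[[b]]
    cc <- .log_counts(log[idx, ])
    dp <- if (cc$hits + cc$misses >= 1 && cc$fas + cc$crs >= 1)
      dprime(cc$hits, cc$misses, cc$fas, cc$crs) else NULL
    data.frame(bin = b, trial_start = min(idx), trial_end = max(idx),
               n_target = cc$hits + cc$misses, n_nontarget = cc$fas + cc$crs,
               hit_rate = if (is.null(dp)) NA_real_ else dp$hit_rate,
               fa_rate = if (is.null(dp)) NA_real_ else dp$fa_rate,
               dprime = if (is.null(dp)) NA_real_ else dp$dprime)
  }))
  rownames(out) <- NULL
  out
}

#' Per-stage d-prime summary
#'
#' Stage performance is summarized from the trials in the final portion of
#' each stage (default the last third), after learning within the stage has
#' plateaued.
#'
#' @param log a `behavior_log` with a `stage_id` column.
#' @param final_frac fraction of each stage's trials used (default 1/3).
#' @return data.frame: stage_id, n_trials_used, hit_rate, fa_rate, dprime.
#' @export
stage_dprime <- function(log, final_frac = 1/3) {
  if (nrow(log) == 0) stop("empty behavior log")
  stopifnot(final_frac > 0, final_frac <= 1)
  log <- log[log$stimulus_kind != "catch", , drop = FALSE]
  out <- do.call(rbind, lapply(split(log, log$stage_id), function(st) {
    n <- nrow(st)
    keep <- st[seq.int(n - ceiling(final_frac * n) + 1, n), ]
    cc <- .log_counts(keep)
    dp <- dprime(cc$hits, cc$misses, cc$fas, cc$crs)
    data.frame(stage_id = st$stage_id[1], n_trials_used = nrow(keep),
               hit_rate = dp$hit_rate, fa_rate = dp$fa_rate,
               dprime = dp$dprime)
  }))
  rownames(out) <- NULL
  out[order(out$stage_id), ]
}

#' Fit a psychometric curve to catch-trial responses
#'
#' Aggregates lick proportions per probe frequency and fits a 4-parameter
#' logistic on the log2 (octave) frequency axis:
#' p(x) = floor + (ceiling - floor) / (1 + exp(-slope (x - x0))).
#' The decision boundary is the inflection point x0, reported in kHz.
#'
#' @param freq_khz probe-tone frequency of each catch trial (kHz).
#' @param licked logical lick response per catch trial.
#' @return An object of class `psychometric_fit`: `data` (freq_khz, n,
#'   lick_prop), `pars` (floor, ceiling, slope, inflection_oct),
#'   `boundary_khz`, `converged`, `degenerate`.
#' @export
fit_psychometric <- function(freq_khz, licked) {
  stopifnot(length(freq_khz) == length(licked))
  agg <- aggregate(list(lick_prop = as.numeric(licked)),
                   by = list(freq_khz = freq_khz), FUN = mean)
  agg$n <- as.vector(table(freq_khz)[as.character(agg$freq_khz)])
  agg <- agg[order(agg$freq_khz), c("freq_khz", "n", "lick_prop")]
  if (nrow(agg) < 4) stop("need at least 4 distinct catch frequencies")
  x <- log2(agg$freq_khz); y <- agg$lick_prop

  res <- list(data = agg, pars = c(floor = NA, ceiling = NA, slope = NA,
                                   inflection_oct = NA),
              boundary_khz = NA_real_, converged = FALSE, degenerate = FALSE)
  class(res) <- "psychometric_fit"
  if (diff(range(y)) < 0.05) {       # flat curve: no boundary to estimate
    res$degenerate <- TRUE
    res$pars[] <- c(mean(y), mean(y), 0, NA)
    return(res)
  }
  increasing <- cor(x, y) >= 0
  start <- list(lo = max(min(y), 1e-3), hi = min(max(y), 1 - 1e-3),
                k = if (increasing) 8 else -8,
                x0 = stats::weighted.mean(x, w = abs(y - mean(y)) + 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ lo + (hi - lo) * plogis(k * (x - x0)),
                      start = start, weights = agg$n,
                      lower = c(0, 0, -200, min(x) - 1),
                      upper = c(1, 1, 200, max(x) + 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res$diagnostics <- conditionMessage(fit)
    return(res)
  }
  cf <- coef(fit)
  res$pars[] <- c(cf["lo"], cf["hi"], cf["k"], cf["x0"])
  res$boundary_khz <- 2 ^ cf[["x0"]]
  res$converged <- TRUE
  if (abs(cf[["k"]]) < 0.5) res$degenerate <- TRUE
  res
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$degenerate) cat("psychometric_fit: degenerate (flat curve)\n")
  else if (!x$converged) cat("psychometric_fit: did not converge\n")
  else cat(sprintf("psychometric_fit: boundary %.3f kHz (slope %.2f/oct, floor %.2f, ceiling %.2f)\n",
                   x$boundary_khz, x$pars["slope"], x$pars["floor"],
                   x$pars["ceiling"]))
  invisible(x)
}

#' Lick-based detection time
#'
#' Bins lick times of hit and correct-rejection trials, runs a two-sample
#' t-test of per-trial lick counts in each bin, and returns the center of
#' the earliest bin whose p-value first crosses `alpha`. Per the stated
#' rule, the first crossing is taken and no multiple-bin correction is
#' applied.
#'
#' @param hit_lick_rasters,cr_lick_rasters lists of numeric vectors of lick
#'   times (ms), one vector per trial. An optional `duration_ms` attribute
#'   on each list must agree between the two classes.
#' @param duration_ms raster duration (ms); defaults to the latest lick
#'   rounded up to a bin edge.
#' @param bin_ms bin width (default 50 ms).
#' @param alpha significance threshold (default 0.001).
#' @return list: `time_ms` (NA if never significant), `detected`,
#'   `p_values`, `bin_centers_ms`.
#' @export
detection_time <- function(hit_lick_rasters, cr_lick_rasters,
                           duration_ms = NULL, bin_ms = 50, alpha = 0.001) {
  if (length(hit_lick_rasters) < 10 || length(cr_lick_rasters) < 10)
    stop("need at least 10 trials per class")
  d1 <- attr(hit_lick_rasters, "duration_ms")
  d2 <- attr(cr_lick_rasters, "duration_ms")
  if (!is.null(d1) && !is.null(d2) && d1 != d2)
    stop("mismatched raster durations")
  if (is.null(duration_ms)) duration_ms <- if (!is.null(d1)) d1 else d2
  if (is.null(duration_ms)) {
    mx <- max(c(unlist(hit_lick_rasters), unlist(cr_lick_rasters), bin_ms))
    duration_ms <- ceiling(mx / bin_ms) * bin_ms
  }
  edges <- seq(0, duration_ms, by = bin_ms)
  if (length(edges) < 2) stop("duration shorter than one bin")
  count_mat <- function(rasters) {
    t(vapply(rasters, function(tt)
      hist(tt[tt >= 0 & tt <= duration_ms], breaks = edges,
           plot = FALSE)$counts,
      numeric(length(edges) - 1)))
  }
  h <- count_mat(hit_lick_rasters)
  cr <- count_mat(cr_lick_rasters)
  pv <- vapply(seq_len(ncol(h)), function(b) {
    a <- h[, b]; d <- cr[, b]
    if (sd(a) == 0 && sd(d) == 0)
      return(if (mean(a) == mean(d)) 1 else 0)
    t.test(a, d)$p.value
  }, numeric(1))
  centers <- edges[-length(edges)] + bin_ms / 2
  hit_idx <- which(pv < alpha)
  list(time_ms = if (length(hit_idx)) centers[hit_idx[1]] else NA_real_,
       detected = length(hit_idx) > 0,
       p_values = pv, bin_centers_ms = centers)
}
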