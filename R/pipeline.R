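#' Default configuration for an end-to-end study run
#'
#' Returns the configuration list consumed by [run_tone_study()] and
#' [run_vocal_study()], with every stochastic stage given an explicit seed.
#' Sizes are kept modest so a full run completes in seconds; scale
#' `n_neurons` / `n_model_neurons` / `decode_iter` up for production runs.
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    seeds = list(naive = seed + 101, expert = seed + 202,
                 behavior = seed + 303, model = seed + 404,
                 decode = seed + 505, vocal_naive = seed + 606,
                 vocal_expert = seed + 707),
    n_neurons = 60,
    n_trials = 20,
    K = 6,
    n_model_neurons = 200,
    decode_iter = 30,
    training_band_khz = c(7.1, 10),
    behavior_stages = data.frame(
      target_khz = 10, nontarget_khz = c(7.1, 8.333, 9.07),
      n_trials = c(300, 300, 300),
      p_hit = c(0.85, 0.85, 0.8), p_fa = c(0.15, 0.25, 0.4)),
    vocal = list(n_neurons = 41, n_trials = 16, decode_neurons = 37,
                 decode_iter = 100)
  ), class = "run_config")
}

.validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  if (is.null(config$seed) || is.null(config$seeds))
    stop("config must carry explicit seeds for every stochastic stage")
  invisible(config)
}

#' Run the pure-tone study end to end
#'
#' Synthesizes naive and expert ensembles and a behavior log, then chains
#' the analyses: learning curves and per-stage d', neuron summaries,
#' pairwise signal correlations, the SVD basis model per group, Fisher
#' information profiles of sampled model neurons, decoder discriminability
#' at one- and two-grid-step separations, and rank-sum group comparisons
#' (Holm-adjusted). All stage outputs are written under `out_dir` together
#' with a `summary.json`; reruns with the same config are byte-identical.
#'
#' @param config a [default_run_config()]-style list.
#' @param out_dir output directory.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_tone_study <- function(config = default_run_config(), out_dir = tempfile("tone_")) {
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- stimulus_grid()
  band <- config$training_band_khz

  # --- synthesize -------------------------------------------------------
  ens <- list(
    naive = generate_tuning_ensemble(
      ensemble_spec(config$n_neurons, "naive", n_trials = config$n_trials,
                    training_band_khz = band, seed = config$seeds$naive), grid),
    expert = generate_tuning_ensemble(
      ensemble_spec(config$n_neurons, "expert", n_trials = config$n_trials,
                    training_band_khz = band, seed = config$seeds$expert), grid))
  blog <- generate_behavior_log(config$behavior_stages,
                                seed = config$seeds$behavior)
  write_behavior_csv(blog, file.path(out_dir, "trials.csv"))

  # --- behavior ---------------------------------------------------------
  curve <- learning_curve(blog, bin_trials = 20)
  stages <- stage_dprime(blog)
  utils::write.csv(curve, file.path(out_dir, "learning_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(stages, file.path(out_dir, "stage_dprime.csv"),
                   row.names = FALSE)

  # --- single-neuron summaries and signal correlations ------------------
  summaries <- do.call(rbind, lapply(ens, summarize_ensemble,
                                     training_band_khz = c(7, 10)))
  rownames(summaries) <- NULL
  utils::write.csv(summaries, file.path(out_dir, "neuron_summaries.csv"),
                   row.names = FALSE)
  sc <- do.call(rbind, lapply(names(ens), function(g) {
    d <- pairwise_signal_correlations(ens[[g]]); d$group <- g; d
  }))
  utils::write.csv(sc, file.path(out_dir, "signal_correlations.csv"),
                   row.names = FALSE)

  # --- generative model, FI, decoding -----------------------------------
  models <- lapply(ens, function(e)
    fit_ibf(e$rate_curves, K = config$K, freq_log2 = grid$log2_axis,
            group_label = e$spec$group_label))
  samples <- lapply(names(models), function(g)
    sample_neurons(models[[g]], config$n_model_neurons,
                   seed = config$seeds$model))
  names(samples) <- names(models)
  # rate floor at the spontaneous-count scale: sampled curves are floored at
  # zero where the basis mixture goes negative, and a vanishing denominator
  # would otherwise dominate the FI profile
  fi <- lapply(samples, fisher_information, floor_eps = 0.05)
  fi_df <- do.call(rbind, lapply(names(fi), function(g)
    data.frame(group = g, freq_khz = 2 ^ fi[[g]]$x, fi_total = fi[[g]]$total)))
  utils::write.csv(fi_df, file.path(out_dir, "fi_profile.csv"),
                   row.names = FALSE)

  x <- grid$log2_axis
  in_band_idx <- which(2 ^ x >= band[1] & 2 ^ x <= band[2])
  pair_onestep <- x[in_band_idx[1] + c(0, 1)]             # inside the band
  flank_idx <- max(which(2 ^ x < band[1])) - c(2, 0)       # low flank, 2 steps
  pair_twostep <- x[flank_idx]
  decode <- do.call(rbind, lapply(names(samples), function(g) {
    d1 <- decode_pair(model_rates_at(samples[[g]], pair_onestep[1]),
                      model_rates_at(samples[[g]], pair_onestep[2]),
                      max_iter = config$decode_iter, seed = config$seeds$decode)
    d2 <- decode_pair(model_rates_at(samples[[g]], pair_twostep[1]),
                      model_rates_at(samples[[g]], pair_twostep[2]),
                      max_iter = config$decode_iter, seed = config$seeds$decode)
    data.frame(group = g,
               pair = c("in_band_1step", "flank_2step"),
               delta_oct = c(diff(pair_onestep), diff(pair_twostep)),
               accuracy = c(d1$accuracy, d2$accuracy),
               dprime = c(d1$dprime, d2$dprime))
  }))
  utils::write.csv(decode, file.path(out_dir, "decoding.csv"),
                   row.names = FALSE)

  # --- group comparisons ------------------------------------------------
  comp <- group_compare(summaries,
                        c("bf_khz", "spontaneous_hz", "evoked_rate_bf_hz",
                          "rate_training_band_hz", "selectivity_pct"))
  utils::write.csv(comp, file.path(out_dir, "group_comparison.csv"),
                   row.names = FALSE)

  flank_mask <- setdiff(seq_along(x), in_band_idx)
  summary <- list(
    config_seed = config$seed,
    stage_dprime = stages$dprime,
    final_dprime = stages$dprime[nrow(stages)],
    mean_signal_correlation = lapply(split(sc$r, sc$group), mean),
    explained_variance_at_K = lapply(models, function(m)
      m$explained_variance[m$K]),
    fi_in_band = lapply(fi, function(f) mean(f$total[in_band_idx])),
    fi_flank = lapply(fi, function(f) mean(f$total[flank_mask])),
    decode = split(decode$accuracy, paste(decode$group, decode$pair)),
    group_comparison = comp,
    files = list.files(out_dir))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Run the vocalization study end to end
#'
#' Synthesizes naive and expert syllable response sets, computes lifetime
#' and population sparseness, Fano factors, response-similarity matrices,
#' and cumulative-syllable decoding curves, writes the stage outputs under
#' `out_dir` and a `summary.json` with rank-sum group comparisons.
#'
#' @param config a [default_run_config()]-style list.
#' @param out_dir output directory.
#' @return Invisibly, the summary list.
#' @export
run_vocal_study <- function(config = default_run_config(),
                            out_dir = tempfile("vocal_")) {
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vc <- config$vocal
  sets <- list(
    naive = generate_vocal_responses(vc$n_neurons, "naive",
                                     n_trials = vc$n_trials,
                                     seed = config$seeds$vocal_naive),
    expert = generate_vocal_responses(vc$n_neurons, "expert",
                                      n_trials = vc$n_trials,
                                      seed = config$seeds$vocal_expert))
  reports <- lapply(sets, sparseness_report)
  sp <- do.call(rbind, lapply(names(reports), function(g)
    data.frame(group = g, neuron = seq_along(reports[[g]]$lifetime),
               lifetime_sparseness = reports[[g]]$lifetime,
               fano = reports[[g]]$fano)))
  utils::write.csv(sp, file.path(out_dir, "sparseness.csv"), row.names = FALSE)
  pop <- do.call(rbind, lapply(names(reports), function(g)
    data.frame(group = g, syllable = seq_along(reports[[g]]$population),
               population_sparseness = reports[[g]]$population)))
  utils::write.csv(pop, file.path(out_dir, "population_sparseness.csv"),
                   row.names = FALSE)

  sims <- lapply(sets, similarity_matrix)
  sim_df <- do.call(rbind, lapply(names(sims), function(g) {
    m <- sims[[g]]$r
    idx <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(group = g,
               s_a = sims[[g]]$speeding_factors[idx[, 1]],
               s_b = sims[[g]]$speeding_factors[idx[, 2]],
               r = m[idx])
  }))
  utils::write.csv(sim_df, file.path(out_dir, "similarity.csv"),
                   row.names = FALSE)

  orig <- which(sets$naive$speeding_factors == 1)
  hardest <- which.min(sets$naive$speeding_factors)
  curves <- do.call(rbind, lapply(names(sets), function(g) {
    d <- decode_vocal_pair(sets[[g]], orig, hardest,
                           n_neurons = vc$decode_neurons,
                           n_iter = vc$decode_iter,
                           seed = config$seeds$decode)
    data.frame(group = g, d)
  }))
  utils::write.csv(curves, file.path(out_dir, "decoding_curve.csv"),
                   row.names = FALSE)

  comp <- group_compare(sp, c("lifetime_sparseness", "fano"))
  summary <- list(
    config_seed = config$seed,
    mean_lifetime_sparseness = lapply(reports, function(r)
      mean(r$lifetime, na.rm = TRUE)),
    mean_population_sparseness = lapply(reports, function(r)
      mean(r$population)),
    mean_offdiag_similarity = lapply(sims, function(s)
      mean(s$r[upper.tri(s$r)])),
    decoding_final_accuracy = lapply(split(curves, curves$group), function(d)
      d$accuracy[which.max(d$n_syllables)]),
    group_comparison = comp,
    files = list.files(out_dir))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
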