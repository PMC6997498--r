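test_that("stimulus grid is log-spaced with the standard geometry", {
  g <- stimulus_grid()
  expect_length(g$frequencies_khz, 18)
  expect_equal(range(g$frequencies_khz), c(3, 40))
  expect_true(all(diff(g$frequencies_khz) > 0))
  steps <- diff(g$log2_axis)
  expect_equal(max(steps) - min(steps), 0, tolerance = 1e-12)
  expect_length(g$levels_db, 4)
  expect_equal(range(g$levels_db), c(42, 72))
})

test_that("tuning ensemble handles empty and zero-rate edge cases", {
  g <- stimulus_grid()
  e0 <- generate_tuning_ensemble(ensemble_spec(0, "naive"), g)
  expect_equal(nrow(e0$neurons), 0)
  ez <- generate_tuning_ensemble(
    ensemble_spec(3, "naive", peak_rate_hz = 0, spontaneous_rate_hz = 0,
                  n_trials = 5), g)
  expect_true(all(ez$counts == 0))
  expect_error(ensemble_spec(-1, "naive"), "n_neurons")
  expect_error(ensemble_spec(3, "naive", peak_rate_hz = -2), "non-negative")
})

test_that("trial counts are Poisson-calibrated around the true rate", {
  # constant curve at 5 expected counts/window via the spontaneous rate
  g <- stimulus_grid(n_freq = 2, levels_db = c(62, 72))
  e <- generate_tuning_ensemble(
    ensemble_spec(1, "naive", peak_rate_hz = 0, spontaneous_rate_hz = 50,
                  n_trials = 10000, seed = 42), g)
  counts <- e$counts[1, 1, 1, ]
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(5 / 10000))
  vm <- var(counts) / mean(counts)
  expect_lt(abs(vm - 1), 3 * sqrt(2 / 10000))
})

test_that("generators are deterministic under a fixed seed", {
  g <- stimulus_grid()
  sp <- ensemble_spec(5, "expert", n_trials = 4, seed = 9)
  expect_identical(generate_tuning_ensemble(sp, g),
                   generate_tuning_ensemble(sp, g))
  st <- data.frame(target_khz = 10, nontarget_khz = 7.1, n_trials = 50,
                   p_hit = 0.8, p_fa = 0.2)
  expect_identical(generate_behavior_log(st, seed = 3),
                   generate_behavior_log(st, seed = 3))
  expect_identical(generate_vocal_responses(4, "naive", n_trials = 3, seed = 2),
                   generate_vocal_responses(4, "naive", n_trials = 3, seed = 2))
})

test_that("behavior log outcomes are consistent with stimulus and lick", {
  st <- data.frame(target_khz = 10, nontarget_khz = c(7.1, 8.333),
                   n_trials = c(400, 400), p_hit = c(0.9, 0.8),
                   p_fa = c(0.1, 0.3))
  log <- generate_behavior_log(st, catch_rate = 0.06, seed = 5)
  tgt <- log$stimulus_kind == "target"
  ntg <- log$stimulus_kind == "nontarget"
  expect_true(all(log$outcome[tgt & log$licked] == "hit"))
  expect_true(all(log$outcome[tgt & !log$licked] == "miss"))
  expect_true(all(log$outcome[ntg & log$licked] == "fa"))
  expect_true(all(log$outcome[ntg & !log$licked] == "cr"))
  expect_true(all(log$outcome[log$stimulus_kind == "catch"] == "catch"))
  # catch insertion near the configured rate; targets ~70% of the rest
  expect_lt(abs(mean(log$stimulus_kind == "catch") - 0.06), 0.03)
  expect_lt(abs(mean(tgt[!log$stimulus_kind == "catch"]) - 0.7), 0.06)
  expect_error(generate_behavior_log(st[0, ]), "non-empty")
})

test_that("a no-sensitivity log measures d-prime near zero", {
  st <- data.frame(target_khz = 10, nontarget_khz = 9, n_trials = 2000,
                   p_hit = 0.5, p_fa = 0.5)
  log <- generate_behavior_log(st, seed = 11)
  cc <- table(factor(log$outcome, c("hit", "miss", "fa", "cr")))
  dp <- dprime(cc["hit"], cc["miss"], cc["fa"], cc["cr"])
  expect_lt(abs(dp$dprime), 0.15)
})

test_that("vocal generator respects its sparseness and correlation knobs", {
  # dense limit: every pair responsive, near-equal rates -> S near 0
  dense <- generate_vocal_responses(20, "naive", p_responsive = 1,
                                    rate_mean = 50, rate_shape = 5000,
                                    baseline = 0, n_trials = 100, seed = 1)
  rep_d <- sparseness_report(dense)
  expect_true(all(rep_d$lifetime < 5))
  # perfectly correlated variants converge to similarity 1
  same <- generate_vocal_responses(30, "naive",
                                   speeding_factors = c(1, 0.9),
                                   target_correlations = c(1, 1),
                                   n_trials = 400, seed = 2)
  expect_gt(similarity_matrix(same)$r[1, 2], 0.97)
  # calibration round-trip: target 0.6 at s = 0.9 realized within 0.1
  vs <- generate_vocal_responses(200, "naive", speeding_factors = c(1, 0.9),
                                 target_correlations = c(1, 0.6),
                                 n_trials = 200, seed = 5)
  expect_lt(abs(similarity_matrix(vs)$r[1, 2] - 0.6), 0.1)
  expect_error(generate_vocal_responses(10, speeding_factors = c(1, 0.9),
                                        target_correlations = c(1, 1.2)),
               "\\[-1, 1\\]")
  expect_error(generate_vocal_responses(10, speeding_factors = c(1, 1.5)),
               "speeding factors")
})

test_that("syllable warp ramps speed from s to 2 - s and preserves duration", {
  x <- sin(2 * pi * 5 * (0:2047) / 2048)
  expect_identical(warp_syllable(x, 1), x)
  expect_length(warp_syllable(x, 0.7), length(x))
  # warping the identity ramp exposes the time re-mapping itself
  ramp <- seq(0, 1, length.out = 2001)
  w <- warp_syllable(ramp, 0.6)
  slope_start <- (w[2] - w[1]) / (ramp[2] - ramp[1])
  slope_end <- (w[2001] - w[2000]) / (ramp[2] - ramp[1])
  expect_lt(abs(slope_start - 0.6), 0.01)
  expect_lt(abs(slope_end - 1.4), 0.01)
  expect_equal(w[2001], 1, tolerance = 1e-9)   # total duration preserved
  # energy approximately conserved for band-limited tones
  for (s in c(0.66, 0.8, 0.9)) {
    y <- warp_syllable(x, s)
    expect_lt(abs(sum(y ^ 2) / sum(x ^ 2) - 1), 0.05)
  }
  expect_error(warp_syllable(x, 0), "speeding factor")
  expect_error(warp_syllable(x, 1.2), "speeding factor")
})
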