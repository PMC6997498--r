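test_that("response-window search maximizes the response integral", {
  # boxcar burst spanning 20-120 ms
  prof <- rep(0, 400); prof[21:120] <- 2
  w <- find_response_window(psth_from_profile(prof))
  expect_equal(w$onset_ms, 20)
  expect_equal(w$width_ms, 100)
  # uniform PSTH: earliest window wins, tie flagged
  wu <- find_response_window(psth_from_profile(rep(1, 300)))
  expect_equal(wu$onset_ms, 0)
  expect_true(wu$tied)
  # two bursts, second larger
  prof2 <- rep(0, 400); prof2[51:80] <- 1; prof2[201:260] <- 2
  w2 <- find_response_window(psth_from_profile(prof2))
  expect_gte(w2$onset_ms, 160)
  expect_lte(w2$onset_ms, 200)
  expect_equal(sum(prof2[(w2$onset_ms + 1):(w2$onset_ms + 100)]),
               max(vapply(1:300, function(s) sum(prof2[s:(s + 99)]),
                          numeric(1))))
  # all-zero PSTH: earliest window, flagged
  wz <- find_response_window(psth_from_profile(rep(0, 200)))
  expect_equal(wz$onset_ms, 0)
  expect_true(wz$all_zero)
})

test_that("window search agrees with brute-force maximization", {
  set.seed(14)
  for (i in 1:100) {
    prof <- rpois(250, lambda = runif(1, 0.1, 2))
    w <- find_response_window(psth_from_profile(prof))
    expect_equal(sum(prof[(w$onset_ms + 1):(w$onset_ms + 100)]),
                 sum(prof[(brute_force_window(prof) + 1):(brute_force_window(prof) + 100)]))
  }
})

test_that("responsiveness test behaves at the boundaries", {
  x <- c(1, 2, 1, 3, 2)
  expect_false(responsiveness_test(x, x)$is_responsive)
  set.seed(3)
  strong <- responsiveness_test(rpois(12, 10), rpois(12, 0.05))
  expect_true(strong$is_responsive)
  expect_equal(responsiveness_test(rep(2, 5), rep(2, 5))$p_value, 1)
  expect_error(responsiveness_test(1, c(1, 2)), "2 trials")
})

test_that("FRA significance uses the Bonferroni-corrected threshold", {
  g <- stimulus_grid()
  set.seed(21)
  spont <- rpois(48, 0.5)
  # null FRA: every combination at the spontaneous rate
  null_counts <- array(rpois(18 * 4 * 12, 0.5), dim = c(18, 4, 12))
  fra0 <- build_fra(null_counts, spont, g)
  expect_equal(sum(fra0$mask), 0)
  expect_equal(dim(fra0$mask), c(18, 4))
  # one combination at 20x spontaneous
  hot <- null_counts
  hot[7, 3, ] <- rpois(12, 10)
  fra1 <- build_fra(hot, spont, g)
  expect_true(fra1$mask[7, 3])
  expect_equal(sum(fra1$mask), 1)
  # a moderately low p-value must NOT pass the corrected level 0.05/72
  expect_false(any(fra1$p_values > 0.05 / 72 & fra1$mask))
  miss <- hot; miss[3, 2, ] <- NA
  expect_error(build_fra(miss, spont, g), "missing")
})

test_that("neuron summary extracts BF, selectivity and band rate", {
  g <- stimulus_grid()
  set.seed(31)
  spont <- rpois(60, 0.3)
  # single peak at grid frequency 8 across all levels
  counts <- array(rpois(18 * 4 * 15, 0.3), dim = c(18, 4, 15))
  counts[8, , ] <- rpois(4 * 15, 8)
  fra <- build_fra(counts, spont, g)
  s <- summarize_neuron(fra, spont_counts = spont)
  expect_equal(s$bf_khz, g$frequencies_khz[8])
  expect_true(s$is_responsive)
  expect_equal(s$selectivity_pct, 100 * sum(fra$mask) / 72)
  expect_equal(s$evoked_rate_bf_hz, mean(fra$mean_counts[8, ]) / 0.1)
  # BF invariant to a positive rescaling of all rates
  fra2 <- fra; fra2$mean_counts <- fra$mean_counts * 3.7
  expect_equal(summarize_neuron(fra2)$bf_khz, s$bf_khz)
})

test_that("best frequencies are recovered inside the training band at high SNR", {
  g <- stimulus_grid()
  # narrow symmetric tuning: the peak must stand clear of its grid
  # neighbours for the argmax to be identifiable at all
  spec <- ensemble_spec(30, "expert",
                        bf_components = data.frame(center_oct = mean(log2(c(7.1, 10))),
                                                   spread_oct = 0.05, weight = 1),
                        width_oct = c(0.3, 0.03), skew_range = c(1, 1),
                        p_bimodal = 0, peak_rate_hz = 50,
                        spontaneous_rate_hz = 1, n_trials = 50, seed = 77)
  ens <- generate_tuning_ensemble(spec, g)
  s <- summarize_ensemble(ens)
  expect_true(all(s$bf_khz >= 7.1 & s$bf_khz <= 10))
})

test_that("signal correlation is a Pearson r over FRA entries", {
  g <- stimulus_grid()
  set.seed(5)
  counts <- array(rpois(18 * 4 * 10, 2), dim = c(18, 4, 10))
  spont <- rpois(40, 0.5)
  fa <- build_fra(counts, spont, g)
  expect_equal(signal_correlation(fa, fa), 1)
  fb <- fa
  fb$mean_counts <- max(fa$mean_counts) - fa$mean_counts
  expect_equal(signal_correlation(fa, fb), -1)
  fz <- fa; fz$mean_counts[] <- 2
  expect_warning(r <- signal_correlation(fa, fz), "zero-variance")
  expect_true(is.na(r))
  # independent FRAs decorrelate: |r| mostly small over many draws
  rs <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    m1 <- fa; m2 <- fa
    m1$mean_counts <- matrix(rpois(72, 2), 18, 4)
    m2$mean_counts <- matrix(rpois(72, 2), 18, 4)
    suppressWarnings(signal_correlation(m1, m2))
  }, numeric(1))
  expect_gt(mean(abs(rs) < 0.4, na.rm = TRUE), 0.95)
})

test_that("BF concentration raises neighboring signal correlations", {
  g <- stimulus_grid()
  naive <- generate_tuning_ensemble(ensemble_spec(24, "naive", seed = 51), g)
  expert <- generate_tuning_ensemble(ensemble_spec(24, "expert", seed = 52), g)
  r_naive <- mean(pairwise_signal_correlations(naive)$r, na.rm = TRUE)
  r_expert <- mean(pairwise_signal_correlations(expert)$r, na.rm = TRUE)
  expect_gt(r_expert, r_naive)
})
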