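test_that("lifetime sparseness matches the normalized selectivity formula", {
  expect_equal(lifetime_sparseness(c(3, 3, 3, 3)), 0)
  expect_equal(lifetime_sparseness(c(2, 0, 0, 0)), 100)
  expect_equal(lifetime_sparseness(c(3, 1, 0, 0)), 80)
  # scale invariance
  set.seed(2)
  for (i in 1:20) {
    r <- rexp(sample(3:12, 1))
    expect_equal(lifetime_sparseness(r), lifetime_sparseness(pi * r),
                 tolerance = 1e-10)
  }
  expect_warning(s <- lifetime_sparseness(c(0, 0, 0)), "undefined")
  expect_true(is.na(s))
  expect_error(lifetime_sparseness(5), "2 syllables")
  expect_error(lifetime_sparseness(c(-1, 2)), "non-negative")
})

test_that("sparseness extremes are exactly the one-hot and uniform patterns", {
  # brute force over all 0/1 response patterns up to n = 6
  for (n in 2:6) {
    for (code in 1:(2 ^ n - 1)) {
      r <- as.integer(intToBits(code))[1:n]
      s <- lifetime_sparseness(r)
      if (sum(r) == 1) expect_equal(s, 100, tolerance = 1e-9)
      else expect_lt(s, 100 - 1e-6)
      if (sum(r) == n) expect_equal(s, 0, tolerance = 1e-9)
      else expect_gt(s, 1e-6)
    }
  }
})

test_that("population sparseness counts non-responsive cells", {
  sig <- matrix(TRUE, 10, 3)
  expect_equal(population_sparseness(sig), c(0, 0, 0))
  sig[, 2] <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(population_sparseness(sig)[2], 70)
  expect_error(population_sparseness(matrix(logical(0), 0, 3)), "one neuron")
  # generator round trip at high SNR: responsive fraction 0.45 -> ~55%
  vs <- generate_vocal_responses(200, "naive", p_responsive = 0.45,
                                 rate_mean = 5, baseline = 0.05, seed = 31)
  ps <- population_sparseness(syllable_significance(vs))
  expect_lt(abs(mean(ps) - 55), 5)
})

test_that("similarity matrix is symmetric with unit diagonal and exact limits", {
  base <- array(rexp(6 * 1 * 8), dim = c(6, 1, 8))
  same_mr <- array(0, dim = c(6, 2, 8))
  same_mr[, 1, ] <- base[, 1, ]
  same_mr[, 2, ] <- base[, 1, ]
  sm <- similarity_matrix(manual_response_set(same_mr, c(1, 0.9)))
  expect_equal(sm$r[1, 2], 1)
  # anticorrelated variant: reflection around the per-neuron mean
  anti <- array(0, dim = c(6, 2, 8))
  anti[, 1, ] <- base[, 1, ]
  for (i in 1:6) anti[i, 2, ] <- max(base[i, 1, ]) - base[i, 1, ]
  sma <- similarity_matrix(manual_response_set(anti, c(1, 0.9)))
  expect_equal(sma$r[1, 2], -1)
  # structural invariants on a stochastic set
  vs <- generate_vocal_responses(15, "expert", seed = 8)
  s <- similarity_matrix(vs)
  expect_equal(s$r, t(s$r))
  expect_equal(diag(s$r), rep(1, 4))
  expect_true(all(s$r >= -1 & s$r <= 1))
  sp <- similarity_matrix(vs, mode = "psth")
  expect_equal(sp$r, t(sp$r))
  # zero-variance neurons are excluded and counted
  flat <- manual_response_set(array(2, dim = c(3, 2, 5)), c(1, 0.8))
  expect_equal(similarity_matrix(flat)$n_excluded[1, 2], 3L)
})

test_that("Fano factor matches its definition and the Poisson limit", {
  expect_equal(fano_factor(rep(4, 10)), 0)
  cnt <- rep(c(0, 2), 50)
  expect_equal(fano_factor(cnt), var(cnt) / mean(cnt), tolerance = 1e-12)
  set.seed(9)
  big <- rpois(1e5, 5)
  ff <- fano_factor(big)
  expect_gt(ff, 0.98); expect_lt(ff, 1.02)
  expect_warning(f0 <- fano_factor(rep(0, 5)), "undefined")
  expect_true(is.na(f0))
  expect_error(fano_factor(3), "2 trials")
})

test_that("vocal decoding is at chance for identical variants and grows with syllables", {
  # identical generating process for both "variants"
  accs <- vapply(1:3, function(r) {
    vi <- generate_vocal_responses(40, "naive", speeding_factors = c(1, 0.9),
                                   target_correlations = c(1, 1),
                                   seed = 40 + r)
    mean(decode_vocal_pair(vi, 1, 2, n_neurons = 37, n_iter = 40,
                           seed = r)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.08)
  # separable variants: more syllables never hurt on average
  gain <- vapply(1:3, function(r) {
    vs <- generate_vocal_responses(40, "naive", seed = 60 + r)
    d <- decode_vocal_pair(vs, 1, 0.66, n_neurons = 37, n_iter = 40,
                           seed = r)
    d$accuracy[12] - d$accuracy[1]
  }, numeric(1))
  expect_gte(mean(gain), 0)
  vs <- generate_vocal_responses(10, "naive", seed = 3)
  expect_error(decode_vocal_pair(vs, 1, 2, n_neurons = 37), "available")
})
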