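test_that("d-prime matches the inverse-normal identities", {
  expect_equal(dprime(50, 50, 50, 50)$dprime, 0)
  expect_equal(dprime(84134, 15866, 15866, 84134)$dprime, 2, tolerance = 1e-3)
  expect_equal(dprime(69146, 30854, 30854, 69146)$dprime, 1, tolerance = 1e-3)
  # perfect scores are clipped at 1/(2N) before the probit transform
  dp <- dprime(100, 0, 0, 100)
  expect_true(dp$clipped)
  expect_equal(dp$dprime, 2 * qnorm(1 - 1 / 200), tolerance = 1e-9)
  expect_error(dprime(0, 0, 5, 5), "at least one")
  expect_error(dprime(-1, 2, 3, 4), "non-negative")
})

test_that("d-prime is antisymmetric and monotone in its rates", {
  for (h in c(10, 40, 70)) for (f in c(5, 35, 65)) {
    a <- dprime(h, 100 - h, f, 100 - f)$dprime
    b <- dprime(f, 100 - f, h, 100 - h)$dprime
    expect_equal(a, -b, tolerance = 1e-12)
  }
  hs <- seq(10, 90, by = 10)
  d_h <- vapply(hs, function(h) dprime(h, 100 - h, 30, 70)$dprime, numeric(1))
  d_f <- vapply(hs, function(f) dprime(70, 30, f, 100 - f)$dprime, numeric(1))
  expect_true(all(diff(d_h) > 0))
  expect_true(all(diff(d_f) < 0))
})

test_that("learning curve bins recover a constant underlying sensitivity", {
  st <- data.frame(target_khz = 10, nontarget_khz = 7.1, n_trials = 2000,
                   p_hit = 0.9, p_fa = 0.1)
  log <- generate_behavior_log(st, seed = 8)
  lc <- learning_curve(log, bin_trials = 500)
  expect_equal(nrow(lc), 4)
  expect_true(all(abs(lc$dprime - (qnorm(0.9) - qnorm(0.1))) < 0.5))
  # degenerate binning: one bin covering everything
  expect_equal(nrow(learning_curve(log, bin_trials = 10000)), 1)
  expect_error(learning_curve(log[0, ]), "empty")
})

test_that("stage summary uses only the final third of each stage", {
  st_chance <- data.frame(target_khz = 10, nontarget_khz = 9, n_trials = 400,
                          p_hit = 0.5, p_fa = 0.5)
  st_good <- data.frame(target_khz = 10, nontarget_khz = 9, n_trials = 200,
                        p_hit = 0.95, p_fa = 0.05)
  two_phase <- rbind(generate_behavior_log(st_chance, seed = 1),
                     generate_behavior_log(st_good, seed = 2))
  two_phase$stage_id <- 1
  class(two_phase) <- c("behavior_log", "data.frame")
  sd1 <- stage_dprime(two_phase)
  expect_equal(nrow(sd1), 1)
  # last 33% of 600 trials is dominated by the high-performance phase
  expect_gt(sd1$dprime, 2)
})

test_that("psychometric fit recovers a planted decision boundary", {
  freqs <- 2 ^ seq(log2(7), log2(10), length.out = 8)
  sim_fit <- function(seed) {
    set.seed(seed)
    x <- rep(log2(freqs), each = 200)
    p <- 0.05 + 0.9 * plogis(12 * (x - log2(8.4)))
    fit_psychometric(rep(freqs, each = 200), runif(length(x)) < p)
  }
  errs <- vapply(1:50, function(s) {
    f <- sim_fit(s)
    abs(log2(f$boundary_khz) - log2(8.4))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  f1 <- sim_fit(1)
  expect_true(f1$converged)
  expect_equal(f1$boundary_khz, 2 ^ f1$pars[["inflection_oct"]])
})

test_that("flat and step-shaped lick curves are handled sensibly", {
  freqs <- c(7, 7.7, 8.5, 9.3, 10)
  flat <- fit_psychometric(rep(freqs, each = 50),
                           rep(rep(c(TRUE, FALSE), each = 25), 5))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$boundary_khz))
  # monotone step between 8.5 and 9.3 kHz: boundary lands in between
  licked <- rep(freqs, each = 200) > 8.8
  step <- fit_psychometric(rep(freqs, each = 200), licked)
  expect_true(step$converged)
  expect_gt(step$boundary_khz, 8.5)
  expect_lt(step$boundary_khz, 9.3)
})

test_that("detection time finds the lick-divergence point", {
  make_rasters <- function(n, base_rate, extra_rate = 0, onset = 500,
                           dur = 1500, seed = 1) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      base <- runif(rpois(1, base_rate * dur / 1000), 0, dur)
      extra <- runif(rpois(1, extra_rate * (dur - onset) / 1000), onset, dur)
      sort(c(base, extra))
    })
  }
  cr <- make_rasters(100, 0.2, seed = 2)
  hit <- make_rasters(100, 0.2, extra_rate = 5, seed = 3)
  res <- detection_time(hit, cr, duration_ms = 1500)
  expect_true(res$detected)
  expect_lt(abs(res$time_ms - 500), 50 + 25)       # within one bin
  # identical lick processes never diverge
  null <- detection_time(make_rasters(50, 1, seed = 4),
                         make_rasters(50, 1, seed = 5), duration_ms = 1500)
  expect_false(null$detected)
  expect_true(is.na(null$time_ms))
  # alpha = 1 degenerates to the first bin (given any lick variability there)
  res1 <- detection_time(make_rasters(100, 3, seed = 8),
                         make_rasters(100, 3, seed = 9),
                         duration_ms = 1500, alpha = 1)
  expect_equal(res1$time_ms, 25)
  attr(hit, "duration_ms") <- 1500
  attr(cr, "duration_ms") <- 1000
  expect_error(detection_time(hit, cr), "mismatched")
  expect_error(detection_time(hit[1:5], cr[1:5]), "10 trials")
})
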