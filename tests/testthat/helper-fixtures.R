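# shared fixture builders; everything is generated in code at test time

# PSTH object from a deterministic per-bin rate profile (1 ms bins)
psth_from_profile <- function(profile, t_min = 0) {
  structure(list(bin_edges_ms = seq(t_min, t_min + length(profile)),
                 mean_counts = profile, n_trials = 1, bin_ms = 1),
            class = "psth")
}

# brute-force oracle for the response-window search
brute_force_window <- function(profile, width = 100) {
  n <- length(profile)
  sums <- vapply(seq_len(n - width + 1),
                 function(s) sum(profile[s:(s + width - 1)]), numeric(1))
  which.max(sums) - 1  # onset in ms for 1-ms bins starting at 0
}

# minimal syllable_response_set built directly from a mean-rate array
# (N x S x J), with deterministic "counts" equal to scaled means so that
# trial averages are exact
manual_response_set <- function(mean_rates, speeding_factors,
                                n_trials = 4) {
  d <- dim(mean_rates)
  responses <- array(rep(mean_rates, n_trials),
                     dim = c(d, n_trials))
  structure(list(responses = responses, speeding_factors = speeding_factors,
                 syllable_windows_ms = cbind(onset_ms = (seq_len(d[3]) - 1) * 250,
                                             offset_ms = (seq_len(d[3]) - 1) * 250 + 100),
                 spont_counts = matrix(0, d[1], n_trials),
                 mean_rates = mean_rates,
                 responsive_mask = matrix(TRUE, d[1], d[3]),
                 group_label = "naive", params = list()),
            class = "syllable_response_set")
}

# planted rank-6 non-negative tuning-curve matrix: a positive "mean" basis
# vector plus 5 orthogonal shape components with decaying coefficients
planted_rank6 <- function(n_neurons = 100, n_freq = 18, seed = 1) {
  set.seed(seed)
  raw <- cbind(rep(1, n_freq), matrix(rnorm(n_freq * 5), n_freq, 5))
  B <- qr.Q(qr(raw))
  B[, 1] <- abs(B[, 1])
  A <- cbind(rnorm(n_neurons, 20, 2),
             matrix(rnorm(n_neurons * 5), n_neurons, 5) %*%
               diag(c(4, 3, 2.5, 2, 1.5)))
  R <- A %*% t(B)
  # lift along the constant first basis vector so rates stay positive
  # without clipping (keeps the matrix exactly rank 6)
  if (min(R) < 0.05)
    R <- R + (0.05 - min(R)) / B[1, 1] *
      matrix(B[, 1], nrow(R), ncol(R), byrow = TRUE)
  R
}
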