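#' Generate a staged go/no-go behavior log
#'
#' Simulates trial-by-trial performance of one mouse across training stages.
#' Within each stage the target tone is played with probability
#' `target_prob` (default 0.70) and lick responses are drawn as Bernoulli
#' with the stage's hit and false-alarm probabilities. Catch trials
#' (non-reinforced probe tones spanning the training band) can be inserted
#' at a low rate; lick probability on catch trials follows a logistic
#' psychometric curve between the stage's FA and hit probabilities with
#' inflection at the geometric midpoint of target and non-target.
#'
#' @param stages data.frame with columns `target_khz`, `nontarget_khz`,
#'   `n_trials`, `p_hit`, `p_fa` (one row per training stage, in order).
#' @param mouse_id identifier stored with every trial.
#' @param target_prob probability a (non-catch) trial plays the target.
#' @param catch_rate fraction of trials replaced by catch trials (default 0;
#'   the protocol value when enabled is 0.06).
#' @param catch_freqs_khz probe frequencies used on catch trials; default 8
#'   tones spanning 7-10 kHz.
#' @param psycho_slope slope (per octave) of the latent lick psychometric
#'   curve used for catch trials.
#' @param seed integer RNG seed; identical inputs and seed give a
#'   field-for-field identical log.
#' @return A data.frame of class `behavior_log`, ordered by trial, with
#'   columns mouse_id, trial, timestamp_s, stage_id, stimulus_kind
#'   (target/nontarget/catch), stimulus_khz, licked, outcome
#'   (hit/miss/fa/cr/catch) and a list-column `lick_times_ms`.
#' @export
generate_behavior_log <- function(stages, mouse_id = "m01",
                                  target_prob = 0.7,
                                  catch_rate = 0,
                                  catch_freqs_khz = NULL,
                                  psycho_slope = 10,
                                  seed = 1) {
  if (is.null(stages) || nrow(stages) == 0) stop("stages must be non-empty")
  need <- c("target_khz", "nontarget_khz", "n_trials", "p_hit", "p_fa")
  stopifnot(all(need %in% names(stages)))
  if (any(stages$p_hit < 0 | stages$p_hit > 1 | stages$p_fa < 0 | stages$p_fa > 1))
    stop("hit/FA probabilities must lie in [0, 1]")
  if (catch_rate < 0 || catch_rate >= 1) stop("catch_rate must be in [0, 1)")
  set.seed(seed)

  rows <- vector("list", nrow(stages))
  for (s in seq_len(nrow(stages))) {
    st <- stages[s, ]
    n <- st$n_trials
    is_catch <- if (catch_rate > 0) runif(n) < catch_rate else rep(FALSE, n)
    is_target <- !is_catch & runif(n) < target_prob
    kind <- ifelse(is_catch, "catch", ifelse(is_target, "target", "nontarget"))
    freqs <- ifelse(is_target, st$target_khz, st$nontarget_khz)
    if (any(is_catch)) {
      cf <- catch_freqs_khz
      if (is.null(cf)) cf <- 2 ^ seq(log2(7), log2(10), length.out = 8)
      freqs[is_catch] <- sample(cf, sum(is_catch), replace = TRUE)
    }
    mid <- mean(log2(c(st$target_khz, st$nontarget_khz)))
    sgn <- sign(log2(st$target_khz) - mid)  # licks increase toward the target
    p_lick <- ifelse(is_target, st$p_hit,
                     ifelse(!is_catch, st$p_fa,
                            st$p_fa + (st$p_hit - st$p_fa) *
                              plogis(psycho_slope * sgn * (log2(freqs) - mid))))
    licked <- runif(n) < p_lick
    outcome <- ifelse(is_catch, "catch",
                      ifelse(is_target,
                             ifelse(licked, "hit", "miss"),
                             ifelse(licked, "fa", "cr")))
    lick_times <- lapply(seq_len(n), function(j) {
      if (!licked[j]) return(numeric(0))
      sort(round(runif(rpois(1, 2) + 1, 0, 3000), 1))
    })
    rows[[s]] <- data.frame(mouse_id = mouse_id, stage_id = s,
                            stimulus_kind = kind, stimulus_khz = freqs,
                            licked = licked, outcome = outcome,
                            stringsAsFactors = FALSE)
    rows[[s]]$lick_times_ms <- lick_times
  }
  log <- do.call(rbind, rows)
  log$trial <- seq_len(nrow(log))
  log$timestamp_s <- cumsum(rexp(nrow(log), rate = 1 / 30))  # ~2 trials/min
  log <- log[, c("mouse_id", "trial", "timestamp_s", "stage_id",
                 "stimulus_kind", "stimulus_khz", "licked", "outcome",
                 "lick_times_ms")]
  class(log) <- c("behavior_log", "data.frame")
  attr(log, "stages") <- stages
  log
}
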