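#' Pure-tone stimulus grid
#'
#' Builds the frequency x level grid used for tuning-curve mapping: tones
#' logarithmically spaced between `f_min_khz` and `f_max_khz` presented at a
#' small number of sound levels. Frequencies are equally spaced on the log2
#' (octave) axis, the metric used throughout the package.
#'
#' @param n_freq number of tone frequencies (default 18).
#' @param f_min_khz,f_max_khz grid endpoints in kHz (default 3 and 40).
#' @param levels_db sound levels in dB SPL (default 42-72 dB in 10 dB steps).
#' @return An object of class `stimulus_grid` with fields `frequencies_khz`,
#'   `levels_db` and `log2_axis` (x = log2(f / 1 kHz)).
#' @examples
#' g <- stimulus_grid()
#' octave_step(g)  # one grid step in octaves
#' @export
stimulus_grid <- function(n_freq = 18, f_min_khz = 3, f_max_khz = 40,
                          levels_db = c(42, 52, 62, 72)) {
  stopifnot(n_freq >= 2, f_min_khz > 0, f_max_khz > f_min_khz,
            length(levels_db) >= 1)
  lx <- seq(log2(f_min_khz), log2(f_max_khz), length.out = n_freq)
  structure(list(frequencies_khz = 2 ^ lx,
                 levels_db = sort(levels_db),
                 log2_axis = lx),
            class = "stimulus_grid")
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf("stimulus_grid: %d tones %.3g-%.3g kHz (step %.4f octave), %d levels %g-%g dB SPL\n",
              length(x$frequencies_khz), min(x$frequencies_khz),
              max(x$frequencies_khz), octave_step(x),
              length(x$levels_db), min(x$levels_db), max(x$levels_db)))
  invisible(x)
}

#' Octave spacing of a stimulus grid
#'
#' @param grid a `stimulus_grid`.
#' @return Spacing between adjacent grid frequencies on the log2 axis.
#' @export
octave_step <- function(grid) {
  stopifnot(inherits(grid, "stimulus_grid"))
  grid$log2_axis[2L] - grid$log2_axis[1L]
}

#' Octave distance between two frequencies
#'
#' @param f1_khz,f2_khz frequencies in kHz.
#' @return |log2(f2/f1)|, the separation in octaves.
#' @export
octaves_between <- function(f1_khz, f2_khz) {
  stopifnot(f1_khz > 0, f2_khz > 0)
  abs(log2(f2_khz / f1_khz))
}

#' Duration of a tone-train stimulus
#'
#' A trial stimulus is a series of short tones separated by silent gaps;
#' the default (six 100-ms tones, 300-ms gaps) lasts 2.1 s.
#'
#' @param n_tones number of tone pips.
#' @param tone_ms pip duration (ms).
#' @param gap_ms silent interval between consecutive pips (ms).
#' @return Total stimulus duration in seconds.
#' @export
tone_train_duration_s <- function(n_tones = 6, tone_ms = 100, gap_ms = 300) {
  stopifnot(n_tones >= 1, tone_ms >= 0, gap_ms >= 0)
  (n_tones * tone_ms + (n_tones - 1) * gap_ms) / 1000
}
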