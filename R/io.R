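#' Write a tuning ensemble to CSV
#'
#' Writes `spikes.csv` (cell_id, group, cell_class, site, stim_id, trial,
#' count) and `stimuli.csv` (stim_id, freq_khz, level_db) in RFC-4180 CSV,
#' plus `spec.json` with the generator parameters.
#'
#' @param ensemble a `tuning_ensemble`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ensemble_csv <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "tuning_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- ensemble$grid
  stim <- expand.grid(f = seq_along(g$frequencies_khz),
                      l = seq_along(g$levels_db))
  stim <- data.frame(stim_id = seq_len(nrow(stim)),
                     freq_khz = g$frequencies_khz[stim$f],
                     level_db = g$levels_db[stim$l],
                     f_idx = stim$f, l_idx = stim$l)
  utils::write.csv(stim[, c("stim_id", "freq_khz", "level_db")],
                   file.path(dir, "stimuli.csv"), row.names = FALSE)
  N <- nrow(ensemble$neurons); Tn <- dim(ensemble$counts)[4]
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    cnt <- ensemble$counts[i, , , , drop = TRUE]   # F x L x T
    df <- expand.grid(f_idx = seq_along(g$frequencies_khz),
                      l_idx = seq_along(g$levels_db), trial = seq_len(Tn))
    rows[[i]] <- data.frame(cell_id = ensemble$neurons$neuron_id[i],
                            group = ensemble$neurons$group[i],
                            cell_class = ensemble$neurons$cell_class[i],
                            site = ensemble$neurons$site[i],
                            stim_id = stim$stim_id[
                              match(paste(df$f_idx, df$l_idx),
                                    paste(stim$f_idx, stim$l_idx))],
                            trial = df$trial,
                            count = as.vector(cnt))
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  spec <- ensemble$spec
  spec$bf_components <- as.list(spec$bf_components)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, c("spikes.csv", "stimuli.csv", "spec.json")))
}

#' Read a tuning ensemble written by [write_ensemble_csv()]
#'
#' @param dir directory holding `spikes.csv` and `stimuli.csv`.
#' @param window_ms response-window length metadata (default 100 ms).
#' @return A list with `grid`, `neurons`, `counts` (N x F x L x T) and
#'   `rate_curves`, mirroring a `tuning_ensemble` (no spontaneous counts).
#' @export
read_ensemble_csv <- function(dir, window_ms = 100) {
  stim <- utils::read.csv(file.path(dir, "stimuli.csv"))
  spk <- utils::read.csv(file.path(dir, "spikes.csv"))
  freqs <- sort(unique(stim$freq_khz)); levels <- sort(unique(stim$level_db))
  grid <- structure(list(frequencies_khz = freqs, levels_db = levels,
                         log2_axis = log2(freqs)), class = "stimulus_grid")
  cells <- unique(spk[, c("cell_id", "group", "cell_class", "site")])
  N <- nrow(cells); Tn <- max(spk$trial)
  counts <- array(NA_integer_, dim = c(N, length(freqs), length(levels), Tn))
  fidx <- match(stim$freq_khz[match(spk$stim_id, stim$stim_id)], freqs)
  lidx <- match(stim$level_db[match(spk$stim_id, stim$stim_id)], levels)
  nidx <- match(spk$cell_id, cells$cell_id)
  counts[cbind(nidx, fidx, lidx, spk$trial)] <- spk$count
  rate <- apply(counts, c(1, 2), mean)
  names(cells)[1] <- "neuron_id"
  list(grid = grid, neurons = cells, counts = counts, rate_curves = rate,
       window_ms = window_ms)
}

#' Write a behavior log to CSV
#'
#' Lick times are semicolon-joined into a single column.
#'
#' @param log a `behavior_log`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_behavior_csv <- function(log, path) {
  df <- as.data.frame(log)
  df$lick_times_ms <- vapply(df$lick_times_ms, paste, character(1),
                             collapse = ";")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a behavior log written by [write_behavior_csv()]
#'
#' @param path CSV file.
#' @return A `behavior_log` data.frame with the lick-time list-column
#'   restored.
#' @export
read_behavior_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$lick_times_ms <- lapply(strsplit(as.character(df$lick_times_ms), ";"),
                             function(s) as.numeric(s[nzchar(s)]))
  class(df) <- c("behavior_log", "data.frame")
  df
}

#' Rank-sum group comparison with Holm-Bonferroni correction
#'
#' Wilcoxon rank-sum tests per variable between two groups, with the
#' Holm-Bonferroni adjustment across the variables compared.
#'
#' @param df data.frame containing `group_col` and the variables.
#' @param vars variable names to compare.
#' @param group_col grouping column (must have exactly 2 levels).
#' @return data.frame: variable, median per group, p_value,
#'   p_adjusted (Holm).
#' @export
group_compare <- function(df, vars, group_col = "group") {
  gr <- unique(df[[group_col]])
  if (length(gr) != 2) stop("need exactly two groups")
  res <- do.call(rbind, lapply(vars, function(v) {
    a <- df[[v]][df[[group_col]] == gr[1]]
    b <- df[[v]][df[[group_col]] == gr[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    p <- if (length(a) && length(b))
      suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
    data.frame(variable = v,
               median_a = median(a), median_b = median(b),
               group_a = gr[1], group_b = gr[2], p_value = p)
  }))
  res$p_adjusted <- p.adjust(res$p_value, method = "holm")
  res
}
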