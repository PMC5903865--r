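#' Response ratio
#'
#' Proportion of presented cues of one type that received a receptacle entry
#' during the cue. The training criterion for the task is a CS+ response
#' ratio above 0.40 (together with a discrimination index of at least 0.67).
#'
#' @param trials A `trial_table`.
#' @param cue_type `"cs_plus"` or `"cs_minus"`.
#' @param window Optional `c(start, end)` restriction on cue onsets, seconds.
#' @param epoch Optional epoch filter.
#' @return Ratio in `[0, 1]`.
#' @export
response_ratio <- function(trials, cue_type = "cs_plus", window = NULL,
                           epoch = NULL) {
  keep <- trials$cue_type == cue_type
  if (!is.null(window))
    keep <- keep & trials$cue_onset >= window[1] & trials$cue_onset < window[2]
  if (!is.null(epoch)) keep <- keep & trials$epoch %in% epoch
  if (!any(keep)) stop("no ", cue_type, " presentations in window")
  mean(trials$responded[keep])
}

#' Discrimination index
#'
#' CS+ responses divided by total cue responses; at or above 0.67 the animal
#' is considered to discriminate reliably between the cues.
#'
#' @inheritParams response_ratio
#' @return DI in `[0, 1]`.
#' @export
discrimination_index <- function(trials, window = NULL) {
  keep <- trials$responded
  if (!is.null(window))
    keep <- keep & trials$cue_onset >= window[1] & trials$cue_onset < window[2]
  n_plus <- sum(keep & trials$cue_type == "cs_plus")
  n_total <- sum(keep)
  if (n_total == 0) stop("no cue responses in window")
  n_plus / n_total
}

#' Time-binned performance summary
#'
#' Response ratios per cue type in consecutive bins aligned to session start
#' (default 20 min). Bins without presentations of a type carry `NA`; a
#' final partial bin is flagged.
#'
#' @param trials A `trial_table`.
#' @param session_length Session length, seconds.
#' @param bin_min Bin size, minutes.
#' @return Data frame with `bin_start`, `bin_end`, `partial`, and per cue
#'   type `presented`, `responded`, `ratio`.
#' @export
time_binned_performance <- function(trials, session_length,
                                    bin_min = 20) {
  bw <- bin_min * 60
  starts <- bw * (seq_len(ceiling(session_length / bw)) - 1)
  do.call(rbind, lapply(starts, function(s) {
    e <- min(s + bw, session_length)
    row <- data.frame(bin_start = s, bin_end = e, partial = (e - s) < bw)
    for (ct in c("cs_plus", "cs_minus")) {
      keep <- trials$cue_type == ct & trials$cue_onset >= s & trials$cue_onset < e
      pres <- sum(keep)
      resp <- sum(keep & trials$responded)
      row[[paste0(ct, "_presented")]] <- pres
      row[[paste0(ct, "_responded")]] <- resp
      row[[paste0(ct, "_ratio")]] <- if (pres > 0) resp / pres else NA_real_
    }
    row
  }))
}

#' Holm-Sidak step-down p-value adjustment
#'
#' @param p Raw p-values.
#' @return Adjusted p-values, monotone in and never below the raw values.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pre- versus post-injection comparison across sessions
#'
#' Paired Wilcoxon signed-rank tests of per-session pre- against
#' post-injection values (e.g. CS+ response ratios), one test per group,
#' with Holm-Sidak adjustment across groups.
#'
#' @param pre,post Named lists (one element per group) of per-session paired
#'   numeric vectors.
#' @return Data frame with `group`, `n_sessions`, `median_pre`,
#'   `median_post`, `p_raw`, `p_adjusted`, `significant`, `low_power`
#'   (fewer than 5 pairs).
#' @export
pre_post_compare <- function(pre, post) {
  stopifnot(identical(names(pre), names(post)))
  rows <- lapply(names(pre), function(g) {
    x <- pre[[g]]; y <- post[[g]]
    stopifnot(length(x) == length(y), length(x) > 0)
    p <- if (all(x == y)) 1 else
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    data.frame(group = g, n_sessions = length(x),
               median_pre = stats::median(x), median_post = stats::median(y),
               p_raw = p, low_power = length(x) < 5)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_sidak(out$p_raw)
  out$significant <- out$p_adjusted < 0.05
  out[, c("group", "n_sessions", "median_pre", "median_post", "p_raw",
          "p_adjusted", "significant", "low_power")]
}

#' Receptacle entries per minute of intertrial time
#'
#' A locomotor-activity proxy for the ITI: the number of receptacle entries
#' falling outside all cue presentations, divided by the total non-cue time
#' in minutes.
#'
#' @param events An `event_log`.
#' @param trials A `trial_table` built from it.
#' @param session_length Session length, seconds.
#' @return Entries per minute.
#' @export
iti_entry_rate <- function(events, trials, session_length) {
  entries <- events$time[events$kind == "receptacle_entry"]
  in_cue <- vapply(entries, function(e)
    any(e >= trials$cue_onset & e <= trials$cue_off), logical(1))
  cue_time <- sum(trials$cue_off - trials$cue_onset)
  sum(!in_cue) / ((session_length - cue_time) / 60)
}
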