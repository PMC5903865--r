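#' Spike train with unit metadata
#'
#' @param unit_id Unit identifier.
#' @param times Spike timestamps, seconds, strictly increasing.
#' @param amplitude_uV Absolute waveform amplitude in microvolts.
#' @param hemisphere `"left"` or `"right"`.
#' @param drug_exposure `"ipsi"`, `"contra"` or `"none"` relative to a
#'   unilateral infusion (`"ipsi"` for both hemispheres under bilateral).
#' @param state Satiety state of the session, `"free_fed"` or `"restricted"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, times, amplitude_uV = 150,
                        hemisphere = "left", drug_exposure = "none",
                        state = "free_fed") {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike timestamps must be strictly increasing")
  if (amplitude_uV <= 0) stop("amplitude must be > 0")
  structure(list(unit_id = as.character(unit_id), times = times,
                 amplitude_uV = amplitude_uV, hemisphere = hemisphere,
                 drug_exposure = drug_exposure, state = state),
            class = "spike_train")
}

#' Build the per-trial table from an event log
#'
#' One row per cue onset, with the response flag (any receptacle entry during
#' the cue), response latency, rewarded entry time (first in-cue entry on CS+
#' trials, which terminates the cue and triggers reward), the 10-s pre-cue
#' baseline window, and the injection-epoch label. With infusion markers
#' present, trials are labelled `pre` on `[0, infusion_start)` and `post` on
#' `[infusion_end, infusion_end + infusion_start)` — equal-length epochs that
#' exclude the infusion interval itself.
#'
#' Trials whose baseline window overlaps the preceding trial's reward
#' consumption epoch (entry to exit) are flagged in `baseline_overlap`, not
#' dropped.
#'
#' @param events An `event_log` data frame (`time`, `kind`, ...). Record
#'   order is irrelevant; times are canonicalized by sorting.
#' @param cue_duration Nominal cue duration, seconds.
#' @param baseline_length Pre-cue baseline length, seconds (default 10).
#' @return A `trial_table` data frame with columns `trial`, `cue_type`
#'   (`"cs_plus"`/`"cs_minus"`), `cue_onset`, `cue_off`, `responded`,
#'   `response_latency`, `rewarded_entry_time`, `baseline_start`,
#'   `baseline_end`, `baseline_overlap`, `epoch`.
#' @export
build_trial_table <- function(events, cue_duration = 5, baseline_length = 10) {
  events <- events[order(events$time), , drop = FALSE]
  onsets <- events[events$kind %in% c("cs_plus_on", "cs_minus_on"), , drop = FALSE]
  offs <- events$time[events$kind == "cue_off"]
  entries <- events$time[events$kind == "receptacle_entry"]
  exits <- events$time[events$kind == "receptacle_exit"]
  inf_start <- events$time[events$kind == "infusion_start"]
  inf_end <- events$time[events$kind == "infusion_end"]

  n <- nrow(onsets)
  if (n == 0) {
    empty <- data.frame(trial = integer(0), cue_type = character(0),
                        cue_onset = numeric(0), cue_off = numeric(0),
                        responded = logical(0), response_latency = numeric(0),
                        rewarded_entry_time = numeric(0),
                        baseline_start = numeric(0), baseline_end = numeric(0),
                        baseline_overlap = logical(0), epoch = character(0))
    return(structure(empty, class = c("trial_table", "data.frame")))
  }

  cue_off <- vapply(onsets$time, function(t0) {
    cand <- offs[offs > t0 & offs <= t0 + cue_duration + 1e-9]
    if (length(cand) == 0) t0 + cue_duration else cand[1]
  }, numeric(1))
  if (any(onsets$time[-1] < cue_off[-n] - 1e-9))
    stop("overlapping cues in event log")

  cue_type <- ifelse(onsets$kind == "cs_plus_on", "cs_plus", "cs_minus")
  first_entry <- vapply(seq_len(n), function(i) {
    e <- entries[entries >= onsets$time[i] & entries <= cue_off[i] + 1e-9]
    if (length(e)) e[1] else NA_real_
  }, numeric(1))
  responded <- !is.na(first_entry)
  latency <- first_entry - onsets$time
  rewarded_entry <- ifelse(responded & cue_type == "cs_plus", first_entry, NA_real_)

  # consumption epoch of each responded CS+ trial: entry to next exit
  cons_end <- vapply(rewarded_entry, function(en) {
    if (is.na(en)) return(NA_real_)
    ex <- exits[exits > en]
    if (length(ex)) ex[1] else en + 3
  }, numeric(1))
  baseline_start <- onsets$time - baseline_length
  overlap <- vapply(seq_len(n), function(i) {
    if (i == 1) return(FALSE)
    prev <- which(!is.na(rewarded_entry[seq_len(i - 1)]))
    if (!length(prev)) return(FALSE)
    j <- max(prev)
    cons_end[j] > baseline_start[i] && rewarded_entry[j] < onsets$time[i]
  }, logical(1))

  epoch <- rep("none", n)
  if (length(inf_start) == 1 && length(inf_end) == 1) {
    pre_len <- inf_start
    epoch[onsets$time < inf_start] <- "pre"
    epoch[onsets$time >= inf_end & onsets$time < inf_end + pre_len] <- "post"
  }

  out <- data.frame(trial = seq_len(n), cue_type = cue_type,
                    cue_onset = onsets$time, cue_off = cue_off,
                    responded = responded, response_latency = latency,
                    rewarded_entry_time = rewarded_entry,
                    baseline_start = baseline_start,
                    baseline_end = onsets$time,
                    baseline_overlap = overlap, epoch = epoch,
                    stringsAsFactors = FALSE)
  structure(out, class = c("trial_table", "data.frame"))
}

#' Responded CS+ cue onsets (the default trial set for cue analyses)
#'
#' @param trials A `trial_table`.
#' @param epoch Optional epoch filter (`"pre"`, `"post"`, `"none"`).
#' @return Numeric vector of cue-onset times.
#' @export
responded_csplus_onsets <- function(trials, epoch = NULL) {
  keep <- trials$cue_type == "cs_plus" & trials$responded
  if (!is.null(epoch)) keep <- keep & trials$epoch %in% epoch
  trials$cue_onset[keep]
}

#' Rewarded receptacle-entry times (consumption alignment events)
#'
#' @inheritParams responded_csplus_onsets
#' @return Numeric vector of rewarded entry times.
#' @export
rewarded_entry_times <- function(trials, epoch = NULL) {
  keep <- !is.na(trials$rewarded_entry_time)
  if (!is.null(epoch)) keep <- keep & trials$epoch %in% epoch
  trials$rewarded_entry_time[keep]
}

#' Unit quality control
#'
#' A unit passes when its absolute amplitude is at least 75 uV and at most
#' 0.1% of its inter-spike intervals are 2 ms or shorter (refractory-period
#' violation rate). Units with fewer than 2 spikes have no evaluable ISI
#' distribution and are reported as `"indeterminate"`.
#'
#' @param unit A [spike_train()].
#' @param min_amplitude Amplitude criterion, microvolts.
#' @param max_isi_violation Maximum tolerated fraction of ISIs at or below
#'   `refractory`.
#' @param refractory Refractory period, seconds.
#' @return A list with `pass` (`TRUE`/`FALSE`/`NA` for indeterminate) and
#'   `reason` (`"ok"`, `"amplitude"`, `"refractory"`, `"indeterminate"`).
#' @export
qc_unit <- function(unit, min_amplitude = 75, max_isi_violation = 0.001,
                    refractory = 0.002) {
  if (unit$amplitude_uV < min_amplitude)
    return(list(pass = FALSE, reason = "amplitude"))
  if (length(unit$times) < 2)
    return(list(pass = NA, reason = "indeterminate"))
  isi <- diff(unit$times)
  frac <- mean(isi <= refractory)
  if (frac > max_isi_violation)
    return(list(pass = FALSE, reason = "refractory"))
  list(pass = TRUE, reason = "ok")
}

#' Bin spike counts around alignment events
#'
#' Counts spikes in half-open bins `[a, b)` tiling `window` (relative to each
#' alignment event). The window length must be an integer multiple of
#' `bin_width`.
#'
#' @param times Spike timestamps (numeric vector) or a [spike_train()].
#' @param align_times Event times to align to (e.g. responded CS+ onsets).
#' @param window Length-2 window relative to the events, seconds.
#' @param bin_width Bin width, seconds.
#' @return A `binned_counts` object: integer matrix `counts`
#'   (trials x bins), plus `window`, `bin_width`, `bin_starts`,
#'   `align_times`.
#' @export
bin_counts <- function(times, align_times, window, bin_width) {
  if (inherits(times, "spike_train")) times <- times$times
  n_bins <- diff(window) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8)
    stop("window length must be an integer multiple of bin_width")
  n_bins <- as.integer(round(n_bins))
  breaks <- window[1] + bin_width * (0:n_bins)
  counts <- t(vapply(align_times, function(a) {
    rel <- times - a
    rel <- rel[rel >= window[1] & rel < window[2]]
    # small epsilon keeps aligned-time arithmetic on the half-open convention
    idx <- pmin(floor((rel - window[1]) / bin_width + 1e-9) + 1L, n_bins)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins)))
  if (n_bins == 1) counts <- matrix(counts, ncol = 1)
  structure(list(counts = counts, window = window, bin_width = bin_width,
                 bin_starts = breaks[-length(breaks)],
                 align_times = align_times),
            class = "binned_counts")
}

#' Baseline rate estimate over trials
#'
#' Total spike count over all trials' baseline windows divided by the total
#' baseline duration.
#'
#' @param times Spike timestamps or a [spike_train()].
#' @param align_times Cue-onset times of the included trials.
#' @param baseline_length Baseline length, seconds, immediately pre-event.
#' @return Rate in Hz.
#' @export
baseline_rate <- function(times, align_times, baseline_length = 10) {
  if (inherits(times, "spike_train")) times <- times$times
  total <- sum(vapply(align_times, function(a)
    sum(times >= a - baseline_length & times < a), numeric(1)))
  total / (baseline_length * length(align_times))
}
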