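#' Area under the ROC curve for one bin versus baseline
#'
#' Distribution-free discrimination between the per-trial counts of one
#' peri-event bin and a baseline count sample, via the Mann-Whitney identity:
#' auROC = (#pairs with bin > baseline + 0.5 * #ties) / #pairs. 0.5 means no
#' change from baseline, 1 strong excitation, 0 strong inhibition. Invariant
#' to any strictly monotone transform, and antisymmetric under swapping the
#' two sides.
#'
#' @param bin_counts Numeric vector of per-trial counts in the bin.
#' @param baseline_counts Numeric vector of baseline counts.
#' @return auROC in `[0, 1]`.
#' @export
auroc_bin <- function(bin_counts, baseline_counts) {
  n1 <- length(bin_counts); n2 <- length(baseline_counts)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(bin_counts, baseline_counts))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

# fast per-bin auROC of an integer count matrix (trials x bins) against a
# pooled integer baseline sample, via the baseline count distribution
auroc_track <- function(counts, baseline_counts) {
  m <- max(counts, baseline_counts, 0L)
  freq <- tabulate(baseline_counts + 1L, nbins = m + 1L) / length(baseline_counts)
  p_less <- c(0, cumsum(freq))[seq_len(m + 1L)]
  colMeans(matrix(p_less[counts + 1L] + 0.5 * freq[counts + 1L],
                  nrow = nrow(counts)))
}

smooth_track <- function(x, half_width) {
  # centered moving average, truncated at the edges (no padding)
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half_width):min(n, i + half_width)]), numeric(1))
}

auroc_map_engine <- function(unit, align_times, baseline_align, window,
                             bin_width, baseline_window, smooth_window,
                             unit_id) {
  if (length(align_times) < 2) stop("need at least 2 trials")
  binned <- bin_counts(unit, align_times, window, bin_width)
  base <- bin_counts(unit, baseline_align, baseline_window, bin_width)
  raw <- auroc_track(binned$counts, as.vector(base$counts))
  half <- max(1L, as.integer(round(smooth_window / bin_width / 2)))
  structure(list(unit_id = unit_id,
                 bin_centers = binned$bin_starts + bin_width / 2,
                 raw = raw, smoothed = smooth_track(raw, half),
                 bin_width = bin_width, smoothing_window = smooth_window,
                 baseline_window = baseline_window, n_trials = length(align_times)),
            class = "auroc_map")
}

#' Binwise auROC encoding map around the cue
#'
#' auROC in 10-ms bins from 1 s before to 1.5 s after CS+ onset, each bin's
#' per-trial counts compared against the per-trial counts of 10-ms bins
#' tiling the 1-s pre-cue baseline (pooled across trials). The smoothed
#' track (200-ms centered sliding mean) is for display only; all statistics
#' downstream use the raw track.
#'
#' @param unit A [spike_train()] or numeric spike times.
#' @param trials A `trial_table`; responded CS+ trials are used.
#' @param epoch Optional epoch filter.
#' @param window,bin_width,baseline_window,smooth_window Map geometry,
#'   seconds.
#' @return An `auroc_map`: `bin_centers`, `raw`, `smoothed`, geometry fields.
#' @export
cue_auroc_map <- function(unit, trials, epoch = NULL,
                          window = c(-1, 1.5), bin_width = 0.01,
                          baseline_window = c(-1, 0), smooth_window = 0.2) {
  onsets <- responded_csplus_onsets(trials, epoch)
  auroc_map_engine(unit, onsets, onsets, window, bin_width, baseline_window,
                   smooth_window,
                   if (inherits(unit, "spike_train")) unit$unit_id else NA)
}

#' Binwise auROC map around the rewarded receptacle entry
#'
#' 200-ms bins from 1 s before to 5 s after the rewarded entry, against the
#' pre-cue baseline of the same trials (tiled at the map's bin width), with
#' an 800-ms display smoothing window.
#'
#' @inheritParams cue_auroc_map
#' @return An `auroc_map`.
#' @export
consumption_auroc_map <- function(unit, trials, epoch = NULL,
                                  window = c(-1, 5), bin_width = 0.2,
                                  baseline_window = c(-1, 0),
                                  smooth_window = 0.8) {
  keep <- !is.na(trials$rewarded_entry_time)
  if (!is.null(epoch)) keep <- keep & trials$epoch %in% epoch
  auroc_map_engine(unit, trials$rewarded_entry_time[keep],
                   trials$cue_onset[keep], window, bin_width, baseline_window,
                   smooth_window,
                   if (inherits(unit, "spike_train")) unit$unit_id else NA)
}

#' Population z-scored peri-event time histogram
#'
#' Each unit's per-bin trial-mean count is z-scored against bin-width-matched
#' counts from the 10-s pre-cue baseline (mean and SD over all trials'
#' baseline bins); the population PSTH is the across-unit mean and SEM per
#' bin. Units with zero baseline variance have undefined z and are excluded,
#' with their count reported.
#'
#' @param units List of [spike_train()]s (or numeric time vectors).
#' @param trials A `trial_table`; responded CS+ trials are used.
#' @param window,bin_width PSTH geometry, seconds.
#' @param baseline_length Baseline length, seconds.
#' @param epoch Optional epoch filter.
#' @return A `psth`: `bin_centers`, `mean_z`, `sem_z`, `n_units`,
#'   `n_excluded`.
#' @export
psth_z <- function(units, trials, window = c(0, 0.5), bin_width = 0.05,
                   baseline_length = 10, epoch = NULL) {
  onsets <- responded_csplus_onsets(trials, epoch)
  zmat <- lapply(units, function(u)
    unit_z_track(u, onsets, window, bin_width, baseline_length))
  ok <- !vapply(zmat, is.null, logical(1))
  if (!any(ok)) stop("no unit with positive baseline variance")
  z <- do.call(rbind, zmat[ok])
  centers <- window[1] + bin_width * (seq_len(ncol(z)) - 0.5)
  structure(list(bin_centers = centers, mean_z = colMeans(z),
                 sem_z = apply(z, 2, stats::sd) / sqrt(nrow(z)),
                 n_units = nrow(z), n_excluded = sum(!ok)),
            class = "psth")
}

unit_z_track <- function(unit, onsets, window, bin_width, baseline_length) {
  binned <- bin_counts(unit, onsets, window, bin_width)
  base <- bin_counts(unit, onsets, c(-baseline_length, 0), bin_width)
  m <- mean(base$counts); s <- stats::sd(as.vector(base$counts))
  if (is.na(s) || s == 0) return(NULL)
  (colMeans(binned$counts) - m) / s
}

#' Cue-response magnitude in the 100--300 ms window
#'
#' Summary of a unit's early cue response: the per-trial spike count in
#' `[0.1, 0.3)` s post-cue, expressed either as a z-score against
#' window-width-matched baseline counts (default) or as the raw mean count.
#'
#' @param unit A [spike_train()] or numeric spike times.
#' @param trials A `trial_table`; responded CS+ trials are used.
#' @param type `"z"` or `"count"`.
#' @param window Magnitude window, seconds.
#' @param baseline_length Baseline length, seconds.
#' @param epoch Optional epoch filter.
#' @return A single number (`NA` for `type = "z"` when the baseline variance
#'   is zero).
#' @export
magnitude_100_300 <- function(unit, trials, type = c("z", "count"),
                              window = c(0.1, 0.3), baseline_length = 10,
                              epoch = NULL) {
  type <- match.arg(type)
  onsets <- responded_csplus_onsets(trials, epoch)
  width <- diff(window)
  counts <- bin_counts(unit, onsets, window, width)$counts
  if (type == "count") return(mean(counts))
  base <- bin_counts(unit, onsets, c(-baseline_length, 0), width)$counts
  s <- stats::sd(as.vector(base))
  if (is.na(s) || s == 0) return(NA_real_)
  (mean(counts) - mean(base)) / s
}
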