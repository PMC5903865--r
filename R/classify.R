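#' One-sided Poisson count bounds
#'
#' For an expected count `lambda`, returns the smallest integer whose Poisson
#' CDF reaches `upper_level` (excitation threshold) and the largest integer
#' whose CDF is at most `lower_level` (inhibition threshold). When even a
#' count of zero is not improbable enough (`P(X = 0) > lower_level`),
#' inhibition is undetectable — a floor effect common in low-rate accumbens
#' units — and the lower bound is `NA`.
#'
#' @param lambda Expected count (>= 0).
#' @param upper_level Upper CDF level (e.g. 0.999).
#' @param lower_level Lower CDF level (e.g. 0.01).
#' @return List with integer `upper_count` and `lower_count` (`NA` if
#'   undetectable).
#' @export
poisson_bounds <- function(lambda, upper_level = 0.999, lower_level = 0.01) {
  if (lambda < 0) stop("lambda must be >= 0")
  stopifnot(upper_level > 0.5, upper_level < 1,
            lower_level > 0, lower_level < 0.5)
  upper <- stats::qpois(upper_level, lambda)
  # largest x with CDF(x) <= lower_level
  q <- stats::qpois(lower_level, lambda)  # smallest x with CDF(x) >= level
  lower <- if (stats::ppois(q, lambda) <= lower_level) q else q - 1L
  if (lower < 0) lower <- NA_integer_
  list(upper_count = as.integer(upper), lower_count = lower)
}

#' Classify a unit's peri-event response by Poisson confidence bounds
#'
#' Implements the any-one-bin rule: per-trial counts are summed over trials
#' within each bin and compared with one-sided Poisson bounds computed from
#' the expected count `baseline_rate * bin_width * n_trials`. A unit is
#' *excited* if at least one bin strictly exceeds the `upper_level` bound and
#' *inhibited* if at least one bin falls strictly below the `lower_level`
#' bound (a laxer level than for excitation, because low baseline rates
#' create floor effects). Multiple-comparison correction across bins is
#' deliberately not applied — the rule is any-one-bin by definition.
#'
#' @param binned A `binned_counts` object from [bin_counts()] (cue analyses:
#'   50-ms bins on `[0, 0.5)` s over responded CS+ trials).
#' @param baseline_rate_hz Baseline rate estimate, Hz (see
#'   [baseline_rate()], 10-s pre-cue baseline).
#' @param upper_level CDF level for excitation (default 0.999).
#' @param lower_level CDF level for inhibition (default 0.01).
#' @param unit_id Identifier carried into the result.
#' @return A `classification_result`: `label` (`"excited"`, `"inhibited"`,
#'   `"both"`, `"none"`), logical `excited_bins` / `inhibited_bins` masks,
#'   `lambda` (expected summed count per bin), `upper_count`, `lower_count`,
#'   `inhibition_undetectable` flag, `n_trials`.
#' @export
classify_response <- function(binned, baseline_rate_hz,
                              upper_level = 0.999, lower_level = 0.01,
                              unit_id = NA_character_) {
  n_trials <- nrow(binned$counts)
  if (n_trials == 0) stop("no trials to classify")
  lambda <- baseline_rate_hz * binned$bin_width * n_trials
  b <- poisson_bounds(lambda, upper_level, lower_level)
  bin_sums <- colSums(binned$counts)
  excited_bins <- bin_sums > b$upper_count
  inhibited_bins <- if (is.na(b$lower_count)) rep(FALSE, length(bin_sums))
    else bin_sums < b$lower_count
  label <- if (any(excited_bins) && any(inhibited_bins)) "both"
    else if (any(excited_bins)) "excited"
    else if (any(inhibited_bins)) "inhibited" else "none"
  structure(list(unit_id = unit_id, label = label,
                 excited_bins = excited_bins, inhibited_bins = inhibited_bins,
                 lambda = lambda, upper_count = b$upper_count,
                 lower_count = b$lower_count,
                 inhibition_undetectable = is.na(b$lower_count),
                 n_trials = n_trials, bin_width = binned$bin_width,
                 window = binned$window),
            class = "classification_result")
}

#' Cue-evoked response classification
#'
#' 50-ms bins on `[0, 0.5)` s after CS+ onset, responded trials only;
#' excitation at the 99.9% bound, inhibition at the 99% bound, both derived
#' from the 10-s pre-cue baseline.
#'
#' @param unit A [spike_train()] or numeric spike times.
#' @param trials A `trial_table`; responded CS+ trials are used. For
#'   infusion sessions classification is restricted to the pre-injection
#'   epoch via `epoch`.
#' @param epoch Optional epoch filter (e.g. `"pre"`).
#' @param baseline_length Baseline length, seconds (default 10).
#' @inheritParams classify_response
#' @return A `classification_result`.
#' @export
classify_cue_response <- function(unit, trials, epoch = NULL,
                                  baseline_length = 10,
                                  upper_level = 0.999, lower_level = 0.01) {
  onsets <- responded_csplus_onsets(trials, epoch)
  if (length(onsets) == 0) stop("no responded CS+ trials")
  binned <- bin_counts(unit, onsets, window = c(0, 0.5), bin_width = 0.05)
  rate <- baseline_rate(unit, onsets, baseline_length)
  classify_response(binned, rate, upper_level, lower_level,
                    unit_id = if (inherits(unit, "spike_train")) unit$unit_id
                      else NA_character_)
}

#' Consumption-epoch response classification
#'
#' 400-ms bins after the rewarded receptacle entry, compared with the 99%
#' Poisson bounds from the 10-s pre-cue baseline. The nominal 3-s window is
#' not divisible by 400 ms; the seven full bins covering `[0, 2.8)` s are
#' used and the 200-ms remainder is dropped.
#'
#' @inheritParams classify_cue_response
#' @return A `classification_result`.
#' @export
classify_consumption_response <- function(unit, trials, epoch = NULL,
                                          baseline_length = 10,
                                          upper_level = 0.99,
                                          lower_level = 0.01) {
  keep <- !is.na(trials$rewarded_entry_time)
  if (!is.null(epoch)) keep <- keep & trials$epoch %in% epoch
  entries <- trials$rewarded_entry_time[keep]
  onsets <- trials$cue_onset[keep]
  if (length(entries) == 0) stop("no rewarded entries")
  binned <- bin_counts(unit, entries, window = c(0, 2.8), bin_width = 0.4)
  rate <- baseline_rate(unit, onsets, baseline_length)
  classify_response(binned, rate, upper_level, lower_level,
                    unit_id = if (inherits(unit, "spike_train")) unit$unit_id
                      else NA_character_)
}

#' Fraction of units significant in each bin
#'
#' The population traces behind the percent-excited / percent-inhibited
#' figures: for each bin, the fraction of units whose mask is set.
#'
#' @param results List of `classification_result`s over one population.
#' @param direction `"excited"` or `"inhibited"`.
#' @return Numeric vector, one fraction in `[0, 1]` per bin.
#' @export
population_bin_fractions <- function(results,
                                     direction = c("excited", "inhibited")) {
  direction <- match.arg(direction)
  if (length(results) == 0) stop("empty population")
  masks <- vapply(results, function(r)
    if (direction == "excited") r$excited_bins else r$inhibited_bins,
    logical(length(results[[1]]$excited_bins)))
  rowMeans(matrix(masks, ncol = length(results)))
}

#' Proportion of a unit's bins with significant modulation
#'
#' Computed per unit over the bins of its analysis window, in the direction
#' of the unit's own label (the population summaries include only units
#' carrying the corresponding label).
#'
#' @param result A `classification_result`.
#' @param direction `"excited"` or `"inhibited"`; defaults to the label.
#' @return Fraction of bins in `[0, 1]`.
#' @export
significant_bin_proportion <- function(result, direction = NULL) {
  if (is.null(direction)) direction <- result$label
  mask <- switch(direction,
                 excited = result$excited_bins,
                 inhibited = result$inhibited_bins,
                 stop("unit is not labelled excited or inhibited"))
  mean(mask)
}
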