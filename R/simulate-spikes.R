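#' Sample ground-truth approach-vigor covariates
#'
#' Draws per-trial values of the three vigor covariates entering the
#' log-linear cue-window count model: distance from the receptacle at cue
#' onset, latency to maximum speed, and average approach speed. Values are in
#' model units scaled to keep the log-linear predictor in a physiological
#' range for the default coefficient magnitudes.
#'
#' @param n Number of trials.
#' @return Data frame with columns `distance`, `latency_max_speed`,
#'   `avg_speed`, all non-negative.
#' @export
sample_vigor_covariates <- function(n) {
  data.frame(distance = stats::runif(n, 0, 2),
             latency_max_speed = stats::runif(n, 0, 2),
             avg_speed = stats::runif(n, 0, 2))
}

#' Simulate trial counts directly from the log-linear vigor model
#'
#' Generates `n` responded-trial covariate vectors and Poisson spike counts
#' with log-mean `beta[1] + beta[2]*distance + beta[3]*latency_max_speed +
#' beta[4]*avg_speed` — the generative mirror of the count GLM fitted by
#' [fit_count_glm()].
#'
#' @param n Number of trials.
#' @param beta Length-4 coefficient vector (intercept first).
#' @return Data frame with `count` plus the three covariate columns.
#' @export
simulate_glm_trials <- function(n, beta = c(1.2, 0.4, -0.3, 0.1)) {
  stopifnot(length(beta) == 4)
  x <- sample_vigor_covariates(n)
  eta <- beta[1] + beta[2] * x$distance + beta[3] * x$latency_max_speed +
    beta[4] * x$avg_speed
  cbind(data.frame(count = stats::rpois(n, exp(eta))), x)
}

# piecewise-constant-rate Poisson sampler over a partition of [0, len]
sample_piecewise_poisson <- function(segments) {
  times <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    len <- segments$end[i] - segments$start[i]
    if (len <= 0 || segments$rate[i] <= 0) return(numeric(0))
    k <- stats::rpois(1, segments$rate[i] * len)
    if (k == 0) return(numeric(0))
    segments$start[i] + sort(stats::runif(k, 0, len))
  }))
  unique(sort(times))
}

#' Simulate one unit's spike train for a session
#'
#' Piecewise-inhomogeneous Poisson process: rate `baseline_rate` everywhere
#' except (a) the cue-gain window on responded CS+ trials, where the expected
#' count equals `exp(b0 + b1 x1 + b2 x2 + b3 x3)` with the trial's vigor
#' covariates, and (b) the consumption window `[entry, entry + 3)` s after
#' rewarded entries for consumption-modulated units (rate scaled by
#' `consumption_gain`). Where a rewarded entry falls inside the cue-gain
#' window, the cue window takes priority and the consumption modulation
#' starts at its end.
#'
#' For drug-exposed units (`drug_exposure == "ipsi"`) with infusion markers
#' present, the cue gain's excess over baseline is multiplied by a factor
#' ramping linearly from 1 at infusion start to `drug_attenuation` at
#' infusion end, and held there after.
#'
#' Uses the ambient RNG; seed upstream for reproducibility.
#'
#' @param profile A [unit_profile()].
#' @param trials A `trial_table` (from [build_trial_table()]).
#' @param covariates Data frame of vigor covariates with one row per
#'   responded CS+ trial (in trial order); required when the profile's beta
#'   has nonzero slopes, otherwise defaults to zeros.
#' @param session_length Session length, seconds.
#' @param infusion Optional numeric `c(start, end)` of the infusion, seconds.
#' @param unit_id Identifier given to the returned spike train.
#' @return A [spike_train()] carrying the profile's metadata.
#' @export
simulate_spike_train <- function(profile, trials, covariates = NULL,
                                 session_length, infusion = NULL,
                                 unit_id = "u1") {
  stopifnot(inherits(profile, "unit_profile"))
  resp <- trials[trials$cue_type == "cs_plus" & trials$responded, , drop = FALSE]
  if (is.null(covariates)) {
    covariates <- data.frame(distance = rep(0, nrow(resp)),
                             latency_max_speed = 0, avg_speed = 0)
  }
  if (nrow(covariates) != nrow(resp))
    stop("need one covariate row per responded CS+ trial")

  w <- profile$cue_gain_window
  width <- diff(w)
  att <- function(t) {
    if (is.null(infusion) || profile$drug_exposure != "ipsi") return(1)
    if (t < infusion[1]) 1
    else if (t >= infusion[2]) profile$drug_attenuation
    else 1 + (profile$drug_attenuation - 1) * (t - infusion[1]) /
      (infusion[2] - infusion[1])
  }

  mods <- data.frame(start = numeric(0), end = numeric(0), rate = numeric(0))
  cue_mod <- any(c("cue_excited", "cue_inhibited") %in% profile$response_class) ||
    any(profile$beta[-1] != 0) ||
    abs(profile$beta[1] - log(profile$baseline_rate * width)) > 1e-12
  if (cue_mod && nrow(resp) > 0) {
    eta <- profile$beta[1] + profile$beta[2] * covariates$distance +
      profile$beta[3] * covariates$latency_max_speed +
      profile$beta[4] * covariates$avg_speed
    rate_cue <- exp(eta) / width
    a <- vapply(resp$cue_onset, att, numeric(1))
    rate_eff <- profile$baseline_rate + (rate_cue - profile$baseline_rate) * a
    mods <- rbind(mods, data.frame(start = resp$cue_onset + w[1],
                                   end = resp$cue_onset + w[2],
                                   rate = pmax(rate_eff, 0)))
  }
  cons_mod <- any(c("consumption_excited", "consumption_inhibited") %in%
                    profile$response_class)
  if (cons_mod) {
    ent <- trials$rewarded_entry_time[!is.na(trials$rewarded_entry_time)]
    on <- trials$cue_onset[!is.na(trials$rewarded_entry_time)]
    start <- if (cue_mod) pmax(ent, on + w[2]) else ent
    mods <- rbind(mods, data.frame(start = start, end = ent + 3,
                                   rate = profile$baseline_rate *
                                     profile$consumption_gain))
  }
  mods <- mods[order(mods$start), , drop = FALSE]
  if (nrow(mods) > 1 && any(mods$start[-1] < mods$end[-nrow(mods)] - 1e-9))
    stop("overlapping modulation windows")
  # partition [0, session_length] into baseline and modulation segments
  seg_start <- c(0, mods$end)
  seg_end <- c(mods$start, session_length)
  base <- data.frame(start = seg_start, end = pmin(seg_end, session_length),
                     rate = profile$baseline_rate)
  base <- base[base$end > base$start, , drop = FALSE]
  mods <- mods[mods$start < session_length, , drop = FALSE]
  mods$end <- pmin(mods$end, session_length)
  spike_times <- sample_piecewise_poisson(rbind(base, mods))
  spike_train(unit_id, spike_times, amplitude_uV = profile$amplitude_uV,
              hemisphere = profile$hemisphere,
              drug_exposure = profile$drug_exposure)
}
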