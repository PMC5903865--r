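#' Sample truncated-exponential intertrial intervals
#'
#' ITIs follow an exponential distribution with mean `iti_mean`, truncated by
#' rejection to `[iti_min, iti_max]`. Note that the realized mean of the
#' truncated draw exceeds the parent mean (about 46 s for the 30 s / 10--150 s
#' defaults) because truncation removes more short than long intervals.
#'
#' @param n Number of intervals to draw.
#' @param config A [task_config()].
#' @return Numeric vector of `n` intervals, seconds, all within
#'   `[iti_min, iti_max]`.
#' @export
sample_iti <- function(n, config = task_config()) {
  if (config$iti_min > config$iti_max) stop("invalid ITI config")
  if (config$iti_min == config$iti_max) return(rep(config$iti_min, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rexp(max(2 * (n - length(out)), 16), rate = 1 / config$iti_mean)
    out <- c(out, draw[draw >= config$iti_min & draw <= config$iti_max])
  }
  out[seq_len(n)]
}

new_event_log <- function(time, kind, detail = NA_character_) {
  df <- data.frame(time = as.numeric(time), kind = as.character(kind),
                   detail = as.character(detail), stringsAsFactors = FALSE)
  df <- df[order(df$time, match(df$kind, event_kinds())), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

event_kinds <- function() {
  c("cs_plus_on", "cs_minus_on", "cue_off", "receptacle_entry",
    "receptacle_exit", "reward_delivery", "infusion_start", "infusion_end")
}

rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  # inverse-CDF sampling of a log-normal truncated to (0, upper]
  pu <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, 0, pu), meanlog, sdlog)
}

#' Generate the event log of one CS-task session
#'
#' Builds an alternating ITI/cue sequence: each trial is CS+ with probability
#' `cs_plus_prob`; a response (receptacle entry during the cue) on a CS+ trial
#' delivers reward and terminates the cue, whereas the CS- always plays for
#' its full duration and entries during it have no consequence. Responded
#' trials also carry a later receptacle exit (consumption offset). The CS+
#' response probability follows the behavior model's state-dependent level
#' and within-session multiplicative decline. With `infusion_at` set,
#' `infusion_start`/`infusion_end` markers are written
#' `infusion_duration` seconds apart.
#'
#' Uses the current RNG state; seed upstream (e.g. [simulate_session()]) for
#' reproducibility.
#'
#' @param config A [task_config()].
#' @param behavior A [behavior_model()].
#' @param infusion_at Optional infusion trigger time, seconds (e.g. 2000).
#' @param infusion_duration Infusion length, seconds (default 720 = 12 min).
#' @return An `event_log` data frame (columns `time`, `kind`, `detail`). If
#'   the session is too short for a single trial, an empty log with a
#'   `"warning"` attribute is returned.
#' @export
generate_events <- function(config = task_config(),
                            behavior = behavior_model("free_fed"),
                            infusion_at = NULL, infusion_duration = 720) {
  stopifnot(inherits(config, "task_config"), inherits(behavior, "behavior_model"))
  times <- numeric(0); kinds <- character(0); details <- character(0)
  add <- function(t, k, d = NA_character_) {
    times <<- c(times, t); kinds <<- c(kinds, k); details <<- c(details, d)
  }
  consumption_dur <- function(n) 3 + stats::rgamma(n, shape = 2, rate = 0.7)

  t <- 0
  n_trials <- 0
  repeat {
    onset <- t + sample_iti(1, config)
    if (onset + config$cue_duration > config$session_length) break
    n_trials <- n_trials + 1
    is_plus <- stats::runif(1) < config$cs_plus_prob
    drug <- if (is.null(infusion_at) || onset <= infusion_at) 1
      else if (onset >= infusion_at + infusion_duration)
        behavior$drug_response_factor
      else 1 + (behavior$drug_response_factor - 1) *
        (onset - infusion_at) / infusion_duration
    p_resp <- if (is_plus) {
      drug * behavior$p_respond_0 * (1 - behavior$decline_rate)^(onset / 60)
    } else behavior$p_respond_csminus
    responded <- stats::runif(1) < p_resp
    latency <- if (responded)
      rlnorm_trunc(1, behavior$latency_meanlog, behavior$latency_sdlog,
                   config$cue_duration) else NA_real_
    add(onset, if (is_plus) "cs_plus_on" else "cs_minus_on")
    if (is_plus && responded) {
      entry <- onset + latency
      add(entry, "receptacle_entry")
      add(entry, "reward_delivery")
      add(entry, "cue_off")             # rewarded entry terminates the cue
      exit <- min(entry + consumption_dur(1), config$session_length)
      add(exit, "receptacle_exit")
      t <- max(onset + config$cue_duration, exit)
    } else {
      if (responded) add(onset + latency, "receptacle_entry")
      add(onset + config$cue_duration, "cue_off")
      t <- onset + config$cue_duration
    }
  }
  if (!is.null(infusion_at)) {
    add(infusion_at, "infusion_start")
    add(infusion_at + infusion_duration, "infusion_end")
  }
  log <- new_event_log(times, kinds, details)
  if (n_trials == 0) {
    warning("session too short for a single trial; returning empty event log")
    attr(log, "warning") <- "empty"
  }
  log
}
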