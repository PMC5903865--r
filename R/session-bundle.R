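#' Simulate a complete CS-task session with known ground truth
#'
#' Chains the event, covariate, spike-train and (optionally) tracking
#' generators into one reproducible session bundle. The same seed reproduces
#' the session bit-exactly.
#'
#' Per-trial vigor covariates driving the units' cue-window counts are drawn
#' in model units from [sample_vigor_covariates()]; the tracking trace
#' records its own ground-truth covariates in cm / cm/s.
#'
#' @param config A [task_config()].
#' @param behavior A [behavior_model()].
#' @param profiles List of [unit_profile()]s, one simulated unit each.
#' @param infusion_at Optional infusion trigger time, seconds.
#' @param infusion_duration Infusion length, seconds.
#' @param tracking Logical: also simulate a 30-fps position trace.
#' @param seed Integer seed for the whole session.
#' @return A `session_bundle`: `events`, `trials`, `units` (list of
#'   [spike_train()]), `profiles`, `covariates` (one row per responded CS+
#'   trial), `tracking` (or `NULL`), `config`, `behavior`, `infusion`.
#' @export
simulate_session <- function(config = task_config(),
                             behavior = behavior_model("free_fed"),
                             profiles = list(unit_profile()),
                             infusion_at = NULL, infusion_duration = 720,
                             tracking = FALSE, seed = 1) {
  set.seed(seed)
  events <- generate_events(config, behavior, infusion_at, infusion_duration)
  trials <- build_trial_table(events, config$cue_duration)
  n_resp <- sum(trials$cue_type == "cs_plus" & trials$responded)
  covariates <- sample_vigor_covariates(n_resp)
  infusion <- if (!is.null(infusion_at))
    c(infusion_at, infusion_at + infusion_duration) else NULL
  units <- lapply(seq_along(profiles), function(i) {
    st <- simulate_spike_train(profiles[[i]], trials, covariates,
                               config$session_length, infusion,
                               unit_id = sprintf("u%03d", i))
    st$state <- behavior$state
    st
  })
  trace <- if (tracking)
    simulate_tracking(trials, config$session_length) else NULL
  structure(list(events = events, trials = trials, units = units,
                 profiles = profiles, covariates = covariates,
                 tracking = trace, config = config, behavior = behavior,
                 infusion = infusion),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("CS-task session:", nrow(x$trials), "trials (",
      sum(x$trials$cue_type == "cs_plus" & x$trials$responded),
      "responded CS+ ),", length(x$units), "units,",
      if (is.null(x$tracking)) "no tracking" else "with tracking",
      if (is.null(x$infusion)) "" else
        sprintf(", infusion at %.0f s", x$infusion[1]), "\n")
  invisible(x)
}
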