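#' Task configuration for a CS session
#'
#' Bundles the timing parameters of the cued-approach (CS) task: two auditory
#' cues (CS+ reward-predictive, CS- neutral) presented in random order at
#' intertrial intervals drawn from a truncated exponential distribution.
#'
#' @param session_length Session duration in seconds.
#' @param cue_duration Maximum cue duration in seconds (a rewarded entry
#'   terminates the CS+ early).
#' @param iti_mean Mean (rate parameter^-1) of the parent exponential ITI
#'   distribution, seconds.
#' @param iti_min,iti_max Truncation bounds of the ITI distribution, seconds.
#' @param cs_plus_prob Probability that a given trial is a CS+.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(session_length = 7200, cue_duration = 5,
                        iti_mean = 30, iti_min = 10, iti_max = 150,
                        cs_plus_prob = 0.5) {
  if (!(iti_min <= iti_mean && iti_mean <= iti_max))
    stop("invalid ITI config: need iti_min <= iti_mean <= iti_max")
  if (cue_duration <= 0) stop("cue_duration must be > 0")
  if (cs_plus_prob <= 0 || cs_plus_prob >= 1)
    stop("cs_plus_prob must be in (0, 1)")
  if (session_length <= 0) stop("session_length must be > 0")
  structure(list(session_length = session_length, cue_duration = cue_duration,
                 iti_mean = iti_mean, iti_min = iti_min, iti_max = iti_max,
                 cs_plus_prob = cs_plus_prob),
            class = "task_config")
}

#' Behavioral response model
#'
#' Parameterizes state-dependent cued responding: free-fed animals start at a
#' lower response probability and decline multiplicatively over the session,
#' food-restricted animals respond at a high, stable rate and respond more to
#' the CS- as well. Response latency is truncated log-normal on
#' (0, cue_duration].
#'
#' @param state `"free_fed"` or `"restricted"`.
#' @param p_respond_0 Initial CS+ response probability.
#' @param decline_rate Per-minute multiplicative decline of CS+ responding
#'   (free-fed only; must be 0 for restricted).
#' @param p_respond_csminus CS- response probability (constant).
#' @param latency_meanlog,latency_sdlog Log-normal latency parameters
#'   (seconds), truncated to (0, cue_duration]. Restricted animals approach
#'   with shorter latencies (hence higher average approach speed) by default.
#' @param drug_response_factor Multiplicative factor on the CS+ response
#'   probability after an intracranial infusion (1 = no behavioral drug
#'   effect), ramping in linearly over the infusion, mirroring the
#'   MOR-antagonist attenuation of cued approach in free-fed animals.
#'
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(state = c("free_fed", "restricted"),
                           p_respond_0 = NULL, decline_rate = NULL,
                           p_respond_csminus = NULL,
                           latency_meanlog = NULL, latency_sdlog = 0.5,
                           drug_response_factor = 1) {
  state <- match.arg(state)
  if (is.null(p_respond_0)) p_respond_0 <- if (state == "free_fed") 0.9 else 0.95
  if (is.null(decline_rate)) decline_rate <- if (state == "free_fed") 0.01 else 0
  if (is.null(p_respond_csminus))
    p_respond_csminus <- if (state == "free_fed") 0.15 else 0.35
  if (is.null(latency_meanlog))
    latency_meanlog <- if (state == "free_fed") log(1.8) else log(0.9)
  stopifnot(p_respond_0 >= 0, p_respond_0 <= 1,
            p_respond_csminus >= 0, p_respond_csminus <= 1,
            decline_rate >= 0)
  if (state == "restricted" && decline_rate != 0)
    stop("restricted state has no within-session decline (decline_rate must be 0)")
  stopifnot(drug_response_factor >= 0, drug_response_factor <= 1)
  structure(list(state = state, p_respond_0 = p_respond_0,
                 decline_rate = decline_rate,
                 p_respond_csminus = p_respond_csminus,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 drug_response_factor = drug_response_factor),
            class = "behavior_model")
}

#' Ground-truth firing profile of a simulated unit
#'
#' Describes one unit's baseline rate, peri-event modulation class, and the
#' log-linear coefficients governing its trial-to-trial cue-window spike count
#' as a function of approach-vigor covariates. `beta` is the ground-truth side
#' of the count model ln E[Y] = b0 + b1 x1 + b2 x2 + b3 x3; when `NULL` it is
#' derived from `cue_gain` as an intercept-only model.
#'
#' @param baseline_rate Baseline firing rate, Hz (> 0).
#' @param response_class Character vector drawn from `"cue_excited"`,
#'   `"cue_inhibited"`, `"consumption_excited"`, `"consumption_inhibited"`,
#'   or `"none"`; combinations (e.g. cue- and consumption-excited) allowed.
#' @param cue_gain Multiplicative rate gain inside `cue_gain_window` used when
#'   `beta` is `NULL` (for inhibited classes supply a value < 1).
#' @param cue_gain_window Post-cue window carrying the cue modulation,
#'   seconds (default 0.1--0.3 s).
#' @param beta Optional length-4 coefficient vector (b0..b3) of the
#'   log-linear cue-window count model (counts in `cue_gain_window`).
#' @param consumption_gain Rate gain on `[entry, entry + 3)` s after the
#'   rewarded entry for consumption classes.
#' @param drug_attenuation Factor in `[0, 1]` multiplying the cue gain's
#'   excess over baseline after infusion for drug-exposed units (1 = no
#'   effect).
#' @param drug_exposure `"ipsi"`, `"contra"` or `"none"`: whether the unit's
#'   hemisphere received drug.
#' @param amplitude_uV Waveform amplitude in microvolts (unit-QC metadata).
#' @param hemisphere `"left"` or `"right"`.
#'
#' @return An object of class `unit_profile`.
#' @export
unit_profile <- function(baseline_rate = 5, response_class = "none",
                         cue_gain = 1, cue_gain_window = c(0.1, 0.3),
                         beta = NULL, consumption_gain = 1,
                         drug_attenuation = 1,
                         drug_exposure = c("none", "ipsi", "contra"),
                         amplitude_uV = 150,
                         hemisphere = c("left", "right")) {
  drug_exposure <- match.arg(drug_exposure)
  hemisphere <- match.arg(hemisphere)
  known <- c("cue_excited", "cue_inhibited", "consumption_excited",
             "consumption_inhibited", "none")
  if (!all(response_class %in% known))
    stop("unknown response_class: ",
         paste(setdiff(response_class, known), collapse = ", "))
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (drug_attenuation < 0 || drug_attenuation > 1)
    stop("drug_attenuation must be in [0, 1]")
  w <- diff(cue_gain_window)
  if (w <= 0) stop("cue_gain_window must have positive length")
  if (is.null(beta)) {
    g <- if ("cue_excited" %in% response_class && cue_gain <= 1) 5
         else if ("cue_inhibited" %in% response_class && cue_gain >= 1) 0.2
         else cue_gain
    beta <- c(log(baseline_rate * g * w), 0, 0, 0)
  }
  if (length(beta) != 4) stop("beta must have length 4 (b0..b3)")
  if ("consumption_excited" %in% response_class && consumption_gain <= 1)
    consumption_gain <- 3
  if ("consumption_inhibited" %in% response_class && consumption_gain >= 1)
    consumption_gain <- 0.2
  structure(list(baseline_rate = baseline_rate,
                 response_class = response_class,
                 cue_gain_window = cue_gain_window, beta = beta,
                 consumption_gain = consumption_gain,
                 drug_attenuation = drug_attenuation,
                 drug_exposure = drug_exposure,
                 amplitude_uV = amplitude_uV, hemisphere = hemisphere),
            class = "unit_profile")
}
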