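#!/usr/bin/env Rscript
# Simulate the study's session types with known ground truth and write them
# as delimited session directories under results/sessions/.
#
# Three sessions are produced:
#   freefed    — free-fed recording session (response decline, mixed units)
#   restricted — food-restricted session (higher responding, stronger gains)
#   injection  — free-fed session with a mid-session antagonist infusion
#                (2000 s baseline, 12-min infusion, drug-exposed units)

library(cuedapproach)

out_root <- "results/sessions"

mixed_units <- function(gain_excited, n_exc = 6, n_inh = 2, n_cons = 4,
                        n_none = 4, ...) {
  c(lapply(seq_len(n_exc), function(i)
      unit_profile(baseline_rate = 6, response_class = "cue_excited",
                   cue_gain = gain_excited, ...)),
    lapply(seq_len(n_inh), function(i)
      unit_profile(baseline_rate = 12, response_class = "cue_inhibited", ...)),
    lapply(seq_len(n_cons), function(i)
      unit_profile(baseline_rate = 5,
                   response_class = "consumption_excited", ...)),
    lapply(seq_len(n_none), function(i)
      unit_profile(baseline_rate = 4, ...)))
}

message("simulating free-fed session ...")
freefed <- simulate_session(task_config(session_length = 7200),
                            behavior_model("free_fed"),
                            profiles = mixed_units(gain_excited = 3.5),
                            tracking = TRUE, seed = 1001)
write_session(freefed, file.path(out_root, "freefed"))
print(freefed)

message("simulating food-restricted session ...")
restricted <- simulate_session(task_config(session_length = 7200),
                               behavior_model("restricted"),
                               profiles = mixed_units(gain_excited = 5),
                               tracking = TRUE, seed = 1002)
write_session(restricted, file.path(out_root, "restricted"))
print(restricted)

message("simulating free-fed injection session ...")
injection <- simulate_session(
  task_config(session_length = 4720),
  behavior_model("free_fed", drug_response_factor = 0.35),
  profiles = mixed_units(gain_excited = 4, drug_exposure = "ipsi",
                         drug_attenuation = 0.3),
  infusion_at = 2000, infusion_duration = 720, seed = 1003)
write_session(injection, file.path(out_root, "injection"))
print(injection)

message("sessions written under ", out_root)
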