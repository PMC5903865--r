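#!/usr/bin/env Rscript
# Behavioral endpoints of the simulated sessions: response ratios,
# discrimination index, 20-min time course, and the pre/post-infusion
# comparison for the injection design.

library(cuedapproach)

sessions <- c("freefed", "restricted", "injection")
summary_rows <- list()
for (name in sessions) {
  s <- read_session(file.path("results/sessions", name))
  tt <- s$trials
  summary_rows[[name]] <- data.frame(
    session = name,
    n_trials = nrow(tt),
    csplus_ratio = response_ratio(tt, "cs_plus"),
    csminus_ratio = response_ratio(tt, "cs_minus"),
    discrimination = discrimination_index(tt),
    meets_criterion = response_ratio(tt, "cs_plus") > 0.40 &
      discrimination_index(tt) >= 0.67)
  tb <- time_binned_performance(tt, s$config$session_length, bin_min = 20)
  write.table(tb, sprintf("results/behavior_timecourse_%s.tsv", name),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
behavior <- do.call(rbind, summary_rows)
write.table(behavior, "results/behavior_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(behavior, row.names = FALSE)

# pre/post comparison over a small simulated cohort of injection sessions:
# antagonist sessions attenuate post-infusion CS+ responding, vehicle
# sessions do not
set.seed(2001)
cfg <- task_config(session_length = 4720)
pair <- function(bm) {
  tt <- build_trial_table(generate_events(cfg, bm, infusion_at = 2000,
                                          infusion_duration = 720), 5)
  c(pre = response_ratio(tt, "cs_plus", epoch = "pre"),
    post = response_ratio(tt, "cs_plus", epoch = "post"))
}
ctap <- replicate(8, pair(behavior_model("free_fed", drug_response_factor = 0.35)))
veh <- replicate(5, pair(behavior_model("free_fed")))
cmp <- pre_post_compare(list(ctap = ctap["pre", ], vehicle = veh["pre", ]),
                        list(ctap = ctap["post", ], vehicle = veh["post", ]))
write.table(cmp, "results/behavior_prepost.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("\npre/post-infusion comparison (Wilcoxon signed-rank, Holm-Sidak):")
print(cmp, row.names = FALSE)
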