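#!/usr/bin/env Rscript
# Video-tracking analyses of the simulated traces: locomotor index,
# two-Gaussian still/moving threshold, movement-onset latencies, and the
# per-trial vigor covariates that feed the count GLM.

library(cuedapproach)

rows <- list(); lat_rows <- list()
for (name in c("freefed", "restricted")) {
  s <- read_session(file.path("results/sessions", name))
  li <- locomotor_index(s$tracking)
  li <- movement_threshold(li)
  message(sprintf("%s: LI threshold %.3f (mixture means %.3f / %.3f)",
                  name, li$threshold, li$mixture$means[1],
                  li$mixture$means[2]))
  tt <- s$trials
  resp <- which(tt$cue_type == "cs_plus" & tt$responded)
  for (i in resp) {
    end <- tt$rewarded_entry_time[i]
    cv <- trial_vigor_covariates(s$tracking, tt$cue_onset[i], end)
    rows[[paste(name, i)]] <- data.frame(
      session = name, trial = i, distance = cv$distance,
      latency_max_speed = cv$latency_max_speed, avg_speed = cv$avg_speed)
    lat_rows[[paste(name, i)]] <- data.frame(
      session = name, trial = i,
      move_latency = movement_onset_latency(li, tt$cue_onset[i],
                                            deadline = end + 1))
  }
}
cov <- do.call(rbind, rows)
lat <- do.call(rbind, lat_rows)
write.table(cov, "results/tracking_covariates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(lat, "results/tracking_latencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

agg <- aggregate(cbind(distance, latency_max_speed, avg_speed) ~ session,
                 cov, mean)
print(agg, row.names = FALSE)
w <- wilcox.test(cov$avg_speed[cov$session == "restricted"],
                 cov$avg_speed[cov$session == "freefed"])
message(sprintf("restricted vs free-fed average approach speed: rank-sum p = %.3g",
                w$p.value))
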