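# shared fixture builders (all synthetic, generated at test time)

# homogeneous Poisson spike train on [0, len] at `rate` Hz
poisson_train <- function(rate, len, id = "u1", ...) {
  n <- rpois(1, rate * len)
  spike_train(id, unique(sort(runif(n, 0, len))), ...)
}

# trial table with `n` responded CS+ trials spaced `gap` s apart
responded_trials <- function(n, gap = 20, latency = 2, first = 15) {
  onsets <- first + gap * (seq_len(n) - 1)
  ev <- new_event_log_for_test(onsets, latency)
  build_trial_table(ev, cue_duration = 5)
}

new_event_log_for_test <- function(onsets, latency = 2) {
  times <- c(onsets, onsets + latency, onsets + latency, onsets + latency,
             onsets + latency + 4)
  kinds <- rep(c("cs_plus_on", "receptacle_entry", "reward_delivery",
                 "cue_off", "receptacle_exit"), each = length(onsets))
  df <- data.frame(time = times, kind = kinds,
                   detail = rep(NA_character_, length(times)))
  df <- df[order(df$time), ]
  class(df) <- c("event_log", "data.frame")
  df
}

# brute-force Poisson CDF by term summation (independent of ppois/qpois)
brute_poisson_cdf <- function(x, lambda) {
  k <- 0:x
  sum(exp(-lambda + k * log(lambda) - lfactorial(k)))
}

# trapezoidal area under the explicitly constructed ROC curve
roc_area_explicit <- function(bin, base) {
  thr <- sort(unique(c(bin, base, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(bin >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(base >= s), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
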