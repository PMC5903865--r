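test_that("sampled ITIs respect the truncation bounds and the parent CDF", {
  set.seed(11)
  cfg <- task_config()
  draws <- sample_iti(10000, cfg)
  expect_true(all(draws >= 10), info = "no ITI below the minimum")
  expect_true(all(draws <= 150), info = "no ITI above the maximum")

  # degenerate truncation collapses to a point mass
  expect_equal(sample_iti(5, task_config(iti_mean = 30, iti_min = 30,
                                         iti_max = 30)),
               rep(30, 5))

  # empirical CDF against the analytically renormalized truncated-exp CDF
  trunc_cdf <- function(x) {
    lo <- pexp(10, 1 / 30); hi <- pexp(150, 1 / 30)
    (pexp(x, 1 / 30) - lo) / (hi - lo)
  }
  grid <- seq(10, 150, by = 0.5)
  emp <- ecdf(draws)
  expect_lt(max(abs(emp(grid) - trunc_cdf(grid))), 0.05)
})

test_that("invalid task configurations are rejected", {
  expect_error(task_config(iti_min = 40, iti_mean = 30), "iti_min")
  expect_error(task_config(cue_duration = 0))
  expect_error(task_config(cs_plus_prob = 1))
})

test_that("event generation rewards exactly the responded CS+ trials", {
  set.seed(21)
  cfg <- task_config(session_length = 4000)
  bm <- behavior_model("restricted", p_respond_0 = 1, p_respond_csminus = 0)
  ev <- generate_events(cfg, bm)
  tt <- build_trial_table(ev, cfg$cue_duration)
  plus <- tt$cue_type == "cs_plus"
  expect_true(all(tt$responded[plus]))
  expect_true(all(!is.na(tt$rewarded_entry_time[plus])))
  expect_true(all(is.na(tt$rewarded_entry_time[!plus])))
  expect_equal(sum(ev$kind == "reward_delivery"), sum(plus))
  # responded CS+ cues are truncated at the entry, CS- always full length
  expect_true(all(tt$cue_off[plus] < tt$cue_onset[plus] + 5))
  expect_equal(tt$cue_off[!plus], tt$cue_onset[!plus] + 5)
  # all event times inside the session
  expect_true(all(ev$time >= 0 & ev$time <= cfg$session_length))
})

test_that("cue identity is Bernoulli(cs_plus_prob) per trial", {
  set.seed(22)
  cfg <- task_config(session_length = 16000, iti_mean = 10, iti_min = 10,
                     iti_max = 10)
  tt <- build_trial_table(generate_events(cfg, behavior_model("restricted")),
                          5)
  n <- nrow(tt)
  expect_gt(n, 900)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  n_plus <- sum(tt$cue_type == "cs_plus")
  expect_gte(n_plus, ci[1])
  expect_lte(n_plus, ci[2])
})

test_that("free-fed responding declines within the session", {
  set.seed(23)
  diffs <- replicate(200, {
    ev <- generate_events(task_config(session_length = 7200),
                          behavior_model("free_fed"))
    tt <- build_trial_table(ev, 5)
    first <- response_ratio(tt, "cs_plus", window = c(0, 1200))
    last <- response_ratio(tt, "cs_plus", window = c(6000, 7200))
    first - last
  })
  expect_gt(mean(diffs), 0)
})

test_that("a session too short for one trial warns and returns an empty log", {
  expect_warning(ev <- generate_events(task_config(session_length = 5)),
                 "too short")
  expect_equal(nrow(build_trial_table(ev, 5)), 0)
})

test_that("unmodulated units are homogeneous Poisson in disjoint windows", {
  set.seed(31)
  tt <- responded_trials(3)
  # chi-square dispersion test on counts in 20 disjoint 0.5-s windows
  n_rej <- 0
  for (i in 1:1000) {
    st <- simulate_spike_train(unit_profile(baseline_rate = 5), tt,
                               session_length = 100)
    counts <- bin_counts(st, seq(70, 89.5, by = 1), c(0, 0.5), 0.5)$counts
    x <- as.vector(counts)
    disp <- sum((x - mean(x))^2) / mean(x)
    p <- pchisq(disp, length(x) - 1, lower.tail = FALSE)
    if (p < 0.005 || p > 0.995) n_rej <- n_rej + 1   # two-sided alpha 0.01
  }
  expect_lt(n_rej / 1000, 0.01 + 3 * sqrt(0.01 * 0.99 / 1000))
})

test_that("the cue-window count follows the log-linear ground truth", {
  set.seed(32)
  tt <- responded_trials(200, gap = 15)
  # intercept-only: 5x gain over an 8 Hz baseline in a 0.2-s window
  pr <- unit_profile(baseline_rate = 8, response_class = "cue_excited",
                     cue_gain = 5)
  expect_equal(pr$beta[1], log(8 * 5 * 0.2))
  st <- simulate_spike_train(pr, tt, session_length = 3100)
  counts <- bin_counts(st, responded_csplus_onsets(tt), c(0.1, 0.3), 0.2)$counts
  expect_equal(mean(counts), 8, tolerance = 0.15)  # E = exp(b0) = 8

  # covariate-driven counts: expected count tracks exp(beta' x) per trial
  beta <- c(1.2, 0.4, -0.3, 0.1)
  covs <- sample_vigor_covariates(200)
  pr2 <- unit_profile(baseline_rate = 5, response_class = "cue_excited",
                      beta = beta)
  mu <- exp(beta[1] + as.matrix(covs) %*% beta[-1])
  tot <- replicate(40, {
    st2 <- simulate_spike_train(pr2, tt, covs, session_length = 3100)
    sum(bin_counts(st2, responded_csplus_onsets(tt), c(0.1, 0.3), 0.2)$counts)
  })
  expect_equal(mean(tot), sum(mu), tolerance = 0.05)
})

test_that("fixing the seed reproduces a session bit-exactly", {
  a <- simulate_session(task_config(session_length = 1500),
                        profiles = list(unit_profile()), tracking = TRUE,
                        seed = 7)
  b <- simulate_session(task_config(session_length = 1500),
                        profiles = list(unit_profile()), tracking = TRUE,
                        seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$units[[1]]$times, b$units[[1]]$times)
  expect_identical(a$tracking$frames, b$tracking$frames)
})

test_that("simulated tracking carries the intended movement structure", {
  set.seed(33)
  # no responses and no jitter: perfectly still trace, LI identically 0
  tt0 <- build_trial_table(new_event_log_for_test(numeric(0)), 5)
  tr0 <- simulate_tracking(tt0, session_length = 60, still_sd = 0)
  li0 <- locomotor_index(tr0)
  expect_true(all(li0$li[!is.na(li0$li)] == 0))

  # with approaches, the LI histogram separates movement from jitter
  tt <- responded_trials(30, gap = 25)
  tr <- simulate_tracking(tt, session_length = 800)
  li <- locomotor_index(tr)
  still_level <- quantile(li$li[!is.na(li$li)], 0.5)
  expect_gt(max(li$li, na.rm = TRUE), 20 * still_level)
  expect_equal(nrow(tr$covariates), 30)
  expect_true(all(tr$covariates$distance >= 8))
})

test_that("restricted sessions have higher ground-truth approach speed", {
  set.seed(34)
  speed_of <- function(state) {
    s <- simulate_session(task_config(session_length = 3000),
                          behavior_model(state),
                          profiles = list(), tracking = TRUE,
                          seed = if (state == "free_fed") 101 else 102)
    mean(s$tracking$covariates$avg_speed)
  }
  expect_gt(speed_of("restricted"), speed_of("free_fed"))
})
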