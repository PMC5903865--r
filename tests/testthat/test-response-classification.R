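test_that("Poisson bounds match brute-force CDF summation", {
  # derived cases
  b <- poisson_bounds(0)
  expect_equal(b$upper_count, 0)
  expect_true(is.na(b$lower_count))
  expect_equal(poisson_bounds(5, 0.999, 0.01)$upper_count, 13)
  expect_equal(poisson_bounds(5, 0.999, 0.01)$lower_count, 0)
  expect_error(poisson_bounds(-1), ">= 0")

  # oracle equivalence over the lambda grid, both levels
  for (lam in c(0.1, 1, 5, 20, 100)) {
    for (lv in list(c(0.999, 0.01), c(0.99, 0.01))) {
      b <- poisson_bounds(lam, lv[1], lv[2])
      # smallest x with CDF >= upper_level
      x <- 0
      while (brute_poisson_cdf(x, lam) < lv[1]) x <- x + 1
      expect_equal(b$upper_count, x)
      # largest x with CDF <= lower_level
      lo <- NA_integer_
      x <- 0
      while (brute_poisson_cdf(x, lam) <= lv[2]) { lo <- x; x <- x + 1 }
      expect_equal(b$lower_count, lo)
    }
  }
})

test_that("null units are classified excited/inhibited at the nominal rates", {
  set.seed(51)
  n_units <- 1000; n_trials <- 30; rate <- 8
  n_exc <- 0; n_inh <- 0
  exc_bins <- 0; inh_bins <- 0; n_bins_tot <- 0
  for (i in seq_len(n_units)) {
    st <- rpois(n_trials * 10, rate * 0.05)         # 50-ms window counts
    counts <- matrix(st, nrow = n_trials)
    binned <- structure(list(counts = counts, window = c(0, 0.5),
                             bin_width = 0.05,
                             bin_starts = seq(0, 0.45, 0.05)),
                        class = "binned_counts")
    base_rate <- rpois(1, rate * 10 * n_trials) / (10 * n_trials)
    r <- classify_response(binned, base_rate)
    if (r$label %in% c("excited", "both")) n_exc <- n_exc + 1
    if (r$label %in% c("inhibited", "both")) n_inh <- n_inh + 1
    exc_bins <- exc_bins + sum(r$excited_bins)
    if (!r$inhibition_undetectable) {
      inh_bins <- inh_bins + sum(r$inhibited_bins)
      n_bins_tot <- n_bins_tot + length(r$inhibited_bins)
    }
  }
  # family-wise bound over the 10 bins for excitation at the 99.9% level
  fam <- 1 - 0.999^10
  expect_lt(n_exc / n_units, fam + 3 * sqrt(fam * (1 - fam) / n_units))
  # per-bin rates at the one-sided levels (bounds are conservative for
  # discrete counts; baseline-rate estimation adds a little spread)
  expect_lt(exc_bins / (n_units * 10), 0.001 + 3 * sqrt(0.001 / (n_units * 10)))
  expect_lt(inh_bins / n_bins_tot, 0.01 + 3 * sqrt(0.01 / n_bins_tot))
})

test_that("a 5x cue gain at 30 trials and 8 Hz baseline is detected", {
  set.seed(52)
  tt <- responded_trials(30, gap = 16)
  hits <- 0
  for (i in 1:200) {
    st <- simulate_spike_train(unit_profile(baseline_rate = 8,
                                            response_class = "cue_excited",
                                            cue_gain = 5),
                               tt, session_length = 520)
    r <- classify_cue_response(st, tt)
    if (r$label == "excited") hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("a silent unit is unclassifiable with an undetectable-inhibition flag", {
  tt <- responded_trials(20)
  r <- classify_cue_response(spike_train("s", numeric(0)), tt)
  expect_equal(r$label, "none")
  expect_true(r$inhibition_undetectable)
})

test_that("consumption-epoch classification detects inhibition and stays calibrated", {
  set.seed(53)
  tt <- responded_trials(40, gap = 16)
  # rate x0.2 for 3 s after entry, 10 Hz baseline
  st <- simulate_spike_train(unit_profile(baseline_rate = 10,
                                          response_class = "consumption_inhibited"),
                             tt, session_length = 700)
  r <- classify_consumption_response(st, tt)
  expect_equal(r$label, "inhibited")
  expect_length(r$excited_bins, 7)   # seven full 400-ms bins in [0, 2.8)

  # identical pre/post rates: the none-rate matches the exact calibration
  # of the any-of-7-bins rule. With known lambda the per-bin tail
  # probabilities are computable in closed form, so the expected none-rate
  # is (1 - p_exc - p_inh)^7.
  lambda <- 10 * 0.4 * 40
  bnds <- poisson_bounds(lambda, 0.99, 0.01)
  p_exc <- ppois(bnds$upper_count, lambda, lower.tail = FALSE)
  p_inh <- ppois(bnds$lower_count - 1, lambda)
  p_none <- (1 - p_exc - p_inh)^7
  n_none <- 0
  for (i in 1:300) {
    counts <- matrix(rpois(40 * 7, lambda / 40), nrow = 40)
    binned <- structure(list(counts = counts, window = c(0, 2.8),
                             bin_width = 0.4,
                             bin_starts = seq(0, 2.4, 0.4)),
                        class = "binned_counts")
    if (classify_response(binned, 10, 0.99, 0.01)$label == "none")
      n_none <- n_none + 1
  }
  se <- sqrt(p_none * (1 - p_none) / 300)
  expect_lt(abs(n_none / 300 - p_none), 4 * se)
})

test_that("raising the excitation level never adds excited bins", {
  set.seed(54)
  for (i in 1:50) {
    counts <- matrix(rpois(200, 1), nrow = 20)
    binned <- structure(list(counts = counts, window = c(0, 0.5),
                             bin_width = 0.05,
                             bin_starts = seq(0, 0.45, 0.05)),
                        class = "binned_counts")
    lo <- classify_response(binned, 2, upper_level = 0.99)
    hi <- classify_response(binned, 2, upper_level = 0.999)
    expect_true(all(lo$excited_bins | !hi$excited_bins))
  }
})

test_that("population bin fractions and per-unit proportions partition correctly", {
  mk <- function(exc, inh) {
    structure(list(label = if (any(exc)) "excited" else if (any(inh))
      "inhibited" else "none",
      excited_bins = exc, inhibited_bins = inh), class = "classification_result")
  }
  bins3 <- c(FALSE, FALSE, TRUE, rep(FALSE, 7))
  pop <- list(mk(bins3, rep(FALSE, 10)), mk(bins3, rep(FALSE, 10)))
  expect_equal(population_bin_fractions(pop, "excited"),
               c(0, 0, 1, rep(0, 7)))
  expect_error(population_bin_fractions(list()), "empty")

  r <- mk(c(rep(TRUE, 4), rep(FALSE, 6)), rep(FALSE, 10))
  expect_equal(significant_bin_proportion(r), 0.4)
  expect_error(significant_bin_proportion(mk(rep(FALSE, 10), rep(FALSE, 10))),
               "not labelled")

  # labels partition a population
  set.seed(55)
  tt <- responded_trials(25, gap = 16)
  labels <- replicate(60, {
    st <- simulate_spike_train(unit_profile(baseline_rate = 6), tt,
                               session_length = 420)
    classify_cue_response(st, tt)$label
  })
  expect_equal(sum(labels %in% c("excited", "inhibited", "both", "none")), 60)
})

test_that("classification with an injection uses only the pre epoch", {
  s <- simulate_session(task_config(session_length = 4720),
                        behavior_model("restricted"),
                        profiles = list(unit_profile(baseline_rate = 8,
                                                     response_class = "cue_excited",
                                                     cue_gain = 5,
                                                     drug_exposure = "ipsi",
                                                     drug_attenuation = 0)),
                        infusion_at = 2000, infusion_duration = 720,
                        seed = 56)
  u <- s$units[[1]]
  expect_equal(classify_cue_response(u, s$trials, epoch = "pre")$label,
               "excited")
  # with the gain fully suppressed post-injection, the post epoch is silent
  expect_equal(classify_cue_response(u, s$trials, epoch = "post")$label,
               "none")
})
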