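#' Fit the Poisson count GLM of post-cue firing on vigor covariates
#'
#' Maximum-likelihood Poisson regression with log link of the spike count in
#' the 50--500 ms post-cue window on the approach-vigor covariates:
#' ln E[Y] = b0 + b1 x1 + ... + bm xm. Trials from all units of a population
#' are pooled without per-unit intercepts (the population-level reading; a
#' per-unit offset variant is available via `unit` for sensitivity checks but
#' off by default). Covariates are entered in natural units; set
#' `standardize = TRUE` to z-scale them (recorded in the fit).
#'
#' @param counts Integer spike counts, one per responded CS+ trial.
#' @param covariates Data frame of numeric covariates (one row per trial).
#' @param population Label carried into the fit.
#' @param standardize Z-scale covariates before fitting.
#' @param unit Optional factor of unit identities; adds per-unit intercept
#'   offsets.
#' @return A `glm_fit`: `coefficients`, `covariate_names`,
#'   `residual_deviance`, `residual_df`, `n_trials`, `vcov`, `population`,
#'   `standardize`, `scale_center`/`scale_sd` when standardized.
#' @export
fit_count_glm <- function(counts, covariates, population = NA_character_,
                          standardize = FALSE, unit = NULL) {
  covariates <- as.data.frame(covariates)
  if (any(!vapply(covariates, is.numeric, logical(1))))
    stop("covariates must be numeric")
  if (any(!is.finite(as.matrix(covariates)))) stop("non-finite covariates")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  if (length(counts) < ncol(covariates) + 2)
    stop("too few trials for the number of covariates")
  const <- if (ncol(covariates))
    vapply(covariates, function(x) stats::var(x) == 0, logical(1)) else logical(0)
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const],
                                          collapse = ", "))
  center <- sds <- NULL
  if (standardize) {
    center <- vapply(covariates, mean, numeric(1))
    sds <- vapply(covariates, stats::sd, numeric(1))
    covariates <- as.data.frame(scale(covariates))
  }
  df <- data.frame(.count = counts)
  for (nm in names(covariates)) df[[nm]] <- covariates[[nm]]
  form <- if (is.null(unit)) stats::as.formula(".count ~ .")
    else { df$.unit <- factor(unit); stats::as.formula(".count ~ .") }
  fit <- stats::glm(form, family = stats::poisson(), data = df)
  structure(list(coefficients = stats::coef(fit),
                 covariate_names = names(covariates),
                 residual_deviance = fit$deviance,
                 residual_df = fit$df.residual,
                 pearson_ss = sum(stats::residuals(fit, "pearson")^2),
                 n_trials = length(counts),
                 vcov = stats::vcov(fit),
                 fitted = stats::fitted(fit),
                 population = population, standardize = standardize,
                 scale_center = center, scale_sd = sds),
            class = "glm_fit")
}

#' Predict trial counts from a fitted population GLM
#'
#' Modeled count per trial: exp(b0 + sum bi xi) with the coefficients of one
#' population's fit applied to another population's covariates — the
#' cross-population prediction behind the modeled-versus-actual comparison.
#'
#' @param fit A `glm_fit`.
#' @param covariates Data frame whose columns match the fit's covariates.
#' @return Numeric vector of modeled counts.
#' @export
cross_predict <- function(fit, covariates) {
  covariates <- as.data.frame(covariates)
  if (!setequal(fit$covariate_names, names(covariates)))
    stop("covariate names do not match the fit: expected ",
         paste(fit$covariate_names, collapse = ", "))
  x <- as.matrix(covariates[, fit$covariate_names, drop = FALSE])
  if (fit$standardize)
    x <- sweep(sweep(x, 2, fit$scale_center), 2, fit$scale_sd, "/")
  eta <- fit$coefficients[1] + drop(x %*% fit$coefficients[fit$covariate_names])
  unname(exp(eta))
}

#' Rank-sum comparison of modeled versus actual counts
#'
#' @param modeled Modeled counts (from [cross_predict()]).
#' @param actual Observed counts.
#' @return List with `p_value`, `statistic` (Wilcoxon rank-sum W),
#'   `median_modeled`, `median_actual`.
#' @export
compare_modeled_vs_actual <- function(modeled, actual) {
  w <- suppressWarnings(stats::wilcox.test(modeled, actual))
  list(p_value = w$p.value, statistic = unname(w$statistic),
       median_modeled = stats::median(modeled),
       median_actual = stats::median(actual))
}

#' Population-equivalence F test on residual deviances
#'
#' Tests whether k separately fitted population GLMs model one overall
#' population, by comparing the residual deviance of a combined fit (SSt)
#' with the pooled residual deviance of the per-population fits (SSp):
#' F = ((SSt - SSp) / ((m+1)(k-1))) / (SSp / DFp), referred to an F
#' distribution with ((m+1)(k-1), DFp) degrees of freedom, where m is the
#' number of covariates and DFp the pooled residual df. p > 0.05 is read as
#' "the populations are interchangeable". `deviance = "pearson"` substitutes
#' squared Pearson residual sums.
#'
#' @param fits List of k `glm_fit`s (identical covariate sets).
#' @param combined_fit `glm_fit` on the union of the k populations' trials.
#' @param deviance `"deviance"` (default) or `"pearson"`.
#' @return A `population_comparison`: `F`, `df_num`, `df_den`, `p_value`,
#'   `SSt`, `SSp`, `k`, `m`.
#' @export
population_equivalence_f <- function(fits, combined_fit,
                                     deviance = c("deviance", "pearson")) {
  deviance <- match.arg(deviance)
  k <- length(fits)
  if (k < 2) stop("need at least 2 population fits")
  m <- length(fits[[1]]$covariate_names)
  if (!all(vapply(fits, function(f)
    setequal(f$covariate_names, combined_fit$covariate_names) &&
      length(f$covariate_names) == m, logical(1))))
    stop("covariate sets differ across fits")
  ss <- function(f) if (deviance == "deviance") f$residual_deviance else
    f$pearson_ss
  sst <- ss(combined_fit)
  ssp <- sum(vapply(fits, ss, numeric(1)))
  if (ssp <= 0) stop("pooled residual deviance is zero; F undefined")
  dfp <- sum(vapply(fits, function(f) f$residual_df, numeric(1)))
  df_num <- (m + 1) * (k - 1)
  f_stat <- ((sst - ssp) / df_num) / (ssp / dfp)
  structure(list(F = f_stat, df_num = df_num, df_den = dfp,
                 p_value = stats::pf(f_stat, df_num, dfp, lower.tail = FALSE),
                 SSt = sst, SSp = ssp, k = k, m = m),
            class = "population_comparison")
}

# lean Poisson fit for the bootstrap inner loop
glm_fit_lean <- function(y, x) {
  f <- stats::glm.fit(cbind(1, x), y, family = stats::poisson())
  list(residual_deviance = f$deviance, residual_df = length(y) - ncol(x) - 1,
       covariate_names = colnames(x))
}

#' Split-half bootstrap adequacy check of a population GLM
#'
#' The model-adequacy procedure: repeatedly split the population's responded
#' CS+ trials 50/50 at random, fit the count GLM to each half, and test the
#' two half-fits against the full fit with the population-equivalence F
#' statistic. If the single-GLM description is adequate, the p-value exceeds
#' 0.05 on about 95% of permutations.
#'
#' @param counts,covariates As in [fit_count_glm()].
#' @param n_permutations Number of random splits (default 1000).
#' @param seed Integer seed.
#' @return A `bootstrap_report`: `pass_fraction`, `p_values`,
#'   `n_permutations`, `n_skipped` (singular splits), `seed`.
#' @export
bootstrap_adequacy <- function(counts, covariates, n_permutations = 1000,
                               seed = 1) {
  covariates <- as.data.frame(covariates)
  x <- as.matrix(covariates)
  n <- length(counts)
  if (n < 2 * (ncol(x) + 2)) stop("too few trials for split-half fitting")
  full <- glm_fit_lean(counts, x)
  m <- ncol(x)
  set.seed(seed)
  p_values <- rep(NA_real_, n_permutations)
  n_skipped <- 0L
  half <- floor(n / 2)
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(n, half)
    ok <- tryCatch({
      f1 <- glm_fit_lean(counts[idx], x[idx, , drop = FALSE])
      f2 <- glm_fit_lean(counts[-idx], x[-idx, , drop = FALSE])
      sst <- full$residual_deviance
      ssp <- f1$residual_deviance + f2$residual_deviance
      dfp <- f1$residual_df + f2$residual_df
      df_num <- (m + 1) * (2 - 1)
      f_stat <- ((sst - ssp) / df_num) / (ssp / dfp)
      p_values[i] <- stats::pf(f_stat, df_num, dfp, lower.tail = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) n_skipped <- n_skipped + 1L
  }
  if (n_skipped > 0)
    warning(n_skipped, " permutation(s) skipped due to singular designs")
  done <- !is.na(p_values)
  structure(list(pass_fraction = mean(p_values[done] > 0.05),
                 p_values = p_values, n_permutations = n_permutations,
                 n_skipped = n_skipped, seed = seed),
            class = "bootstrap_report")
}

#' Logistic regression of next-trial responding on consumption firing
#'
#' Does the spike count 1--3 s after the rewarded entry on trial t predict
#' whether the animal responds on trial t+1? Fits a logistic regression of
#' the next-trial response flag on the consumption count and reports the
#' Wald test on the slope. Complete separation is flagged instead of
#' reporting a spurious estimate.
#'
#' @param consumption_counts Spike counts in `[1, 3)` s after the rewarded
#'   entry, one per rewarded trial t (last trial excluded upstream or here).
#' @param next_responded Logical response flag of trial t+1 (same length).
#' @return List with `coefficient`, `se`, `wald_p`, `separation` flag, `n`.
#' @export
next_trial_logistic <- function(consumption_counts, next_responded) {
  stopifnot(length(consumption_counts) == length(next_responded))
  n <- length(consumption_counts)
  if (n < 10) stop("need at least 10 (t, t+1) pairs")
  y <- as.integer(next_responded)
  if (all(y == 1) || all(y == 0))
    return(list(coefficient = NA_real_, se = NA_real_, wald_p = NA_real_,
                separation = TRUE, n = n))
  fit <- suppressWarnings(stats::glm(y ~ consumption_counts,
                                     family = stats::binomial()))
  sm <- summary(fit)$coefficients
  sep <- !fit$converged || abs(sm[2, 1]) > 15
  list(coefficient = sm[2, 1], se = sm[2, 2],
       wald_p = if (sep) NA_real_ else sm[2, 4], separation = sep, n = n)
}

#' Pre- versus post-injection baseline-rate slope test
#'
#' Regresses each unit's post-injection baseline firing rate on its
#' pre-injection rate and builds a 95% confidence interval around the slope;
#' a population-wide rate change is declared only when the interval excludes
#' 1 (the no-change slope).
#'
#' @param pre_rates,post_rates Baseline rates (Hz), one pair per unit.
#' @return List with `slope`, `ci95` (length 2), `significant`, `n_units`.
#' @export
baseline_slope_test <- function(pre_rates, post_rates) {
  stopifnot(length(pre_rates) == length(post_rates))
  if (length(pre_rates) < 3) stop("need at least 3 units")
  if (any(pre_rates < 0) || any(post_rates < 0)) stop("rates must be >= 0")
  if (stats::var(pre_rates) == 0) stop("zero variance in pre-injection rates")
  fit <- suppressWarnings(stats::lm(post_rates ~ pre_rates))
  ci <- suppressWarnings(stats::confint(fit, "pre_rates", level = 0.95))
  # tolerance keeps an exactly-degenerate fit (post == pre) non-significant
  list(slope = unname(stats::coef(fit)["pre_rates"]),
       ci95 = as.numeric(ci),
       significant = isTRUE(ci[1] > 1 + 1e-8) || isTRUE(ci[2] < 1 - 1e-8),
       n_units = length(pre_rates))
}
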