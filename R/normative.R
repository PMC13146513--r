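#' Stratify subjects at the 24-month boundary
#'
#' @param subjects data.frame with an `age_months` column (all > 0).
#' @return The same data.frame with a `group` column: `"young"` for
#'   age < 24 months, `"old"` for age >= 24 months (the boundary itself
#'   is old).
#' @examples
#' stratify(data.frame(age_months = c(5.5, 24, 91)))
#' @export
stratify <- function(subjects) {
  if (!all(subjects$age_months > 0)) {
    stop("ages must be positive", call. = FALSE)
  }
  subjects$group <- ifelse(subjects$age_months < 24, "young", "old")
  subjects
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the spreadsheet convention), so reported
#' IQRs are reproducible.
#'
#' @param values Numeric vector, length >= 1, finite.
#' @return Named numeric: `median`, `iqr_low` (25th), `iqr_high` (75th).
#' @examples
#' summarize_hu(1:5)
#' @export
summarize_hu <- function(values) {
  if (!length(values)) stop("no values to summarize", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], iqr_low = q[1], iqr_high = q[3])
}

#' Normality-gated two-group comparison with Bonferroni correction
#'
#' Each group is tested for normality (Shapiro-Wilk at alpha = 0.05);
#' if both pass, an unpaired Welch t-test is used, otherwise the
#' two-sided Mann-Whitney U test. The raw p-value is Bonferroni-adjusted
#' by `family_size` and capped at 1.
#'
#' @param x,y Numeric vectors for the two groups (each n >= 3).
#' @param family_size Number of comparisons in the family (>= 1).
#' @param variable Optional label carried into the result.
#' @return data.frame (one row): `variable`, `n_young`, `n_old`,
#'   `median_young`, `iqr_low_young`, `iqr_high_young`, `median_old`,
#'   `iqr_low_old`, `iqr_high_old`, `test_used`, `p_raw`, `p_adjusted`.
#' @export
compare_groups <- function(x, y, family_size = 1, variable = NA_character_) {
  if (length(x) < 3 || length(y) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  if (family_size < 1) stop("'family_size' must be >= 1", call. = FALSE)
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)  # degenerate: gate to rank test
    stats::shapiro.test(v)$p.value > 0.05
  }
  use_t <- normal(x) && normal(y)
  p_raw <- if (use_t) {
    stats::t.test(x, y, var.equal = FALSE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$p.value
  }
  sx <- summarize_hu(x); sy <- summarize_hu(y)
  data.frame(variable = variable, n_young = length(x), n_old = length(y),
             median_young = sx[["median"]], iqr_low_young = sx[["iqr_low"]],
             iqr_high_young = sx[["iqr_high"]],
             median_old = sy[["median"]], iqr_low_old = sy[["iqr_low"]],
             iqr_high_old = sy[["iqr_high"]],
             test_used = if (use_t) "t_test" else "mann_whitney",
             p_raw = p_raw,
             p_adjusted = min(1, p_raw * family_size),
             family_size = as.integer(family_size),
             stringsAsFactors = FALSE)
}

curve_fit_obj <- function(form, a, b, intercept, r2, n) {
  structure(list(form = form, a = a, b = b, intercept = intercept,
                 r_squared = r2, n = n), class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  eq <- if (x$form == "power") {
    sprintf("y = %.4g * x^%.4g", x$a, x$b)
  } else {
    sprintf("y = %.4g * x + %.4g", x$b, x$intercept)
  }
  cat(sprintf("%s fit (n = %d): %s, R^2 = %.4f\n", x$form, x$n, eq,
              x$r_squared))
  invisible(x)
}

#' Fit a power-law age-response curve by log-log least squares
#'
#' Fits `y = a * x^b` by ordinary least squares of `log(y)` on `log(x)`
#' (the spreadsheet trendline method): `a = exp(intercept)`, `b = slope`,
#' with the coefficient of determination reported on the log-log scale.
#' A zero-variance response returns `b = 0` and an R-squared of 0, with
#' a warning.
#'
#' @param ages_months Ages in months, all > 0, n >= 3.
#' @param values Response values, all > 0.
#' @return A `curve_fit` (`form = "power"`).
#' @examples
#' x <- 1:216
#' fit_power_curve(x, 26.424 * x^0.025)
#' @export
fit_power_curve <- function(ages_months, values) {
  if (length(ages_months) != length(values) || length(values) < 3) {
    stop("need matched vectors with n >= 3", call. = FALSE)
  }
  if (any(ages_months <= 0) || any(values <= 0)) {
    stop("power-law fitting requires positive ages and values",
         call. = FALSE)
  }
  lx <- log(ages_months); ly <- log(values)
  if (stats::var(ly) == 0) {
    warning("zero-variance response; R^2 defined as 0", call. = FALSE)
    return(curve_fit_obj("power", values[1], 0, NA_real_, 0,
                         length(values)))
  }
  fit <- stats::lm(ly ~ lx)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  curve_fit_obj("power", exp(unname(stats::coef(fit)[1])),
                unname(stats::coef(fit)[2]), NA_real_, r2,
                length(values))
}

#' Fit a linear age-response curve
#'
#' Ordinary least squares of `values` on `ages_months` on the original
#' scale.
#'
#' @inheritParams fit_power_curve
#' @return A `curve_fit` (`form = "linear"`).
#' @export
fit_linear <- function(ages_months, values) {
  if (length(ages_months) != length(values) || length(values) < 3) {
    stop("need matched vectors with n >= 3", call. = FALSE)
  }
  if (stats::var(ages_months) == 0) {
    stop("all ages identical; slope undefined", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    warning("zero-variance response; R^2 defined as 0", call. = FALSE)
    return(curve_fit_obj("linear", NA_real_, 0, values[1], 0,
                         length(values)))
  }
  fit <- stats::lm(values ~ ages_months)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((values - mean(values))^2)
  curve_fit_obj("linear", NA_real_, unname(stats::coef(fit)[2]),
                unname(stats::coef(fit)[1]), r2, length(values))
}

#' Analytic voxel-noise calibration against a target R-squared
#'
#' For a power-law region sampled at given ages, returns the additive
#' Gaussian HU noise SD for which the expected coefficient of
#' determination of the log-log fit is approximately `target_r2`:
#' the log-scale signal SD is `|b| * sd(log(ages))`, the required
#' log-scale noise SD is `signal * sqrt((1 - R2)/R2)`, and the HU-scale
#' SD rescales by the mean curve level.
#'
#' @param region Power-form region name (see [age_curve_registry()]).
#' @param ages_months Ages at which subjects will be sampled.
#' @param target_r2 Target coefficient of determination in (0, 1).
#' @return Noise SD in HU.
#' @export
calibrate_noise_for_r2 <- function(region, ages_months, target_r2) {
  if (target_r2 <= 0 || target_r2 >= 1) {
    stop("'target_r2' must be in (0, 1)", call. = FALSE)
  }
  reg <- age_curve_registry()
  i <- match(region, reg$region)
  if (is.na(i) || reg$form[i] != "power") {
    stop("'", region, "' is not a registered power-form region",
         call. = FALSE)
  }
  sd_log_signal <- abs(reg$b[i]) * stats::sd(log(ages_months))
  sd_log_noise <- sd_log_signal * sqrt((1 - target_r2) / target_r2)
  sd_log_noise * mean(regional_mean_curve(region, ages_months))
}

#' Exponent-recovery simulation for a power-law region
#'
#' Generates seeded synthetic cohorts (ages uniform on `age_range`
#' months, HU = normative curve value + Gaussian noise calibrated so the
#' log-log fit attains roughly the region's reported R-squared), fits
#' each with [fit_power_curve()], and returns the recovered exponents.
#'
#' @param region Power-form region name.
#' @param n Subjects per cohort.
#' @param n_seeds Number of independent cohorts.
#' @param seed Base seed; cohort i uses a seed derived from it.
#' @param target_r2 Target R-squared for noise calibration (defaults to
#'   the region's registered value).
#' @param age_range Age interval in months.
#' @return List: `exponents` (length `n_seeds`), `mean_exponent`,
#'   `true_exponent`, `mean_r_squared`, `noise_sd`.
#' @examples
#' recover_power_exponent("parenchyma_SL1", n = 200, n_seeds = 5)$mean_exponent
#' @export
recover_power_exponent <- function(region, n = 500, n_seeds = 20, seed = 1L,
                                   target_r2 = NULL,
                                   age_range = c(1, 216)) {
  reg <- age_curve_registry()
  i <- match(region, reg$region)
  if (is.na(i) || reg$form[i] != "power") {
    stop("'", region, "' is not a registered power-form region",
         call. = FALSE)
  }
  if (is.null(target_r2)) target_r2 <- reg$r_squared[i]
  exps <- numeric(n_seeds)
  r2s <- numeric(n_seeds)
  noise_sd <- NA_real_
  for (s in seq_len(n_seeds)) {
    set.seed(subseed(seed, s))
    ages <- stats::runif(n, age_range[1], age_range[2])
    noise_sd <- calibrate_noise_for_r2(region, ages, target_r2)
    y <- regional_mean_curve(region, ages) + stats::rnorm(n, 0, noise_sd)
    fit <- fit_power_curve(ages, y)
    exps[s] <- fit$b
    r2s[s] <- fit$r_squared
  }
  list(exponents = exps, mean_exponent = mean(exps),
       true_exponent = reg$b[i], mean_r_squared = mean(r2s),
       noise_sd = noise_sd)
}
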