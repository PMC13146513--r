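test_that("stratification is exhaustive, disjoint and deterministic at 24 months", {
  s <- stratify(data.frame(age_months = c(5.5, 23.999, 24, 91)))
  expect_identical(s$group, c("young", "young", "old", "old"))
  co <- fix_cohort()
  s2 <- stratify(co$subjects)
  expect_equal(sum(s2$group == "young") + sum(s2$group == "old"), 42)
  expect_identical(s2$group, co$subjects$group)
  expect_error(stratify(data.frame(age_months = c(-1, 5))), "positive")
})

test_that("median/IQR use interpolated quartiles and match a brute-force oracle", {
  expect_equal(summarize_hu(1:5),
               c(median = 3, iqr_low = 2, iqr_high = 4))
  expect_equal(summarize_hu(7), c(median = 7, iqr_low = 7, iqr_high = 7))
  expect_equal(unname(summarize_hu(rep(2.5, 9))), rep(2.5, 3))

  # oracle: sort-based linear interpolation at h = (n-1)p + 1
  brute_q <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(9)
  for (n in c(2, 3, 7, 12, 20)) {
    x <- rnorm(n, 30, 4)
    s <- summarize_hu(x)
    expect_equal(s[["median"]], brute_q(x, 0.5))
    expect_equal(s[["iqr_low"]], brute_q(x, 0.25))
    expect_equal(s[["iqr_high"]], brute_q(x, 0.75))
  }
})

test_that("group comparison gates on normality and adjusts by the family size", {
  set.seed(21)
  x <- rnorm(18, 27, 1); y <- rnorm(24, 30, 1)
  cmp <- compare_groups(x, y, family_size = 14)
  expect_identical(cmp$test_used, "t_test")
  expect_equal(cmp$p_adjusted, min(1, cmp$p_raw * 14))
  expect_lt(cmp$p_adjusted, 0.05)

  # heavy-tailed data fall through to the rank test
  set.seed(22)
  xs <- exp(rnorm(30, 0, 1.5)); ys <- exp(rnorm(30, 0, 1.5))
  cmp2 <- compare_groups(xs, ys, family_size = 14)
  expect_identical(cmp2$test_used, "mann_whitney")

  # Bonferroni is monotone and capped at 1
  cmp3 <- compare_groups(rnorm(10, 30), rnorm(10, 30), family_size = 14)
  expect_gte(cmp3$p_adjusted, cmp3$p_raw)
  expect_lte(cmp3$p_adjusted, 1)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("null comparisons are non-significant at the nominal rate", {
  set.seed(30)
  rejections <- sum(replicate(40, {
    compare_groups(rnorm(18, 30, 1), rnorm(24, 30, 1),
                   family_size = 14)$p_adjusted < 0.05
  }))
  expect_lte(rejections, 2)
})

test_that("power-law fits recover exact generating parameters", {
  x <- 1:216
  for (r in c("parenchyma_SL1", "GM_SL1", "CN")) {
    reg <- age_curve_registry()
    i <- match(r, reg$region)
    f <- fit_power_curve(x, reg$a[i] * x^reg$b[i])
    expect_equal(f$a, reg$a[i], tolerance = 1e-7)
    expect_equal(f$b, reg$b[i], tolerance = 1e-7)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
  expect_warning(fc <- fit_power_curve(x, rep(27, 216)), "zero-variance")
  expect_equal(fc$b, 0)
  expect_equal(fc$r_squared, 0)
  expect_error(fit_power_curve(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("linear fits recover exact generating parameters", {
  x <- 1:216
  f <- fit_linear(x, -0.0031 * x + 24.26)
  expect_equal(f$b, -0.0031, tolerance = 1e-10)
  expect_equal(f$intercept, 24.26, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_warning(ff <- fit_linear(x, rep(24, 216)), "zero-variance")
  expect_equal(ff$b, 0)
  expect_error(fit_linear(rep(5, 10), rnorm(10)), "identical")
})

test_that("weak linear age effects are recovered within a wide band at n = 42", {
  # deep-WM regime: slope 0.0061, R^2 ~ 0.04
  slope <- 0.0061
  slopes <- vapply(1:20, function(s) {
    set.seed(400 + s)
    ages <- runif(42, 1, 216)
    y <- slope * ages + 23.086 + rnorm(42, 0, 1.8)
    fit_linear(ages, y)$b
  }, numeric(1))
  expect_lt(abs(mean(slopes) - slope), 0.5 * slope + 0.002)
})

test_that("noise calibration hits the requested R-squared on average", {
  set.seed(77)
  ages <- runif(500, 1, 216)
  for (tgt in c(0.38, 0.49)) {
    sd_hu <- calibrate_noise_for_r2("GM_SL1", ages, tgt)
    r2 <- mean(vapply(1:10, function(s) {
      set.seed(s)
      y <- regional_mean_curve("GM_SL1", ages) + rnorm(500, 0, sd_hu)
      fit_power_curve(ages, y)$r_squared
    }, numeric(1)))
    expect_lt(abs(r2 - tgt), 0.06)
  }
  expect_error(calibrate_noise_for_r2("WM_SL1", ages, 0.4), "power-form")
})

test_that("normative report has the expected blocks and family sizes", {
  md <- fix_measured()
  gwr <- compute_all_gwr(md$table)
  rep <- normative_report(md$table, gwr, md$cohort$subjects)
  expect_equal(nrow(rep$hu_summary), 14 + 9)
  expect_equal(unique(rep$hu_summary$family_size[rep$hu_summary$method == "ROI"]), 14L)
  expect_equal(unique(rep$hu_summary$family_size[rep$hu_summary$method == "DOT"]), 9L)
  expect_equal(nrow(rep$gwr_summary), 12)
  expect_equal(unique(rep$gwr_summary$family_size), 12L)
  expect_equal(nrow(rep$curve_fits), 9)
  expect_true(all(rep$hu_summary$p_adjusted >= rep$hu_summary$p_raw))
  expect_true(all(rep$hu_summary$p_adjusted <= 1))
  # medians lie inside their IQRs
  expect_true(all(rep$hu_summary$median_young >= rep$hu_summary$iqr_low_young &
                  rep$hu_summary$median_young <= rep$hu_summary$iqr_high_young))

  one_group <- md$cohort$subjects[md$cohort$subjects$group == "old", ]
  expect_error(normative_report(md$table, gwr, one_group), "strata")
})

test_that("age direction of the synthetic truth matches the normative pattern", {
  # noiseless curve-following cohort: young medians below old for the
  # age-increasing regions, near-flat elsewhere
  co <- sample_cohort(cohort_config(noise_sd_between = 0, seed = 12))
  tr <- merge(co$truth, co$subjects, by = "subject_id")
  med <- function(r, g) {
    v <- tr[tr$region == r & tr$group == g, "true_hu"]
    median(v)
  }
  for (r in c("parenchyma_SL1", "parenchyma_SL2", "CN", "GM_SL1", "GM_SL2")) {
    expect_lt(med(r, "young"), med(r, "old"))
  }
  for (r in c("PT", "TM", "WM_SL1", "WM_SL2")) {
    expect_lt(abs(med(r, "young") - med(r, "old")), 1.5)
  }
})
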