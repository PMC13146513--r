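test_that("bland_altman reproduces the hand-worked example", {
  ba <- bland_altman(c(10, 20, 30), c(11, 19, 33))
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd_diff, 2)
  expect_equal(ba$loa_lower, 1 - 1.96 * 2)
  expect_equal(ba$loa_upper, 1 + 1.96 * 2)
  expect_equal(round(c(ba$loa_lower, ba$loa_upper), 2), c(-2.92, 4.92))
  expect_equal(ba$diff_range, c(-1, 3))
})

test_that("bland_altman equals a naive two-pass oracle on short inputs", {
  set.seed(42)
  for (n in c(2, 3, 5, 10)) {
    a <- rnorm(n, 25, 3); b <- rnorm(n, 25, 3)
    ba <- bland_altman(a, b)
    d <- b - a
    m <- sum(d) / n
    s <- sqrt(sum((d - m)^2) / (n - 1))
    expect_equal(ba$bias, m)
    expect_equal(ba$sd_diff, s)
    expect_equal(ba$loa_lower, m - 1.96 * s)
    expect_equal(ba$loa_upper, m + 1.96 * s)
  }
})

test_that("perfect agreement collapses the limits to the bias", {
  x <- c(12, 15.5, 31)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))
})

test_that("differences are DOT minus ROI: inflating DOT shifts the bias", {
  set.seed(1)
  a <- rnorm(10, 30, 2); b <- a + rnorm(10, 0, 1)
  base <- bland_altman(a, b)
  shifted <- bland_altman(a, b + 2.5)
  expect_equal(shifted$bias, base$bias + 2.5)
  expect_equal(shifted$sd_diff, base$sd_diff)
})

test_that("limits reconstruct from printed bias and SD summaries", {
  expect_equal(round(loa_from_summary(-1.39, 1.27)[1], 2), -3.88)  # putamen
  expect_equal(round(loa_from_summary(-0.76, 1.37)[2], 2), 1.93)   # thalamus
  expect_equal(round(loa_from_summary(7.98, 2.98)[1], 2), 2.14)    # vent SL1
  expect_equal(round(loa_from_summary(4.85, 2.87)[1], 2), -0.78)   # vent SL2
  expect_equal(loa_from_summary(0, 1), c(-1.96, 1.96))
  expect_error(loa_from_summary(1, -0.2), "non-negative")
})

test_that("ICC matches an aov mean-squares oracle and its invariances", {
  m <- cbind(c(1, 3, 5), c(2, 4, 6))
  got <- icc_single_rater(m)

  # oracle: mean squares from base aov on the long-format two-way layout
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:3, 2)),
                     sess = factor(rep(1:2, each = 3)))
  ms <- summary(stats::aov(y ~ subj + sess, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2; n <- 3
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got, oracle)
  expect_equal(got, 8 / 9)  # hand arithmetic for this matrix

  # identical sessions -> perfect agreement
  expect_equal(icc_single_rater(cbind(c(1, 2, 7), c(1, 2, 7))), 1)

  # invariant to common shifts and positive rescaling
  set.seed(5)
  r <- matrix(rnorm(20, 30, 3), 10, 2)
  base <- icc_single_rater(r)
  expect_equal(icc_single_rater(r + 100), base)
  expect_equal(icc_single_rater(r * 7), base)

  expect_error(icc_single_rater(matrix(1, 3, 2)), "no variance")
  expect_error(icc_single_rater(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("a session offset penalizes absolute agreement but not consistency", {
  set.seed(6)
  subj <- rnorm(15, 30, 3)
  r <- cbind(subj + rnorm(15, 0, 0.5), subj + rnorm(15, 0, 0.5))
  shifted <- r
  shifted[, 2] <- shifted[, 2] + 2  # systematic offset between sessions
  expect_equal(icc_single_rater(shifted, type = "ICC3"),
               icc_single_rater(r, type = "ICC3"))
  expect_lt(icc_single_rater(shifted, type = "ICC2"),
            icc_single_rater(r, type = "ICC2"))
})

test_that("simulated re-reads select ceil(fraction * n) subjects, reproducibly", {
  md <- fix_measured()
  co42 <- fix_cohort()
  tab42 <- hu_table_from_truth(co42, "DOT")
  m <- simulate_rereads(tab42, fraction = 0.1, seed = 4)
  expect_length(attr(m, "subjects"), 5)  # ceiling(0.1 * 42)
  m2 <- simulate_rereads(tab42, fraction = 0.1, seed = 4)
  expect_identical(m, m2)
  expect_error(simulate_rereads(tab42, fraction = 0), "fraction")

  # zero re-read noise reproduces session one exactly -> ICC 1
  m0 <- simulate_rereads(md$table, fraction = 0.5, reread_noise_sd = 0,
                         seed = 2)
  expect_identical(m0[, 1], m0[, 2])
  expect_equal(icc_single_rater(m0), 1)
})

test_that("small re-read noise keeps intra-rater ICC in the excellent range", {
  md <- fix_measured()
  for (sl in c("SL1", "SL2")) {
    m <- simulate_rereads(md$table, fraction = 0.5, reread_noise_sd = 0.5,
                          seed = 8, slice = sl)
    expect_gte(icc_single_rater(m), 0.9)
  }
})

test_that("agreement_table summarizes both methods per region", {
  md <- fix_measured()
  agr <- agreement_table(md$table)
  expect_true(all(c("CN", "PT", "TM", "ventricle_SL1", "GM_SL1") %in%
                  agr$region))
  expect_equal(agr$loa_lower, agr$bias - 1.96 * agr$sd)
  expect_equal(agr$loa_upper, agr$bias + 1.96 * agr$sd)
  expect_true(all(agr$n == nrow(md$cohort$subjects)))
  # synthetic phantoms have no systematic ROI/DOT offset
  expect_true(all(abs(agr$bias) < 1))
  roi_only <- md$table[md$table$method == "ROI", ]
  expect_error(agreement_table(roi_only), "both ROI and DOT")
})
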