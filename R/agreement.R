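#' Bland-Altman agreement between two measurement methods
#'
#' Summarizes paired measurements of the same quantity by two methods
#' (here segmented-ROI and circular-DOT) through the per-pair
#' differences: systematic bias (mean difference), the sample SD of the
#' differences (n - 1 denominator), and the 95% limits of agreement at
#' bias +/- 1.96 SD. Differences are taken as `values_b - values_a`,
#' i.e. DOT minus ROI when called with ROI first.
#'
#' @param values_a,values_b Paired HU vectors (method A = ROI, method B
#'   = DOT); equal length >= 2, finite.
#' @param region Optional region label carried into the result.
#' @return Object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `diff_range`, `n`, `means`, `diffs`,
#'   `region`.
#' @examples
#' bland_altman(c(10, 20, 30), c(11, 19, 33))
#' @export
bland_altman <- function(values_a, values_b, region = NA_character_) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(values_a) < 2) {
    stop("at least 2 pairs are required", call. = FALSE)
  }
  if (!all(is.finite(values_a)) || !all(is.finite(values_b))) {
    stop("values must be finite", call. = FALSE)
  }
  d <- values_b - values_a
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa <- loa_from_summary(bias, sd_diff)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_lower = loa[1], loa_upper = loa[2],
                 diff_range = range(d), n = length(d),
                 means = (values_a + values_b) / 2, diffs = d,
                 region = region),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman%s: bias %.2f HU, SD %.2f, LoA [%.2f, %.2f], n = %d\n",
              if (is.na(x$region)) "" else paste0(" (", x$region, ")"),
              x$bias, x$sd_diff, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Limits of agreement from a printed bias and SD
#'
#' @param bias Mean difference (HU).
#' @param sd_diff SD of the differences (HU, >= 0).
#' @return Numeric `(lower, upper)` = bias -/+ 1.96 * sd_diff.
#' @examples
#' loa_from_summary(-1.39, 1.27)
#' @export
loa_from_summary <- function(bias, sd_diff) {
  if (!is.finite(sd_diff) || sd_diff < 0) {
    stop("'sd_diff' must be a non-negative number", call. = FALSE)
  }
  c(bias - 1.96 * sd_diff, bias + 1.96 * sd_diff)
}

#' Per-region Bland-Altman table for a two-method measurement table
#'
#' @param table Tidy measurement data.frame containing both `ROI` and
#'   `DOT` rows.
#' @param regions Regions to compare (default: all regions present under
#'   both methods).
#' @return data.frame `region, bias, sd, loa_lower, loa_upper, diff_min,
#'   diff_max, n`.
#' @export
agreement_table <- function(table, regions = NULL) {
  roi <- table[table$method == "ROI", ]
  dot <- table[table$method == "DOT", ]
  if (!nrow(roi) || !nrow(dot)) {
    stop("table must contain both ROI and DOT rows", call. = FALSE)
  }
  if (is.null(regions)) {
    regions <- intersect(unique(roi$region), unique(dot$region))
  }
  rows <- lapply(regions, function(r) {
    a <- roi[roi$region == r, ]
    b <- dot[dot$region == r, ]
    ids <- intersect(a$subject_id, b$subject_id)
    ba <- bland_altman(a$hu[match(ids, a$subject_id)],
                       b$hu[match(ids, b$subject_id)], region = r)
    data.frame(region = r, bias = ba$bias, sd = ba$sd_diff,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
               diff_min = ba$diff_range[1], diff_max = ba$diff_range[2],
               n = ba$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Intraclass correlation for repeated single-rater measurements
#'
#' Computes the single-measurement intraclass correlation from the
#' two-way ANOVA mean squares of a complete subjects-by-sessions matrix.
#' The default `"ICC2"` is the two-way random-effects, absolute-agreement
#' form ICC(2,1), the conventional choice for intra-rater re-reads;
#' `"ICC3"` gives the two-way mixed, consistency form ICC(3,1).
#'
#' @param ratings Numeric matrix, subjects in rows (>= 2), sessions in
#'   columns (>= 2), no missing values.
#' @param type `"ICC2"` or `"ICC3"`.
#' @return ICC estimate in \[-1, 1\].
#' @examples
#' icc_single_rater(cbind(c(1, 3, 5), c(2, 4, 6)))
#' @export
icc_single_rater <- function(ratings, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) {
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  }
  gm <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- switch(type,
                  ICC2 = msr + (k - 1) * mse + k * (msc - mse) / n,
                  ICC3 = msr + (k - 1) * mse)
  if (denom <= 0) {
    stop("ratings have no variance; ICC undefined", call. = FALSE)
  }
  (msr - mse) / denom
}

#' Simulate an intra-rater re-read of part of a cohort
#'
#' Emulates the protocol of re-reading a random 10% of scans: selects
#' `ceiling(fraction * n)` subjects and models the second read of every
#' stored measurement as the original value plus independent Gaussian
#' re-read noise. Rows of the returned matrix are subject-region
#' measurements for the given slice and method; columns are the two
#' sessions.
#'
#' @param table Tidy measurement data.frame (one cohort).
#' @param fraction Fraction of subjects to re-read, in (0, 1].
#' @param reread_noise_sd SD (HU) of the re-read perturbation.
#' @param seed Integer seed (selection and noise).
#' @param slice Slice whose measurements enter the matrix.
#' @param method Measurement method to re-read.
#' @return Numeric matrix with columns `session1`, `session2`; attribute
#'   `subjects` lists the selected ids.
#' @export
simulate_rereads <- function(table, fraction = 0.1, reread_noise_sd = 0.5,
                             seed = 1L, slice = "SL1", method = "DOT") {
  if (fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  sub <- table[table$method == method & table$slice == slice, ]
  ids <- unique(sub$subject_id)
  if (!length(ids)) stop("no measurements to re-read", call. = FALSE)
  n_sel <- ceiling(fraction * length(ids))
  set.seed(as.integer(seed))
  sel <- sort(sample(ids, n_sel))
  sub <- sub[sub$subject_id %in% sel, ]
  m <- cbind(session1 = sub$hu,
             session2 = sub$hu + stats::rnorm(nrow(sub), 0, reread_noise_sd))
  rownames(m) <- paste(sub$subject_id, sub$region, sep = ":")
  attr(m, "subjects") <- sel
  m
}

#' Bland-Altman plot (difference vs pairwise mean)
#'
#' Scatter of DOT - ROI differences against pairwise means, with the
#' bias line (solid) and the 1.96-SD limits of agreement (dashed).
#' Requires ggplot2.
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bland_altman() requires the ggplot2 package", call. = FALSE)
  }
  df <- data.frame(pair_mean = ba$means, pair_diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = pair_mean, y = pair_diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of ROI and DOT (HU)",
                  y = "DOT - ROI difference (HU)",
                  title = if (is.na(ba$region)) NULL else ba$region) +
    ggplot2::theme_minimal()
}
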