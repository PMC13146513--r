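#' Configuration for synthetic normative cohorts
#'
#' Defines the composition and noise structure of a synthetic cohort of
#' pediatric normal controls. Defaults emulate a 42-scan normative sample:
#' 18 subjects under 2 years (24 months) and 24 subjects aged 2--18 years,
#' with the age distribution right-skewed toward infancy (young-group
#' median near 5.5 months, old-group median near 91 months).
#'
#' @param n_young Number of subjects with age < 24 months.
#' @param n_old Number of subjects with age >= 24 months.
#' @param age_range_young,age_range_old Closed age intervals in months for
#'   the two strata; must not straddle the 24-month boundary.
#' @param noise_sd_between Between-subject SD (HU) of regional true means
#'   around the normative age curves.
#' @param noise_sd_voxel Voxel-level Gaussian noise SD (HU) used when
#'   rendering phantoms.
#' @param lobe_gm_weight Gray-matter weight of the lobar GM/WM mixture.
#' @param seed Integer seed for the cohort's pseudo-random stream.
#' @return A list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cohort <- sample_cohort(cfg)
#' table(cohort$subjects$group)
#' @export
cohort_config <- function(n_young = 18, n_old = 24,
                          age_range_young = c(1, 23.99),
                          age_range_old = c(24, 216),
                          noise_sd_between = 1, noise_sd_voxel = 3,
                          lobe_gm_weight = 0.6, seed = 1L) {
  stopifnot(n_young >= 0, n_old >= 0,
            length(age_range_young) == 2, length(age_range_old) == 2,
            noise_sd_between >= 0, noise_sd_voxel >= 0)
  if (any(age_range_young <= 0) || any(age_range_old <= 0) ||
      diff(age_range_young) <= 0 || diff(age_range_old) <= 0) {
    stop("age ranges must be positive, increasing intervals", call. = FALSE)
  }
  if (age_range_young[2] >= 24 || age_range_old[1] < 24) {
    stop("age ranges must be disjoint at the 24-month boundary", call. = FALSE)
  }
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 age_range_young = as.numeric(age_range_young),
                 age_range_old = as.numeric(age_range_old),
                 noise_sd_between = noise_sd_between,
                 noise_sd_voxel = noise_sd_voxel,
                 lobe_gm_weight = lobe_gm_weight,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated log-normal draw: resample until inside [lo, hi]
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# regions that carry their own true mean (everything rendered; the derived
# generic WM_SL1 is the mean of its two subregions)
truth_regions <- function() {
  reg <- region_registry()
  reg$region[!reg$derived]
}

#' Sample a synthetic normative cohort
#'
#' Draws ages for each stratum from truncated log-normal distributions
#' (young median ~5.5 months, IQR ~3--10; old median ~91 months, IQR
#' ~48--148), then sets each subject's per-region true mean HU to the
#' normative age curve value plus an independent between-subject Gaussian
#' deviation. The same seed always reproduces the same cohort.
#'
#' @param config A [cohort_config()].
#' @return A list of class `gwr_cohort` with elements `subjects`
#'   (data.frame: `subject_id`, `age_months`, `group`), `truth` (long
#'   data.frame: `subject_id`, `region`, `true_hu`, including the derived
#'   `WM_SL1` = mean of its anterior/posterior subregions), and `config`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  ages_y <- if (config$n_young > 0) {
    rlnorm_trunc(config$n_young, log(5.5), 0.875,
                 config$age_range_young[1], config$age_range_young[2])
  } else numeric(0)
  ages_o <- if (config$n_old > 0) {
    rlnorm_trunc(config$n_old, log(91), 0.84,
                 config$age_range_old[1], config$age_range_old[2])
  } else numeric(0)

  n <- config$n_young + config$n_old
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age_months = c(ages_y, ages_o),
    group = rep(c("young", "old"), c(config$n_young, config$n_old)),
    stringsAsFactors = FALSE)

  regions <- truth_regions()
  truth <- expand.grid(subject_id = subjects$subject_id, region = regions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- truth[order(match(truth$subject_id, subjects$subject_id)), ]
  truth$age_months <- subjects$age_months[match(truth$subject_id,
                                                subjects$subject_id)]
  base <- numeric(nrow(truth))
  for (r in regions) {
    idx <- truth$region == r
    base[idx] <- regional_mean_curve(r, truth$age_months[idx],
                                     config$lobe_gm_weight)
  }
  truth$true_hu <- base + stats::rnorm(nrow(truth), 0, config$noise_sd_between)
  truth$age_months <- NULL

  # generic WM_SL1 truth is defined as the mean of its two probe sites
  wm <- truth[truth$region %in% c("WM_SL1_anterior", "WM_SL1_posterior"), ]
  wm_mean <- tapply(wm$true_hu, wm$subject_id, mean)
  truth <- rbind(truth, data.frame(subject_id = names(wm_mean),
                                   region = "WM_SL1",
                                   true_hu = as.numeric(wm_mean),
                                   stringsAsFactors = FALSE))
  rownames(truth) <- NULL

  structure(list(subjects = subjects, truth = truth, config = config),
            class = "gwr_cohort")
}

#' @export
print.gwr_cohort <- function(x, ...) {
  cat("Synthetic normative cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "young"), "aged <24 mo,",
      sum(x$subjects$group == "old"), "aged >=24 mo ), seed",
      x$config$seed, "\n")
  invisible(x)
}

#' True regional means for one subject
#'
#' @param cohort A `gwr_cohort`.
#' @param subject_id Subject id.
#' @return Named numeric vector, region -> true mean HU.
#' @export
subject_truth <- function(cohort, subject_id) {
  t <- cohort$truth[cohort$truth$subject_id == subject_id, ]
  if (!nrow(t)) stop("unknown subject '", subject_id, "'", call. = FALSE)
  stats::setNames(t$true_hu, t$region)
}
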