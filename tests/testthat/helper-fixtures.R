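# shared fixtures, built once per test run
.fix <- new.env(parent = emptyenv())

fix_cohort <- function() {
  if (is.null(.fix$cohort)) {
    .fix$cohort <- sample_cohort(cohort_config(seed = 101))
  }
  .fix$cohort
}

# noiseless phantom pair for the first fixture subject
fix_phantoms <- function() {
  if (is.null(.fix$phantoms)) {
    tr <- subject_truth(fix_cohort(), "S001")
    .fix$phantoms <- list(
      SL1 = render_phantom(tr, "SL1", subject_id = "S001"),
      SL2 = render_phantom(tr, "SL2", subject_id = "S001"))
  }
  .fix$phantoms
}

fix_truth <- function() subject_truth(fix_cohort(), "S001")

# a small noisy measured cohort reused across agreement/normative tests
fix_measured <- function() {
  if (is.null(.fix$measured)) {
    co <- sample_cohort(cohort_config(n_young = 6, n_old = 8, seed = 202))
    .fix$measured <- list(cohort = co, table = measure_cohort(co))
  }
  .fix$measured
}

# uniform-HU measurement table covering all regions of one subject
uniform_table <- function(hu = 30) {
  reg <- region_registry()
  data.frame(subject_id = "U1", method = "DOT", slice = reg$slice,
             region = reg$region, hu = hu, stringsAsFactors = FALSE)
}
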