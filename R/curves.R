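#' Normative age-response curves for regional Hounsfield units
#'
#' Regional mean attenuation in the developing brain follows simple
#' age-response laws over 1--216 months: gray-matter-rich regions
#' (whole-slice parenchyma, caudate nucleus, cortical gray matter) rise
#' as a power law of age in months, `y = a * x^b`, while the putamen,
#' thalamus and white matter are essentially age-flat and are modelled
#' linearly, `y = b * x + intercept`. Ventricles (cerebrospinal fluid)
#' carry no age trend and are held constant at their normative median of
#' 15 HU. These curves parameterize the synthetic cohort generator and
#' serve as ground truth for parameter-recovery checks.
#'
#' Lobar regions have no published curve of their own; they are modelled
#' as an area-weighted gray/white mixture of their slice's cortical GM
#' and deep WM curves (default weight 0.6 GM).
#'
#' @return `age_curve_registry()`: a data.frame with one row per curve:
#'   `region`, `form` (`"power"`, `"linear"` or `"constant"`), `a`, `b`,
#'   `intercept`, `r_squared` (the coefficient of determination reported
#'   for the normative fit, `NA` for constructed curves).
#' @examples
#' age_curve_registry()
#' regional_mean_curve("parenchyma_SL1", 12)
#' @export
age_curve_registry <- function() {
  if (!is.null(.registry_cache$curves)) return(.registry_cache$curves)
  p <- function(region, a, b, r2)
    data.frame(region = region, form = "power", a = a, b = b,
               intercept = NA_real_, r_squared = r2, stringsAsFactors = FALSE)
  l <- function(region, slope, intercept, r2)
    data.frame(region = region, form = "linear", a = NA_real_, b = slope,
               intercept = intercept, r_squared = r2, stringsAsFactors = FALSE)
  k <- function(region, value)
    data.frame(region = region, form = "constant", a = value, b = NA_real_,
               intercept = NA_real_, r_squared = NA_real_,
               stringsAsFactors = FALSE)
  .registry_cache$curves <- do.call(rbind, list(
    p("parenchyma_SL1", 26.424, 0.0250, 0.3809),
    p("parenchyma_SL2", 25.500, 0.0233, 0.3812),
    p("CN",             28.394, 0.0211, 0.3386),
    p("GM_SL1",         26.843, 0.0403, 0.4875),
    p("GM_SL2",         26.713, 0.0390, 0.4941),
    l("PT",      0.0005, 30.230, 0.0004),
    l("TM",      0.0011, 29.530, 0.0028),
    l("WM_SL1", -0.0031, 24.260, 0.0145),
    l("WM_SL2",  0.0061, 23.086, 0.0423),
    k("ventricle_SL1", 15),
    k("ventricle_SL2", 15)
  ))
  .registry_cache$curves
}

#' @rdname age_curve_registry
#' @param region Region name (see [region_registry()]). The white-matter
#'   subregions `WM_SL1_anterior`/`WM_SL1_posterior` share the `WM_SL1`
#'   curve; lobar regions use the GM/WM mixture.
#' @param age_months Age at scan in months, `> 0`. Ages below 1 month are
#'   clamped to 1 month (the power laws steepen without bound toward age
#'   zero; the youngest normative subject is about 1 month old).
#' @param lobe_gm_weight Gray-matter weight of the lobar mixture, in
#'   \[0, 1\].
#' @return `regional_mean_curve()`: the deterministic noise-free mean HU
#'   for `region` at `age_months` (vectorized over `age_months`).
#' @export
regional_mean_curve <- function(region, age_months, lobe_gm_weight = 0.6) {
  if (length(region) != 1L) stop("'region' must be a single region name")
  if (!is.numeric(age_months) || any(!is.finite(age_months)) ||
      any(age_months <= 0)) {
    stop("'age_months' must be positive and finite", call. = FALSE)
  }
  x <- pmax(age_months, 1)

  # subregions and lobes map onto the registered curves
  if (region %in% c("WM_SL1_anterior", "WM_SL1_posterior")) region <- "WM_SL1"
  lobe <- regmatches(region, regexpr("^(frontal|temporal|parietal|occipital)_(SL[12])$", region))
  if (length(lobe)) {
    if (lobe_gm_weight < 0 || lobe_gm_weight > 1) {
      stop("'lobe_gm_weight' must be in [0, 1]", call. = FALSE)
    }
    slice <- sub("^.*_(SL[12])$", "\\1", region)
    return(lobe_gm_weight * regional_mean_curve(paste0("GM_", slice), x) +
           (1 - lobe_gm_weight) * regional_mean_curve(paste0("WM_", slice), x))
  }

  reg <- age_curve_registry()
  i <- match(region, reg$region)
  if (is.na(i)) {
    stop("no age curve registered for region '", region, "'", call. = FALSE)
  }
  switch(reg$form[i],
         power    = reg$a[i] * x ^ reg$b[i],
         linear   = reg$b[i] * x + reg$intercept[i],
         constant = rep(reg$a[i], length(x)))
}
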