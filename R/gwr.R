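#' Registry of the twelve gray-white matter ratio formulas
#'
#' GWR is the ratio of gray-matter to white-matter attenuation; the
#' clinical literature computes it from many different region
#' combinations. Twelve formulas are registered, adapted to the two-slice
#' protocol: two basal-ganglia forms (`bg1`, `bg2`), seven single-nucleus
#' forms (`si_*`), the cortical form, and two averages. Multi-region
#' numerators and denominators are combined as the *mean* of the cited
#' regions' HU (so e.g. `(CN + PT)/WM-SL1` is `mean(CN, PT)/WM-SL1`);
#' `average2` is the arithmetic mean of the `bg1` and `cortical`
#' sub-ratios.
#'
#' @return data.frame with columns `formula_id`, `label` (display form),
#'   `numerator`, `denominator` (region names, `+`-separated),
#'   `composite_of` (for `average2`).
#' @examples
#' gwr_formulas()
#' @export
gwr_formulas <- function() {
  if (!is.null(.registry_cache$gwr)) return(.registry_cache$gwr)
  f <- function(id, label, num, den, comp = NA_character_) {
    data.frame(formula_id = id, label = label,
               numerator = paste(num, collapse = "+"),
               denominator = paste(den, collapse = "+"),
               composite_of = comp, stringsAsFactors = FALSE)
  }
  .registry_cache$gwr <- do.call(rbind, list(
    f("bg1", "(CN + PT)/WM-SL1", c("CN", "PT"), "WM_SL1"),
    f("bg2", "(CN + PT + TM)/WM-SL1", c("CN", "PT", "TM"), "WM_SL1"),
    f("si_PT_PLIC", "PT/WM-SL1-posterior", "PT", "WM_SL1_posterior"),
    f("si_PT_WMfr1", "PT/WM-SL1-anterior", "PT", "WM_SL1_anterior"),
    f("si_CN_PLIC", "CN/WM-SL1-posterior", "CN", "WM_SL1_posterior"),
    f("si_CN_WMfr1", "CN/WM-SL1-anterior", "CN", "WM_SL1_anterior"),
    f("si_CN_WM2", "CN/WM-SL2", "CN", "WM_SL2"),
    f("si_PT_WM2", "PT/WM-SL2", "PT", "WM_SL2"),
    f("si_TM_WM2", "TM/WM-SL2", "TM", "WM_SL2"),
    f("cortical", "(GM-SL1 + GM-SL2)/(WM-SL1 + WM-SL2)",
      c("GM_SL1", "GM_SL2"), c("WM_SL1", "WM_SL2")),
    f("average1", "(CN + PT + GM-SL1 + GM-SL2)/(WM-SL1 + WM-SL2)",
      c("CN", "PT", "GM_SL1", "GM_SL2"), c("WM_SL1", "WM_SL2")),
    f("average2", "(GWR_bg1 + GWR_cortical)/2",
      character(0), character(0), comp = "bg1+cortical")
  ))
  .registry_cache$gwr
}

split_regions <- function(s) if (!nzchar(s)) character(0) else
  strsplit(s, "+", fixed = TRUE)[[1]]

hu_lookup <- function(table, regions, formula_id) {
  v <- table$hu[match(regions, table$region)]
  miss <- regions[is.na(v)]
  if (length(miss)) {
    stop("formula '", formula_id, "' needs missing region(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  v
}

#' Compute one GWR value for one subject
#'
#' @param table One subject's measurement rows from a single method:
#'   data.frame with columns `region` and `hu` (as produced by
#'   [measure_subject()] filtered to one method).
#' @param formula_id One of the ids in [gwr_formulas()].
#' @param warn_below_one Warn (rather than error) when the ratio is
#'   below 1, which is unexpected in normal brain but the signal of
#'   interest in edema.
#' @return The dimensionless ratio (scalar).
#' @examples
#' tab <- data.frame(region = c("CN", "PT", "WM_SL1"), hu = c(32, 30, 24))
#' compute_gwr(tab, "bg1")  # mean(32, 30) / 24
#' @export
compute_gwr <- function(table, formula_id, warn_below_one = FALSE) {
  reg <- gwr_formulas()
  i <- match(formula_id, reg$formula_id)
  if (is.na(i)) stop("unknown GWR formula '", formula_id, "'", call. = FALSE)
  if (!is.na(reg$composite_of[i])) {
    parts <- split_regions(reg$composite_of[i])
    val <- mean(vapply(parts, function(p) compute_gwr(table, p), numeric(1)))
  } else {
    num <- mean(hu_lookup(table, split_regions(reg$numerator[i]), formula_id))
    den <- mean(hu_lookup(table, split_regions(reg$denominator[i]), formula_id))
    if (den <= 0) {
      stop("non-positive denominator mean in formula '", formula_id, "'",
           call. = FALSE)
    }
    val <- num / den
  }
  if (warn_below_one && val < 1) {
    warning("GWR ", formula_id, " = ", round(val, 3),
            " is below 1 (gray matter darker than white matter)",
            call. = FALSE)
  }
  val
}

#' Average-of-sub-ratio composite (GWR average 2)
#'
#' Combines precomputed basal-ganglia and cortical sub-ratios:
#' `(bg1 + cortical) / 2`.
#'
#' @param bg1,cortical Sub-ratio values.
#' @return The composite ratio.
#' @examples
#' gwr_average2(1.22, 1.18)
#' @export
gwr_average2 <- function(bg1, cortical) {
  stopifnot(is.finite(bg1), is.finite(cortical))
  (bg1 + cortical) / 2
}

#' Compute all twelve GWR values for every subject in a table
#'
#' @param table Tidy measurement data.frame (`subject_id`, `method`,
#'   `region`, `hu`); rows from a single method.
#' @param method Method whose rows to use when `table` contains both
#'   (default `"DOT"`: the formulas' tissue compartments are
#'   probe-sampled).
#' @return data.frame `subject_id`, `formula_id`, `method`, `value`, in
#'   registry order within subject.
#' @export
compute_all_gwr <- function(table, method = "DOT") {
  if ("method" %in% names(table)) {
    table <- table[table$method == method, , drop = FALSE]
    if (!nrow(table)) stop("no rows for method '", method, "'", call. = FALSE)
  }
  ids <- gwr_formulas()$formula_id
  subjects <- unique(table$subject_id)
  res <- lapply(subjects, function(s) {
    sub <- table[table$subject_id == s, , drop = FALSE]
    vals <- vapply(ids, function(id) compute_gwr(sub, id), numeric(1))
    data.frame(subject_id = s, formula_id = ids, method = method,
               value = as.numeric(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
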