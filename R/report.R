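# report row sets: the canonical ROI and DOT summary blocks; their row
# counts are also the default Bonferroni family sizes (14 and 9; GWR 12)
roi_report_regions <- function() {
  c("parenchyma_SL1", "parenchyma_SL2",
    "frontal_SL1", "temporal_SL1", "parietal_SL1", "occipital_SL1",
    "frontal_SL2", "parietal_SL2", "occipital_SL2",
    "CN", "PT", "TM", "ventricle_SL1", "ventricle_SL2")
}

dot_report_regions <- function() {
  c("GM_SL1", "GM_SL2", "WM_SL1", "WM_SL2",
    "CN", "PT", "TM", "ventricle_SL1", "ventricle_SL2")
}

# which method feeds each age-response fit: segmented ROI for whole-slice
# parenchyma and the deep nuclei, probe values for the tissue compartments
curve_fit_plan <- function() {
  data.frame(
    region = c("parenchyma_SL1", "parenchyma_SL2", "CN", "GM_SL1", "GM_SL2",
               "PT", "TM", "WM_SL1", "WM_SL2"),
    method = c("ROI", "ROI", "ROI", "DOT", "DOT",
               "ROI", "ROI", "DOT", "DOT"),
    form = c(rep("power", 5), rep("linear", 4)),
    stringsAsFactors = FALSE)
}

#' Age-stratified normative report
#'
#' Produces the pipeline's three normative outputs from a measured
#' cohort: (1) a per-region HU summary (median/IQR by age group with a
#' normality-gated group test, Bonferroni-adjusted within each method
#' block: 14 segmented-ROI rows, 9 probe/DOT rows); (2) the same summary
#' for the twelve GWR formulas (family size 12); and (3) age-response
#' curve fits (power law for parenchyma, caudate and cortical gray
#' matter; linear for putamen, thalamus and white matter).
#'
#' @param hu_table Tidy measurement table (`subject_id`, `method`,
#'   `region`, `hu`) containing both methods.
#' @param gwr_table GWR table from [compute_all_gwr()].
#' @param subjects Subject data.frame with `subject_id`, `age_months`
#'   (the `group` column is (re)derived by [stratify()]).
#' @param family_sizes Named list overriding the Bonferroni family sizes
#'   of the `roi`, `dot` and `gwr` blocks (defaults: block row counts).
#' @return Object of class `normative_report`: list with `hu_summary`,
#'   `gwr_summary`, `curve_fits` (data.frames) and `groups` (stratum
#'   sizes).
#' @export
normative_report <- function(hu_table, gwr_table, subjects,
                             family_sizes = list()) {
  subjects <- stratify(subjects)
  if (length(unique(subjects$group)) < 2) {
    stop("both age strata are required for a normative report",
         call. = FALSE)
  }
  grp <- function(ids) subjects$group[match(ids, subjects$subject_id)]

  block <- function(tab, value_col, vars, var_col, fam, method = NULL) {
    fam <- if (is.null(fam)) length(vars) else fam
    rows <- lapply(vars, function(v) {
      sel <- tab[[var_col]] == v
      if (!is.null(method)) sel <- sel & tab$method == method
      sub <- tab[sel, , drop = FALSE]
      g <- grp(sub$subject_id)
      cmp <- compare_groups(sub[[value_col]][g == "young"],
                            sub[[value_col]][g == "old"],
                            family_size = fam, variable = v)
      if (!is.null(method)) cmp <- cbind(method = method, cmp)
      cmp
    })
    do.call(rbind, rows)
  }

  hu_summary <- rbind(
    block(hu_table, "hu", roi_report_regions(), "region",
          family_sizes$roi, method = "ROI"),
    block(hu_table, "hu", dot_report_regions(), "region",
          family_sizes$dot, method = "DOT"))
  gwr_summary <- block(gwr_table, "value", gwr_formulas()$formula_id,
                       "formula_id", family_sizes$gwr)

  plan <- curve_fit_plan()
  fits <- lapply(seq_len(nrow(plan)), function(i) {
    sub <- hu_table[hu_table$region == plan$region[i] &
                    hu_table$method == plan$method[i], , drop = FALSE]
    ages <- subjects$age_months[match(sub$subject_id, subjects$subject_id)]
    f <- if (plan$form[i] == "power") {
      fit_power_curve(ages, sub$hu)
    } else {
      fit_linear(ages, sub$hu)
    }
    data.frame(region = plan$region[i], method = plan$method[i],
               form = f$form, a = f$a, b = f$b, intercept = f$intercept,
               r_squared = f$r_squared, n = f$n, stringsAsFactors = FALSE)
  })

  structure(list(hu_summary = hu_summary, gwr_summary = gwr_summary,
                 curve_fits = do.call(rbind, fits),
                 groups = table(subjects$group)),
            class = "normative_report")
}

#' @export
print.normative_report <- function(x, ...) {
  cat("Normative report:", x$groups[["young"]], "young /",
      x$groups[["old"]], "old subjects\n")
  cat("  HU rows:", nrow(x$hu_summary),
      "| GWR rows:", nrow(x$gwr_summary),
      "| curve fits:", nrow(x$curve_fits), "\n")
  sig <- x$gwr_summary[x$gwr_summary$p_adjusted < 0.05, "variable"]
  if (length(sig)) {
    cat("  GWR formulas differing by age group (adj. p < 0.05):",
        paste(sig, collapse = ", "), "\n")
  }
  invisible(x)
}
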