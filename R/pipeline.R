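#' Pipeline run configuration
#'
#' A single configuration object drives the staged pipeline. It
#' round-trips losslessly through YAML (`read_run_config()` /
#' `write_run_config()`).
#'
#' @param seed Integer seed for the whole run.
#' @param cohort Named list of [cohort_config()] overrides.
#' @param phantom Named list: `pixel_spacing` (mm), `n_pixels`.
#' @param measurement Named list: `dot_diameter_mm`.
#' @param stats Named list: `family_sizes` overrides (see
#'   [normative_report()]).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = list(), phantom = list(),
                       measurement = list(), stats = list()) {
  ph <- utils::modifyList(list(pixel_spacing = 0.5, n_pixels = 256), phantom)
  ms <- utils::modifyList(list(dot_diameter_mm = 2.6), measurement)
  structure(list(seed = as.integer(seed), cohort = cohort, phantom = ph,
                 measurement = ms, stats = stats),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw),
                                    c("seed", "cohort", "phantom",
                                      "measurement", "stats"))])
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_manifest <- function(outdir, config, stage, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    tool = "gwrkit",
    version = as.character(utils::packageVersion("gwrkit")),
    stage = stage,
    seed = config$seed,
    config = unclass(config),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Pipeline stages
#'
#' Staged orchestration of the full analysis, mirroring the measurement
#' protocol: `run_simulate()` writes NIfTI phantoms, the cohort CSV, the
#' label dictionary and the dot plans; `run_measure()` reads them back
#' and writes the tidy measurement CSV; `run_gwr()` computes the twelve
#' ratios; `run_agree()` writes the per-region ROI-vs-DOT Bland-Altman
#' table and the intra-rater re-read ICC; `run_norms()` writes the
#' age-stratified normative summaries and curve fits. `run_pipeline()`
#' chains all stages into one output directory. Every stage writes a
#' `manifest.json` recording the seed, config and output checksums.
#'
#' @param config A [run_config()].
#' @param outdir Output directory for the stage.
#' @param indir Directory holding the upstream stage's outputs.
#' @return Invisibly, the stage's primary output path(s).
#' @export
run_simulate <- function(config = run_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ccfg <- do.call(cohort_config,
                  utils::modifyList(list(seed = config$seed), config$cohort))
  cohort <- sample_cohort(ccfg)

  utils::write.csv(cohort$subjects, file.path(outdir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(outdir, "true_means.csv"),
                   row.names = FALSE)

  labels <- list(SL1 = label_table("SL1"), SL2 = label_table("SL2"))
  jsonlite::write_json(labels, file.path(outdir, "labels.json"),
                       dataframe = "rows", pretty = TRUE)
  plans <- lapply(c(SL1 = "SL1", SL2 = "SL2"), function(sl) {
    lapply(default_dot_plan(sl, config$phantom$pixel_spacing,
                            config$phantom$n_pixels,
                            config$measurement$dot_diameter_mm), unclass)
  })
  jsonlite::write_json(plans, file.path(outdir, "dot_plan.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  pdir <- file.path(outdir, "phantoms")
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    tr <- subject_truth(cohort, sid)
    for (sl in c("SL1", "SL2")) {
      ph <- render_phantom(tr, sl, config$phantom$pixel_spacing,
                           config$phantom$n_pixels,
                           ccfg$noise_sd_voxel,
                           seed = subseed(ccfg$seed, i,
                                          if (sl == "SL1") 1L else 2L),
                           subject_id = sid)
      write_phantom(ph, pdir)
    }
  }
  write_manifest(outdir, config, "simulate",
                 file.path(outdir, c("cohort.csv", "true_means.csv",
                                     "labels.json", "dot_plan.json")))
  invisible(file.path(outdir, "cohort.csv"))
}

read_dot_plans <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(plan) {
    lapply(plan, function(d) {
      dot_spec(d$center, d$target_region, d$side, d$diameter_mm)
    })
  })
}

#' @rdname run_simulate
#' @param method `"ROI"`, `"DOT"` or `"both"`.
#' @export
run_measure <- function(config = run_config(), indir, outdir = indir,
                        method = "both") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  subjects <- utils::read.csv(file.path(indir, "cohort.csv"),
                              stringsAsFactors = FALSE)
  need <- c("subject_id", "age_months", "group")
  if (!all(need %in% names(subjects))) {
    stop("cohort.csv lacks column(s): ",
         paste(setdiff(need, names(subjects)), collapse = ", "),
         call. = FALSE)
  }
  plans <- read_dot_plans(file.path(indir, "dot_plan.json"))
  pdir <- file.path(indir, "phantoms")
  tabs <- lapply(subjects$subject_id, function(sid) {
    ph <- lapply(c(SL1 = "SL1", SL2 = "SL2"), function(sl) {
      read_phantom(file.path(pdir, paste0(sid, "_", sl, "_img.nii.gz")),
                   file.path(pdir, paste0(sid, "_", sl, "_lbl.nii.gz")),
                   sl, subject_id = sid)
    })
    measure_subject(ph, dot_plans = plans, method = method,
                    subject_id = sid)
  })
  out <- do.call(rbind, tabs)
  path <- file.path(outdir, "measurements.csv")
  utils::write.csv(out, path, row.names = FALSE)
  write_manifest(outdir, config, "measure", path)
  invisible(path)
}

read_measurements <- function(indir) {
  path <- file.path(indir, "measurements.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "method", "slice", "region", "hu")
  if (!all(need %in% names(tab))) {
    stop("measurements.csv lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab
}

#' @rdname run_simulate
#' @export
run_gwr <- function(config = run_config(), indir, outdir = indir,
                    method = "DOT") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_measurements(indir)
  gwr <- compute_all_gwr(tab, method = method)
  path <- file.path(outdir, "gwr.csv")
  utils::write.csv(gwr, path, row.names = FALSE)
  jsonlite::write_json(gwr_formulas(), file.path(outdir, "gwr_registry.json"),
                       dataframe = "rows", pretty = TRUE)
  write_manifest(outdir, config, "gwr",
                 c(path, file.path(outdir, "gwr_registry.json")))
  invisible(path)
}

#' @rdname run_simulate
#' @export
run_agree <- function(config = run_config(), indir, outdir = indir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_measurements(indir)
  if (!"DOT" %in% tab$method) {
    stop("agreement stage needs DOT measurements; re-run measurement ",
         "with method 'both'", call. = FALSE)
  }
  if (!"ROI" %in% tab$method) {
    stop("agreement stage needs ROI measurements; re-run measurement ",
         "with method 'both'", call. = FALSE)
  }
  agr <- agreement_table(tab, regions = c("ventricle_SL1", "ventricle_SL2",
                                          "CN", "PT", "TM"))
  path <- file.path(outdir, "agreement.csv")
  utils::write.csv(agr, path, row.names = FALSE)

  icc <- vapply(c(SL1 = "SL1", SL2 = "SL2"), function(sl) {
    m <- simulate_rereads(tab, fraction = 0.1, seed = config$seed,
                          slice = sl)
    icc_single_rater(m)
  }, numeric(1))
  utils::write.csv(data.frame(slice = names(icc), icc = as.numeric(icc)),
                   file.path(outdir, "icc.csv"), row.names = FALSE)
  write_manifest(outdir, config, "agree",
                 c(path, file.path(outdir, "icc.csv")))
  invisible(path)
}

#' @rdname run_simulate
#' @export
run_norms <- function(config = run_config(), indir, outdir = indir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_measurements(indir)
  gwr <- utils::read.csv(file.path(indir, "gwr.csv"),
                         stringsAsFactors = FALSE)
  subjects <- utils::read.csv(file.path(indir, "cohort.csv"),
                              stringsAsFactors = FALSE)
  rep <- normative_report(tab, gwr, subjects,
                          family_sizes = config$stats$family_sizes %||% list())
  paths <- file.path(outdir, c("hu_summary.csv", "gwr_summary.csv",
                               "curve_fits.csv"))
  utils::write.csv(rep$hu_summary, paths[1], row.names = FALSE)
  utils::write.csv(rep$gwr_summary, paths[2], row.names = FALSE)
  utils::write.csv(rep$curve_fits, paths[3], row.names = FALSE)
  write_manifest(outdir, config, "norms", paths)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_simulate
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  run_simulate(config, outdir)
  run_measure(config, outdir)
  run_gwr(config, outdir)
  run_agree(config, outdir)
  run_norms(config, outdir)
  invisible(outdir)
}
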