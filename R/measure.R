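#' Segmented-ROI mean Hounsfield units
#'
#' Arithmetic mean of the image over all pixels carrying the region's
#' label(s). For bilateral regions, pass `side` to obtain a single side's
#' mean before bilateral averaging; with `side = NULL` both sides' pixels
#' are pooled per side and averaged with [bilateral_average()]. The
#' parenchyma mask is the union of all tissue labels on the slice
#' excluding the ventricles.
#'
#' @param phantom A `slice_phantom`.
#' @param region Region name registered for the phantom's slice.
#' @param side `"left"`, `"right"`, `"mid"`, or `NULL` for the
#'   bilaterally averaged value.
#' @return Mean HU (scalar).
#' @examples
#' cohort <- sample_cohort(cohort_config(seed = 1))
#' ph <- render_phantom(subject_truth(cohort, "S001"), "SL1")
#' roi_mean_hu(ph, "CN")
#' @export
roi_mean_hu <- function(phantom, region, side = NULL) {
  stopifnot(inherits(phantom, "slice_phantom"))
  info <- region_info(region)
  if (info$slice != phantom$slice) {
    stop("region '", region, "' belongs to ", info$slice, ", not ",
         phantom$slice, call. = FALSE)
  }
  if (isTRUE(info$derived)) {  # generic WM_SL1 = mean of its two probe sites
    return(bilateral_average(roi_mean_hu(phantom, "WM_SL1_anterior", side),
                             roi_mean_hu(phantom, "WM_SL1_posterior", side)))
  }
  one_side <- function(s) {
    codes <- region_codes(phantom$slice, region, s)
    px <- phantom$labels %in% codes
    if (!any(px)) {
      stop("no pixels labelled for region '", region, "'",
           if (!is.null(s)) paste0(" (", s, ")"), call. = FALSE)
    }
    mean(phantom$image[px])
  }
  if (!is.null(side) || info$laterality == "midline" ||
      region %in% c("parenchyma_SL1", "parenchyma_SL2")) {
    return(one_side(side))
  }
  bilateral_average(one_side("left"), one_side("right"))
}

#' Average left and right measurements of a bilateral region
#'
#' @param left,right Finite HU values.
#' @return `(left + right) / 2`.
#' @export
bilateral_average <- function(left, right) {
  if (!is.finite(left) || !is.finite(right)) {
    stop("both sides must be finite to average", call. = FALSE)
  }
  (left + right) / 2
}

#' Circular-dot pixel mask
#'
#' Returns the pixels whose centers lie within `diameter_mm / 2` of the
#' dot center, using the pixel-center-in-circle rule (no partial-volume
#' weighting). Pixel coordinates are row-major with the first pixel
#' center at (1, 1); fractional centers are allowed.
#'
#' @param center Numeric `(row, col)` dot center in pixel coordinates.
#' @param diameter_mm Dot diameter in mm; the protocol range is
#'   \[2.4, 2.8\].
#' @param pixel_spacing Pixel spacing in mm (> 0).
#' @param dim Image dimensions `(nrow, ncol)`.
#' @return Two-column integer matrix of `(row, col)` pixel indices.
#' @examples
#' dot_mask(c(10, 10), 2.6, 0.5, c(64, 64))
#' @export
dot_mask <- function(center, diameter_mm, pixel_spacing, dim) {
  if (pixel_spacing <= 0) stop("'pixel_spacing' must be > 0", call. = FALSE)
  if (diameter_mm < 2.4 || diameter_mm > 2.8) {
    stop("dot diameter must lie in [2.4, 2.8] mm", call. = FALSE)
  }
  r_px <- (diameter_mm / 2) / pixel_spacing
  if (center[1] - r_px < 0.5 || center[1] + r_px > dim[1] + 0.5 ||
      center[2] - r_px < 0.5 || center[2] + r_px > dim[2] + 0.5) {
    stop("dot extends outside the image", call. = FALSE)
  }
  rows <- seq(max(1L, floor(center[1] - r_px)),
              min(dim[1], ceiling(center[1] + r_px)))
  cols <- seq(max(1L, floor(center[2] - r_px)),
              min(dim[2], ceiling(center[2] + r_px)))
  g <- expand.grid(row = rows, col = cols)
  d2 <- (g$row - center[1])^2 + (g$col - center[2])^2
  g <- g[d2 <= r_px^2 + 1e-12, , drop = FALSE]
  if (!nrow(g)) {
    stop("dot covers no pixel centers (spacing too coarse for this ",
         "diameter)", call. = FALSE)
  }
  as.matrix(g)
}

#' Dot specification
#'
#' @param center `(row, col)` pixel coordinates of the dot center.
#' @param target_region Region the dot samples.
#' @param side `"left"`, `"right"` or `"mid"`.
#' @param diameter_mm Dot diameter in mm (default 2.6, the midpoint of
#'   the 2.4--2.8 mm protocol range).
#' @return A list of class `dot_spec`.
#' @export
dot_spec <- function(center, target_region, side = "mid",
                     diameter_mm = 2.6) {
  structure(list(center = as.numeric(center), target_region = target_region,
                 side = side, diameter_mm = diameter_mm),
            class = "dot_spec")
}

#' Mean HU within a circular dot
#'
#' A dot whose mask touches any pixel outside its target region's label
#' is a placement error (contamination) and raises an error rather than
#' silently cropping.
#'
#' @param phantom A `slice_phantom`.
#' @param dot A [dot_spec()].
#' @return Mean HU over the dot's pixels.
#' @export
dot_mean_hu <- function(phantom, dot) {
  stopifnot(inherits(phantom, "slice_phantom"), inherits(dot, "dot_spec"))
  m <- dot_mask(dot$center, dot$diameter_mm, phantom$pixel_spacing,
                dim(phantom$image))
  codes <- region_codes(phantom$slice, dot$target_region, dot$side)
  labs <- phantom$labels[m]
  if (!all(labs %in% codes)) {
    stop("dot for '", dot$target_region, "' (", dot$side,
         ") overlaps pixels outside its target label", call. = FALSE)
  }
  mean(phantom$image[m])
}

# mm (ap, lr) -> pixel (row, col)
mm_to_px <- function(ap, lr, pixel_spacing, n_pixels) {
  ctr <- (n_pixels + 1) / 2
  c(ctr - ap / pixel_spacing, ctr + lr / pixel_spacing)
}

#' Default dot placement plan for a slice
#'
#' Places one dot per side at the geometric center of each deep
#' structure (CN, PT, TM, the two SL1 white-matter sites, ventricles,
#' deep WM on SL2) and one per side on the cortical ribbon, derived from
#' the same geometry the phantom renderer uses; every default dot is
#' wholly inside its target label.
#'
#' @inheritParams slice_geometry
#' @param pixel_spacing,n_pixels Grid parameters of the target phantoms.
#' @param diameter_mm Dot diameter in mm.
#' @return List of [dot_spec()] objects.
#' @export
default_dot_plan <- function(slice, pixel_spacing = 0.5, n_pixels = 256,
                             diameter_mm = 2.6) {
  geo <- slice_geometry(slice)
  dots <- list()
  add <- function(region, ap, lr, side) {
    dots[[length(dots) + 1L]] <<- dot_spec(
      mm_to_px(ap, lr, pixel_spacing, n_pixels), region, side, diameter_mm)
  }
  for (stx in geo$structures) {
    if (stx$bilateral) {
      add(stx$region, stx$ap, -stx$lr, "left")
      add(stx$region, stx$ap, stx$lr, "right")
    } else {
      add(stx$region, stx$ap, stx$lr, "mid")
    }
  }
  # cortical ribbon dots at 93% radius, 35 degrees off the anterior axis
  th <- 35 * pi / 180
  ap <- 0.93 * geo$ry * cos(th)
  lr <- 0.93 * geo$rx * sin(th)
  gm <- paste0("GM_", geo$slice)
  add(gm, ap, -lr, "left")
  add(gm, ap, lr, "right")
  dots
}

#' Measure one subject's phantoms by the ROI and/or DOT method
#'
#' Produces the tidy per-subject measurement table: one row per region
#' and method, bilateral sides already averaged. The derived generic
#' `WM_SL1` entry is the mean of the anterior and posterior SL1
#' white-matter values. DOT rows cover the probe-sampled tissue
#' compartments and deep nuclei; ROI rows cover every segmented region.
#'
#' @param phantoms Named list with elements `SL1` and `SL2`
#'   (`slice_phantom` objects).
#' @param dot_plans Named list of dot plans per slice (defaults derived
#'   from each phantom's grid).
#' @param method `"ROI"`, `"DOT"` or `"both"`.
#' @param subject_id Id recorded in the table.
#' @return data.frame with columns `subject_id`, `method`, `slice`,
#'   `region`, `hu`.
#' @export
measure_subject <- function(phantoms, dot_plans = NULL, method = "both",
                            subject_id = phantoms$SL1$subject_id) {
  method <- match.arg(method, c("ROI", "DOT", "both"))
  if (!all(c("SL1", "SL2") %in% names(phantoms))) {
    stop("phantoms for both SL1 and SL2 are required", call. = FALSE)
  }
  if (is.null(dot_plans)) {
    dot_plans <- lapply(phantoms, function(p) {
      default_dot_plan(p$slice, p$pixel_spacing, nrow(p$image))
    })
  }
  out <- list()
  errs <- character(0)
  add <- function(meth, slice, region, hu) {
    out[[length(out) + 1L]] <<- data.frame(
      subject_id = subject_id, method = meth, slice = slice,
      region = region, hu = hu, stringsAsFactors = FALSE)
  }

  if (method %in% c("ROI", "both")) {
    for (sl in c("SL1", "SL2")) {
      reg <- slice_regions(sl)
      for (r in reg$region) {
        hu <- tryCatch(roi_mean_hu(phantoms[[sl]], r),
                       error = function(e) {
                         errs <<- c(errs, paste0("ROI/", r))
                         NA_real_
                       })
        add("ROI", sl, r, hu)
      }
    }
  }
  if (method %in% c("DOT", "both")) {
    for (sl in c("SL1", "SL2")) {
      plan <- dot_plans[[sl]]
      vals <- list()
      for (d in plan) {
        hu <- tryCatch(dot_mean_hu(phantoms[[sl]], d),
                       error = function(e) {
                         errs <<- c(errs, paste0("DOT/", d$target_region,
                                                 "/", d$side, ": ",
                                                 conditionMessage(e)))
                         NA_real_
                       })
        vals[[d$target_region]] <- c(vals[[d$target_region]], hu)
      }
      for (r in names(vals)) {
        v <- vals[[r]]
        add("DOT", sl, r,
            if (length(v) == 2) bilateral_average(v[1], v[2]) else v[1])
      }
      if (sl == "SL1" &&
          all(c("WM_SL1_anterior", "WM_SL1_posterior") %in% names(vals))) {
        add("DOT", sl, "WM_SL1",
            mean(c(mean(vals[["WM_SL1_anterior"]]),
                   mean(vals[["WM_SL1_posterior"]]))))
      }
    }
  }
  if (length(errs)) {
    stop("measurement failed for: ", paste(errs, collapse = "; "),
         call. = FALSE)
  }
  do.call(rbind, out)
}

# deterministic per-subject sub-seed below 2^31
subseed <- function(seed, i, salt = 0L) {
  (abs(as.integer(seed)) + 7919L * as.integer(i) + as.integer(salt)) %%
    2147483629L
}

#' Render and measure a whole cohort
#'
#' Renders both slices for every subject (voxel-noise seeds derived
#' deterministically from the cohort seed) and stacks the per-subject
#' measurement tables.
#'
#' @param cohort A `gwr_cohort`.
#' @param method `"ROI"`, `"DOT"` or `"both"`.
#' @param pixel_spacing,n_pixels Phantom grid parameters.
#' @param noise_sd_voxel Voxel noise SD in HU; defaults to the cohort
#'   config value.
#' @return Tidy measurement data.frame (see [measure_subject()]).
#' @export
measure_cohort <- function(cohort, method = "both", pixel_spacing = 0.5,
                           n_pixels = 256,
                           noise_sd_voxel = cohort$config$noise_sd_voxel) {
  stopifnot(inherits(cohort, "gwr_cohort"))
  res <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    sid <- cohort$subjects$subject_id[i]
    tr <- subject_truth(cohort, sid)
    ph <- list(
      SL1 = render_phantom(tr, "SL1", pixel_spacing, n_pixels,
                           noise_sd_voxel,
                           seed = subseed(cohort$config$seed, i, 1L),
                           subject_id = sid),
      SL2 = render_phantom(tr, "SL2", pixel_spacing, n_pixels,
                           noise_sd_voxel,
                           seed = subseed(cohort$config$seed, i, 2L),
                           subject_id = sid))
    measure_subject(ph, method = method, subject_id = sid)
  })
  do.call(rbind, res)
}

#' Noise-free measurement table straight from cohort truth
#'
#' Returns the measurement table a noiseless phantom pass would produce
#' (the noiseless round-trip is exact, so this is the fast path for
#' statistical studies that do not exercise the renderer).
#'
#' @param cohort A `gwr_cohort`.
#' @param method `"ROI"`, `"DOT"` or `"both"`.
#' @return Tidy measurement data.frame (see [measure_subject()]).
#' @export
hu_table_from_truth <- function(cohort, method = "both") {
  method <- match.arg(method, c("ROI", "DOT", "both"))
  reg <- region_registry()
  keep <- if (method == "ROI") reg[reg$roi, ] else
          if (method == "DOT") reg[reg$dot, ] else reg
  rows <- list()
  for (m in intersect(c("ROI", "DOT"), if (method == "both") c("ROI", "DOT") else method)) {
    sel <- if (m == "ROI") reg$roi else reg$dot
    sub <- reg[sel, ]
    t <- cohort$truth[cohort$truth$region %in% sub$region, ]
    t$method <- m
    t$slice <- sub$slice[match(t$region, sub$region)]
    rows[[m]] <- data.frame(subject_id = t$subject_id, method = m,
                            slice = t$slice, region = t$region,
                            hu = t$true_hu, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
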