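#' Slice geometry for phantom rendering
#'
#' The phantoms are deliberately schematic: an elliptical brain outline
#' (bone already stripped, background HU of air), a cortical gray-matter
#' ribbon along the outer 14% of the ellipse radius, a lobar band between
#' 60% and 86% of the radius split into angular sectors, and elliptical
#' deep structures (ventricles, deep nuclei, white-matter probe sites)
#' drawn over a parenchyma filler. Coordinates are in mm relative to the
#' slice center, anterior positive along the first axis, subject-right
#' positive along the second; downstream measurement code is
#' geometry-agnostic, so shape realism is not required.
#'
#' @param slice `"SL1"` (basal-ganglia level) or `"SL2"`
#'   (supraventricular level).
#' @return A list describing the slice's outline, ribbon/band radii,
#'   sector angles and deep structures.
#' @keywords internal
slice_geometry <- function(slice) {
  slice <- match.arg(slice, c("SL1", "SL2"))
  st <- function(region, ap, lr, s_ap, s_lr, bilateral = TRUE) {
    list(region = region, ap = ap, lr = lr, s_ap = s_ap, s_lr = s_lr,
         bilateral = bilateral)
  }
  if (slice == "SL1") {
    list(slice = "SL1", ry = 60, rx = 50,
         ribbon_inner = 0.86, band_inner = 0.60,
         # lobar sectors by angle (degrees) from the anterior axis
         sectors = data.frame(region = c("frontal_SL1", "temporal_SL1",
                                         "parietal_SL1", "occipital_SL1"),
                              from = c(0, 50, 100, 140),
                              to = c(50, 100, 140, 180),
                              stringsAsFactors = FALSE),
         structures = list(
           st("ventricle_SL1", 0, 0, 9, 2.5, bilateral = FALSE),
           st("CN", 14, 9, 5, 3.5),
           st("PT", 2, 15, 6, 4),
           st("TM", -14, 8, 6, 5),
           st("WM_SL1_anterior", 26, 10, 4, 3.5),
           st("WM_SL1_posterior", -2, 8, 3, 2.5)))
  } else {
    list(slice = "SL2", ry = 55, rx = 45,
         ribbon_inner = 0.86, band_inner = 0.60,
         sectors = data.frame(region = c("frontal_SL2", "parietal_SL2",
                                         "occipital_SL2"),
                              from = c(0, 60, 130), to = c(60, 130, 180),
                              stringsAsFactors = FALSE),
         structures = list(
           st("ventricle_SL2", 5, 7, 16, 3),
           st("WM_SL2", 0, 16, 18, 5.5)))
  }
}

#' Render a synthetic slice phantom for one subject
#'
#' Builds the integer label map from the slice geometry and fills each
#' region with the subject's true mean HU plus independent Gaussian voxel
#' noise. The parenchyma filler value is solved so that the area-weighted
#' mean over the whole parenchyma mask (all tissue, ventricles excluded)
#' equals the subject's parenchyma truth exactly; with zero voxel noise
#' every region's ROI mean therefore reproduces its true mean.
#'
#' @param truth Named numeric vector of true mean HU per region, as
#'   returned by `subject_truth()` or one subject's rows of
#'   `sample_cohort()$truth`.
#' @param slice `"SL1"` or `"SL2"`.
#' @param pixel_spacing Isotropic pixel spacing in mm (> 0).
#' @param n_pixels Grid side length in pixels.
#' @param noise_sd_voxel Voxel noise SD in HU (>= 0).
#' @param seed Optional integer seed for the voxel noise.
#' @param subject_id Optional id stored with the phantom.
#' @return An object of class `slice_phantom`: list with `slice`, `image`
#'   (numeric matrix, HU; background at -1000), `labels` (integer matrix,
#'   0 = background), `pixel_spacing`, `label_table`, `subject_id`.
#' @examples
#' cohort <- sample_cohort(cohort_config(seed = 1))
#' ph <- render_phantom(subject_truth(cohort, "S001"), "SL1",
#'                      noise_sd_voxel = 0)
#' table(ph$labels > 0)
#' @export
render_phantom <- function(truth, slice, pixel_spacing = 0.5,
                           n_pixels = 256, noise_sd_voxel = 0, seed = NULL,
                           subject_id = NA_character_) {
  if (pixel_spacing <= 0) stop("'pixel_spacing' must be > 0", call. = FALSE)
  if (noise_sd_voxel < 0) stop("'noise_sd_voxel' must be >= 0", call. = FALSE)
  geo <- slice_geometry(slice)
  slice <- geo$slice
  lt <- label_table(slice)
  need <- setdiff(lt$region, names(truth))
  if (length(need)) {
    stop("truth is missing regions: ", paste(unique(need), collapse = ", "),
         call. = FALSE)
  }
  code_of <- function(region, side) lt$code[lt$region == region & lt$side == side]

  n <- as.integer(n_pixels)
  ctr <- (n + 1) / 2
  ap <- matrix(rep((ctr - seq_len(n)) * pixel_spacing, times = n), n, n)
  lr <- matrix(rep((seq_len(n) - ctr) * pixel_spacing, each = n), n, n)

  rn <- sqrt((ap / geo$ry)^2 + (lr / geo$rx)^2)
  side_m <- ifelse(lr < 0, "left", "right")
  theta <- atan2(abs(lr), ap) * 180 / pi

  lab <- matrix(0L, n, n)
  par_code <- code_of(paste0("parenchyma_", slice), "mid")
  lab[rn <= 1] <- par_code

  ribbon <- rn <= 1 & rn > geo$ribbon_inner
  for (s in c("left", "right")) {
    lab[ribbon & side_m == s] <- code_of(paste0("GM_", slice), s)
  }
  band <- rn <= geo$ribbon_inner & rn > geo$band_inner
  for (i in seq_len(nrow(geo$sectors))) {
    sec <- band & theta >= geo$sectors$from[i] & theta < geo$sectors$to[i]
    for (s in c("left", "right")) {
      lab[sec & side_m == s] <- code_of(geo$sectors$region[i], s)
    }
  }
  for (stx in geo$structures) {
    sides <- if (stx$bilateral) c(-1, 1) else 0
    for (sg in sides) {
      inside <- ((ap - stx$ap) / stx$s_ap)^2 +
                ((lr - sg * stx$lr) / stx$s_lr)^2 <= 1
      side <- if (!stx$bilateral) "mid" else if (sg < 0) "left" else "right"
      # only claim filler pixels: keeps all region masks disjoint
      lab[inside & lab == par_code] <- code_of(stx$region, side)
    }
  }

  # fill values; parenchyma filler solved from the whole-parenchyma target
  vals <- stats::setNames(truth[lt$region], lt$code)
  par_mask_codes <- region_codes(slice, paste0("parenchyma_", slice))
  counts <- tabulate(lab, nbins = max(lt$code))
  a_tot <- sum(counts[par_mask_codes])
  others <- setdiff(par_mask_codes, par_code)
  s_others <- sum(counts[others] * as.numeric(vals[as.character(others)]))
  vals[as.character(par_code)] <-
    (a_tot * truth[[paste0("parenchyma_", slice)]] - s_others) /
    counts[par_code]

  img <- matrix(-1000, n, n)
  nz <- lab > 0L
  img[nz] <- as.numeric(vals[as.character(lab[nz])])
  if (noise_sd_voxel > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    img[nz] <- img[nz] + stats::rnorm(sum(nz), 0, noise_sd_voxel)
  }

  structure(list(slice = slice, image = img, labels = lab,
                 pixel_spacing = pixel_spacing, label_table = lt,
                 subject_id = subject_id),
            class = "slice_phantom")
}

#' @export
print.slice_phantom <- function(x, ...) {
  cat("slice_phantom", x$slice, ":", nrow(x$image), "x", ncol(x$image),
      "px @", x$pixel_spacing, "mm,", sum(x$labels > 0), "tissue pixels\n")
  invisible(x)
}

#' Write / read a phantom as paired NIfTI files
#'
#' The HU image and the integer label map are stored as
#' `<subject>_<slice>_img.nii.gz` and `<subject>_<slice>_lbl.nii.gz`
#' with the pixel spacing in the NIfTI header.
#'
#' @param phantom A `slice_phantom`.
#' @param dir Output directory (created if absent).
#' @param subject_id Subject id used in the file names (defaults to the
#'   id stored in the phantom).
#' @return `write_phantom()`: invisibly, the two file paths.
#' @export
write_phantom <- function(phantom, dir, subject_id = phantom$subject_id) {
  stopifnot(inherits(phantom, "slice_phantom"))
  if (is.na(subject_id)) stop("subject_id required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0(subject_id, "_", phantom$slice))
  paths <- paste0(base, c("_img.nii.gz", "_lbl.nii.gz"))
  sp <- phantom$pixel_spacing
  img <- array(phantom$image, dim = c(dim(phantom$image), 1))
  attr(img, "pixdim") <- c(sp, sp, 1)
  RNifti::writeNifti(RNifti::asNifti(img), paths[1])
  lbl <- array(phantom$labels, dim = c(dim(phantom$labels), 1))
  attr(lbl, "pixdim") <- c(sp, sp, 1)
  RNifti::writeNifti(RNifti::asNifti(lbl, datatype = "int16"), paths[2])
  invisible(paths)
}

#' @rdname write_phantom
#' @param img_path,lbl_path Paths to the paired NIfTI files.
#' @param slice Slice id of the stored phantom.
#' @return `read_phantom()`: the reconstructed `slice_phantom`.
#' @export
read_phantom <- function(img_path, lbl_path, slice,
                         subject_id = NA_character_) {
  img <- RNifti::readNifti(img_path)
  lbl <- RNifti::readNifti(lbl_path)
  sp <- RNifti::pixdim(img)[1]
  squeeze <- function(x) {
    if (length(dim(x)) == 3) matrix(x[, , 1], dim(x)[1], dim(x)[2])
    else matrix(as.vector(x), dim(x)[1], dim(x)[2])
  }
  im <- squeeze(img)
  lb <- matrix(as.integer(squeeze(lbl)), nrow(im), ncol(im))
  if (!all(dim(im) == dim(lb))) {
    stop("image and label dimensions differ", call. = FALSE)
  }
  slice <- match.arg(slice, c("SL1", "SL2"))
  known <- label_table(slice)$code
  bad <- setdiff(unique(lb[lb > 0L]), known)
  if (length(bad)) {
    stop("label map contains codes not registered for ", slice, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(slice = slice, image = im, labels = lb, pixel_spacing = sp,
                 label_table = label_table(slice), subject_id = subject_id),
            class = "slice_phantom")
}
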