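#' Region registry for the two analysis slices
#'
#' The pipeline measures Hounsfield units on two axial slices: SL1, the
#' basal-ganglia level where the 3rd ventricle is visible, and SL2, the
#' supraventricular level where the bodies of the lateral ventricles are
#' first seen from the vertex. Every measurable anatomical region is
#' registered here with its slice, laterality, and how it is sampled.
#'
#' Regions with `derived = TRUE` (generic `WM_SL1`) carry no label of their
#' own: the measured value is the mean of the anterior (frontal
#' periventricular, WM-fr1) and posterior (posterior limb of the internal
#' capsule, PLIC) white-matter probe values on SL1.
#'
#' @return A data.frame with one row per region: `region`, `slice`
#'   (`"SL1"`/`"SL2"`), `laterality` (`"bilateral"`/`"midline"`), `roi`
#'   and `dot` (logical: measured by the segmented-ROI / circular-DOT
#'   method), and `derived`.
#' @examples
#' region_registry()
#' @export
region_registry <- function() {
  if (!is.null(.registry_cache$regions)) return(.registry_cache$regions)
  r <- function(region, slice, laterality, roi, dot, derived = FALSE) {
    data.frame(region = region, slice = slice, laterality = laterality,
               roi = roi, dot = dot, derived = derived,
               stringsAsFactors = FALSE)
  }
  .registry_cache$regions <- do.call(rbind, list(
    r("parenchyma_SL1",    "SL1", "midline",   TRUE,  FALSE),
    r("ventricle_SL1",     "SL1", "midline",   TRUE,  TRUE),
    r("CN",                "SL1", "bilateral", TRUE,  TRUE),
    r("PT",                "SL1", "bilateral", TRUE,  TRUE),
    r("TM",                "SL1", "bilateral", TRUE,  TRUE),
    r("GM_SL1",            "SL1", "bilateral", TRUE,  TRUE),
    r("WM_SL1_anterior",   "SL1", "bilateral", TRUE,  TRUE),
    r("WM_SL1_posterior",  "SL1", "bilateral", TRUE,  TRUE),
    r("WM_SL1",            "SL1", "bilateral", TRUE,  TRUE, derived = TRUE),
    r("frontal_SL1",       "SL1", "bilateral", TRUE,  FALSE),
    r("temporal_SL1",      "SL1", "bilateral", TRUE,  FALSE),
    r("parietal_SL1",      "SL1", "bilateral", TRUE,  FALSE),
    r("occipital_SL1",     "SL1", "bilateral", TRUE,  FALSE),
    r("parenchyma_SL2",    "SL2", "midline",   TRUE,  FALSE),
    r("ventricle_SL2",     "SL2", "bilateral", TRUE,  TRUE),
    r("GM_SL2",            "SL2", "bilateral", TRUE,  TRUE),
    r("WM_SL2",            "SL2", "bilateral", TRUE,  TRUE),
    r("frontal_SL2",       "SL2", "bilateral", TRUE,  FALSE),
    r("parietal_SL2",      "SL2", "bilateral", TRUE,  FALSE),
    r("occipital_SL2",     "SL2", "bilateral", TRUE,  FALSE)
  ))
  .registry_cache$regions
}

# registries are small constant tables rebuilt on every call otherwise;
# cache them once per session
.registry_cache <- new.env(parent = emptyenv())

#' @rdname region_registry
#' @param slice Slice id, `"SL1"` or `"SL2"`.
#' @export
slice_regions <- function(slice) {
  slice <- match.arg(slice, c("SL1", "SL2"))
  reg <- region_registry()
  reg[reg$slice == slice, , drop = FALSE]
}

region_info <- function(region) {
  reg <- region_registry()
  i <- match(region, reg$region)
  if (is.na(i)) {
    stop("unknown region '", region, "'; see region_registry()", call. = FALSE)
  }
  reg[i, , drop = FALSE]
}

#' Integer label codes used in phantom label maps
#'
#' Each rendered (non-derived) region receives one integer code per side;
#' bilateral regions carry distinct left/right codes, midline regions a
#' single code. Code 0 is background (air and the bone already stripped
#' from the slice). The parenchyma code marks the parenchyma *filler*
#' pixels only; the full parenchyma mask is the union of all tissue codes
#' on the slice excluding the ventricles (ventricles are drawn inside the
#' parenchyma outline but are cerebrospinal fluid, not parenchyma).
#'
#' @param slice Slice id, `"SL1"` or `"SL2"`.
#' @return data.frame with columns `region`, `side`
#'   (`"left"`/`"right"`/`"mid"`), `code`.
#' @export
label_table <- function(slice) {
  slice <- match.arg(slice, c("SL1", "SL2"))
  key <- paste0("labels_", slice)
  if (!is.null(.registry_cache[[key]])) return(.registry_cache[[key]])
  reg <- slice_regions(slice)
  reg <- reg[!reg$derived, , drop = FALSE]
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    sides <- if (reg$laterality[i] == "bilateral") c("left", "right") else "mid"
    data.frame(region = reg$region[i], side = sides, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # offset keeps SL1/SL2 code spaces disjoint so a swapped file is caught
  out$code <- seq_len(nrow(out)) + if (slice == "SL1") 0L else 100L
  .registry_cache[[key]] <- out
  out
}

# codes making up a region's measurable mask (per side)
region_codes <- function(slice, region, side = NULL) {
  lt <- label_table(slice)
  if (region %in% c("parenchyma_SL1", "parenchyma_SL2")) {
    return(lt$code[!grepl("^ventricle", lt$region)])
  }
  sel <- lt$region == region
  if (!is.null(side)) sel <- sel & lt$side == side
  lt$code[sel]
}
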