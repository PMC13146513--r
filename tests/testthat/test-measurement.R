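test_that("roi_mean_hu matches a naive double-loop oracle", {
  # coarse grid keeps the oracle loop small
  ph <- render_phantom(fix_truth(), "SL1", pixel_spacing = 2, n_pixels = 64,
                       noise_sd_voxel = 3, seed = 11)
  lt <- ph$label_table
  naive_mean <- function(codes) {
    tot <- 0; n <- 0
    for (i in seq_len(nrow(ph$image))) {
      for (j in seq_len(ncol(ph$image))) {
        if (ph$labels[i, j] %in% codes) {
          tot <- tot + ph$image[i, j]; n <- n + 1
        }
      }
    }
    tot / n
  }
  for (r in c("CN", "TM", "ventricle_SL1", "parenchyma_SL1")) {
    info <- region_registry()
    codes_l <- lt$code[lt$region == r & lt$side %in% c("left", "mid")]
    codes_r <- lt$code[lt$region == r & lt$side %in% c("right", "mid")]
    if (r == "parenchyma_SL1") {
      expect_equal(roi_mean_hu(ph, r),
                   naive_mean(lt$code[!grepl("^ventricle", lt$region)]),
                   info = r)
    } else if (identical(codes_l, codes_r)) {
      expect_equal(roi_mean_hu(ph, r), naive_mean(codes_l), info = r)
    } else {
      expect_equal(roi_mean_hu(ph, r),
                   (naive_mean(codes_l) + naive_mean(codes_r)) / 2,
                   info = r)
    }
  }
})

test_that("dot_mask equals brute-force pixel-center enumeration", {
  dims <- c(64, 64)
  cases <- list(list(center = c(20, 20), d = 2.4, sp = 0.5),
                list(center = c(20.5, 19.25), d = 2.6, sp = 0.5),
                list(center = c(10, 30), d = 2.8, sp = 0.25))
  for (cs in cases) {
    m <- dot_mask(cs$center, cs$d, cs$sp, dims)
    brute <- NULL
    for (i in seq_len(dims[1])) {
      for (j in seq_len(dims[2])) {
        dmm <- cs$sp * sqrt((i - cs$center[1])^2 + (j - cs$center[2])^2)
        if (dmm <= cs$d / 2) brute <- rbind(brute, c(i, j))
      }
    }
    got <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(brute[order(brute[, 1], brute[, 2]), ,
                                           drop = FALSE]))
  }
})

test_that("dot_mask handles edges and degenerate geometry", {
  # center pixel is always included when centred on a pixel center
  m <- dot_mask(c(5, 5), 2.4, 2, c(64, 64))
  expect_true(any(m[, 1] == 5 & m[, 2] == 5))
  # coarse spacing with an off-center dot covers no pixel centers
  expect_error(dot_mask(c(5.5, 5.5), 2.4, 2.8, c(64, 64)),
               "no pixel centers")
  expect_error(dot_mask(c(1, 1), 2.8, 0.5, c(64, 64)), "outside")
  expect_error(dot_mask(c(5, 5), 3.5, 0.5, c(64, 64)), "2.4")
})

test_that("dot means equal ROI means on noiseless homogeneous regions", {
  ph <- fix_phantoms()
  for (sl in c("SL1", "SL2")) {
    for (d in default_dot_plan(sl)) {
      hu <- dot_mean_hu(ph[[sl]], d)
      expect_equal(hu, roi_mean_hu(ph[[sl]], d$target_region, d$side),
                   tolerance = 1e-9,
                   info = paste(sl, d$target_region, d$side))
    }
  }
})

test_that("a dot overlapping a foreign label raises a contamination error", {
  ph <- fix_phantoms()$SL1
  # a CN-targeted dot parked at image center sits in the 3rd ventricle
  bad <- dot_spec(c(128.5, 128.5), "CN", "left")
  expect_error(dot_mean_hu(ph, bad), "outside its target")
})

test_that("bilateral averaging is the plain arithmetic mean", {
  expect_equal(bilateral_average(30, 32), 31)
  expect_equal(bilateral_average(4.2, 4.2), 4.2)
  expect_equal(bilateral_average(29.3, 30.1), 29.7)
  expect_error(bilateral_average(NA_real_, 2), "finite")
})

test_that("measure_subject fills both method tables completely", {
  tab <- measure_subject(fix_phantoms(), subject_id = "S001")
  roi <- tab[tab$method == "ROI", ]
  dot <- tab[tab$method == "DOT", ]
  reg <- region_registry()
  expect_setequal(roi$region, reg$region[reg$roi])
  expect_setequal(dot$region, reg$region[reg$dot])
  expect_true(all(is.finite(tab$hu)))
  # noiseless: both methods agree with the truth
  tr <- fix_truth()
  expect_equal(dot$hu, unname(tr[dot$region]), tolerance = 1e-9)
  # gray > white > ventricle in the measured table too
  get <- function(m, r) tab$hu[tab$method == m & tab$region == r]
  expect_gt(get("DOT", "GM_SL1"), get("DOT", "WM_SL1"))
  expect_gt(get("DOT", "WM_SL1"), get("DOT", "ventricle_SL1"))
})

test_that("derived WM_SL1 is the mean of the two probe values", {
  md <- fix_measured()
  dot <- md$table[md$table$method == "DOT", ]
  for (s in unique(dot$subject_id)) {
    sub <- dot[dot$subject_id == s, ]
    expect_equal(sub$hu[sub$region == "WM_SL1"],
                 mean(c(sub$hu[sub$region == "WM_SL1_anterior"],
                        sub$hu[sub$region == "WM_SL1_posterior"])))
  }
})
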