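test_that("reference statistics are computed over valid voxels only", {
  vals <- array(39, dim = c(10, 1, 1))
  m <- fake_t2_map(vals)
  roi <- array(TRUE, dim = dim(vals))
  ref <- estimate_reference_stats(m, roi, min_voxels = 5)
  expect_equal(ref$mean, 39)
  expect_equal(ref$sd, 0)
  expect_equal(ref$n, 10L)
  # flagged-invalid voxels are excluded and the count reflects it
  vals2 <- array(c(40, 40, 40, 40, 40, 40, 40, 100, 100, 100),
                 dim = c(10, 1, 1))
  m2 <- fake_t2_map(vals2, invalid = 8:10)
  ref2 <- estimate_reference_stats(m2, roi, min_voxels = 5)
  expect_equal(ref2$mean, 40)
  expect_equal(ref2$n, 7L)
  # too-small ROI errors, naming the floor
  expect_error(estimate_reference_stats(m, roi, min_voxels = 30), "30")
})

test_that("noiseless phantom healthy reference reproduces 39 ms", {
  cfg <- small_config()
  lab <- build_label_volume(cfg, 0)
  s <- simulate_t2prep_series(lab, cfg)
  map <- fit_t2_map(s, class_mask(lab, "myocardium"))
  ref <- estimate_reference_stats(map, reference_roi_mask(lab))
  expect_equal(ref$mean, 39, tolerance = 1e-4)
  expect_lt(ref$sd, 0.01)
})

test_that("a uniform map at the reference mean segments to nothing", {
  vals <- array(39, dim = c(20, 20, 1))
  m <- fake_t2_map(vals)
  region <- array(TRUE, dim = dim(vals))
  seg <- segment_hyperintense(m, reference_stats(39, 0), 3, region)
  expect_equal(sum(seg$mask), 0)
  expect_equal(seg$volume_mL, 0)
})

test_that("hole filling recovers the core enclosed by a suprathreshold rim", {
  # injected in-vivo spread: threshold = 39 + 3 * 5 = 54 ms passes the
  # 58 ms rim but not the 53 ms core; hole filling must recover the
  # core. The rim is generous enough to enclose the lesion here.
  cfg <- small_config(edema = edema_spec(1.3, growth_rate = 0))
  lab <- build_label_volume(cfg, 10)
  s <- simulate_t2prep_series(lab, cfg)
  myo <- class_mask(lab, "myocardium")
  map <- fit_t2_map(s, myo)
  ref <- reference_stats(39, 5)
  seg <- segment_hyperintense(map, ref, 3, myo)
  truth <- class_mask(lab, "edematous_region")
  expect_gte(dice_coefficient(seg$mask, truth), 0.95)
  # only the rim passes the raw threshold; the core arrives via filling
  expect_true(all(seg$raw_mask[class_mask(lab, "lesion")] == FALSE))
  expect_gt(sum(seg$mask & class_mask(lab, "lesion")), 0)
})

test_that("with the measured zero reference SD a noiseless phantom segments exactly", {
  cfg <- small_config(edema = edema_spec(0.77, growth_rate = 0))
  lab <- build_label_volume(cfg, 10)
  myo <- class_mask(lab, "myocardium")
  map <- fit_t2_map(simulate_t2prep_series(lab, cfg), myo)
  ref <- estimate_reference_stats(map, reference_roi_mask(lab))
  expect_lt(ref$sd, 0.01)
  seg <- segment_hyperintense(map, ref, 3, myo)
  expect_gte(dice_coefficient(seg$mask, class_mask(lab, "edematous_region")),
             0.95)
})

test_that("lesion segmentation recovers the core on the long-TI image", {
  cfg <- small_config()
  lab <- build_label_volume(cfg, 10)
  ir <- simulate_ir_series(lab, cfg, TIs = c(400, 600, 831))
  img <- array(ir$data[, , , 3], dim = dim(lab$labels))
  myo <- class_mask(lab, "myocardium")
  ref <- estimate_reference_stats(img, reference_roi_mask(lab))
  seg <- segment_hyperintense(img, ref, 2, myo,
                              spacing_mm = lab$spacing_mm,
                                cleanup = cleanup_params(closing_radius = 0))
  expect_gte(dice_coefficient(seg$mask, class_mask(lab, "lesion")), 0.95)
})

test_that("edema and lesion segmentations achieve Dice >= 0.8 at SNR 30", {
  cfg <- small_config(snr = 30)
  lab <- build_label_volume(cfg, 60)
  myo <- class_mask(lab, "myocardium")
  s <- simulate_t2prep_series(lab, cfg, seed = 17)
  map <- fit_t2_map(s, myo)
  ref <- estimate_reference_stats(map, reference_roi_mask(lab))
  seg <- segment_hyperintense(map, ref, 3, myo)
  expect_gte(dice_coefficient(seg$mask, class_mask(lab, "edematous_region")),
             0.80)
  ir <- simulate_ir_series(lab, cfg, TIs = c(400, 600, 831), seed = 18)
  img <- array(ir$data[, , , 3], dim = dim(lab$labels))
  ref_ir <- estimate_reference_stats(img, reference_roi_mask(lab))
  seg_l <- segment_hyperintense(img, ref_ir, 2, myo,
                                spacing_mm = lab$spacing_mm,
                                cleanup = cleanup_params(closing_radius = 0))
  expect_gte(dice_coefficient(seg_l$mask, class_mask(lab, "lesion")), 0.80)
})

test_that("segmented edema encompasses the segmented lesion (noiseless)", {
  cfg <- small_config()
  lab <- build_label_volume(cfg, 30)
  myo <- class_mask(lab, "myocardium")
  map <- fit_t2_map(simulate_t2prep_series(lab, cfg), myo)
  ref_e <- estimate_reference_stats(map, reference_roi_mask(lab))
  seg_e <- segment_hyperintense(map, ref_e, 3, myo)
  ir <- simulate_ir_series(lab, cfg, TIs = c(831))
  img <- array(ir$data[, , , 1], dim = dim(lab$labels))
  ref_ir <- estimate_reference_stats(img, reference_roi_mask(lab))
  seg_l <- segment_hyperintense(img, ref_ir, 2, myo,
                                spacing_mm = lab$spacing_mm,
                                cleanup = cleanup_params(closing_radius = 0))
  expect_true(all(seg_l$mask[!seg_e$mask] == FALSE))
})

test_that("raising k never grows the raw threshold mask", {
  cfg <- small_config(snr = 30)
  lab <- build_label_volume(cfg, 60)
  myo <- class_mask(lab, "myocardium")
  map <- fit_t2_map(simulate_t2prep_series(lab, cfg, seed = 4), myo)
  ref <- estimate_reference_stats(map, reference_roi_mask(lab))
  prev <- NULL
  for (k in c(1, 2, 3, 4)) {
    seg <- segment_hyperintense(map, ref, k, myo)
    if (!is.null(prev))
      expect_true(all(!seg$raw_mask | prev))   # raw_k subset of raw_{k-1}
    prev <- seg$raw_mask
  }
})

test_that("cleanup is idempotent on its own output", {
  set.seed(12)
  region <- array(TRUE, dim = c(40, 40, 2))
  for (i in 1:5) {
    m <- array(runif(prod(dim(region))) < 0.25, dim = dim(region))
    cl <- cleanup_mask(m, region)
    expect_identical(cleanup_mask(cl, region), cl)
  }
  # and on a realistic segmentation
  cfg <- small_config(snr = 30)
  lab <- build_label_volume(cfg, 60)
  myo <- class_mask(lab, "myocardium")
  map <- fit_t2_map(simulate_t2prep_series(lab, cfg, seed = 9), myo)
  ref <- estimate_reference_stats(map, reference_roi_mask(lab))
  seg <- segment_hyperintense(map, ref, 3, myo)
  expect_identical(cleanup_mask(seg$mask, myo, seg$cleanup), seg$mask)
})

test_that("mask volume is exactly voxel count times voxel volume", {
  m <- array(FALSE, dim = c(20, 20, 5))
  m[1:10, 1:10, 1:5] <- TRUE                    # 10*10*5 = 500 voxels
  expect_equal(compute_volume(m, c(1, 1, 1)), 0.5)
  m2 <- array(FALSE, dim = c(10, 10, 1))
  m2[1:76] <- TRUE
  expect_equal(compute_volume(m2, c(1.3, 1.3, 6)), 76 * 10.14 / 1000)
  expect_equal(compute_volume(array(FALSE, c(4, 4, 1)), c(1, 1, 1)), 0)
})

test_that("transmurality matches the configured lesion depth", {
  cfg <- small_config(lesion = lesion_spec(angle_deg = 40,
                                           depth_fraction = 0.52),
                      edema = edema_spec(0.9, 0))
  lab <- build_label_volume(cfg, 0)
  tm <- measure_transmurality(class_mask(lab, "lesion"), lab$contours,
                              lab$spacing_mm)
  expect_lt(abs(tm$max - 0.52), 0.05)
  # a full-thickness sector reads ~1
  cfg2 <- small_config(lesion = lesion_spec(width_mm = 10,
                                            depth_fraction = 1,
                                            shape = "sector"),
                       edema = edema_spec(3, 0))
  lab2 <- build_label_volume(cfg2, 0)
  tm2 <- measure_transmurality(class_mask(lab2, "lesion"), lab2$contours,
                               lab2$spacing_mm)
  expect_gt(tm2$max, 0.92)
  expect_lte(tm2$max, 1.05)
  # analytic sector depth at intermediate depth fraction
  cfg3 <- small_config(lesion = lesion_spec(width_mm = 14,
                                            depth_fraction = 0.75,
                                            shape = "sector"),
                       edema = edema_spec(3, 0))
  lab3 <- build_label_volume(cfg3, 0)
  tm3 <- measure_transmurality(class_mask(lab3, "lesion"), lab3$contours,
                               lab3$spacing_mm)
  expect_lt(abs(tm3$max - 0.75), 1.3 / 8)       # within one voxel of depth
  # an empty mask is flagged undefined
  tm4 <- measure_transmurality(array(FALSE, dim(lab$labels)),
                               lab$contours, lab$spacing_mm)
  expect_true(is.na(tm4$max))
})

test_that("wall thickness is the radial endo-epi distance", {
  ct <- lv_contours(c(40, 40), 25, 33)
  for (ang in c(0, 45, 120, 300))
    expect_equal(measure_wall_thickness(ct, ang), 8)
})

test_that("mask diameter matches analytic geometry", {
  # disk of radius 5 mm on a 0.5 mm grid
  n <- 60
  sp <- c(0.5, 0.5, 6)
  x <- (seq_len(n) - 1) * sp[1]
  ctr <- x[n / 2]
  disk <- array(outer(x, x, function(a, b) sqrt((a - ctr)^2 + (b - ctr)^2)) <= 5,
                dim = c(n, n, 1))
  d <- measure_diameter(disk, sp)
  expect_lt(abs(d$diameter_mm - 10), 2 * sp[1] + 1e-9)
  # rotated ellipse: major axis 16 mm at 30 degrees
  th <- 30 * pi / 180
  ell <- array(FALSE, dim = c(n, n, 1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- (x[i] - ctr) * cos(th) + (x[j] - ctr) * sin(th)
    v <- -(x[i] - ctr) * sin(th) + (x[j] - ctr) * cos(th)
    ell[i, j, 1] <- (u / 8)^2 + (v / 3)^2 <= 1
  }
  de <- measure_diameter(ell, sp)
  expect_lt(abs(de$diameter_mm - 16), 2 * sp[1] + 1e-9)
  # empty mask flagged
  de0 <- measure_diameter(array(FALSE, c(4, 4, 1)), sp)
  expect_true(de0$flagged)
})
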