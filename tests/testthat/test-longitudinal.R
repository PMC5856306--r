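make_table <- function(volumes, times, lesion = 1L, animal = 1L,
                       contrast = "T2-edema") {
  tibble::tibble(animal_id = animal, lesion_id = lesion,
                 contrast = contrast, t_min = times, volume_mL = volumes)
}

test_that("baseline normalization divides by the earliest volume", {
  tbl <- make_table(c(0.5, 0.6, 0.75), c(10, 60, 120))
  out <- normalize_to_baseline(tbl)
  expect_equal(out$normalized_volume, c(1, 1.2, 1.5))
  # single observation normalizes to exactly 1
  out1 <- normalize_to_baseline(make_table(0.4, 25))
  expect_identical(out1$normalized_volume, 1)
  # tied baseline times resolve to the first row, with a message
  tbl2 <- make_table(c(0.5, 0.25, 0.75), c(10, 10, 120))
  expect_message(out2 <- normalize_to_baseline(tbl2), "tied")
  expect_equal(out2$normalized_volume, c(1, 0.5, 1.5))
  # zero baseline is an error
  expect_error(normalize_to_baseline(make_table(c(0, 1), c(5, 50))),
               "positive")
})

test_that("the mixed model recovers exact linear data", {
  t <- c(10, 50, 90, 130, 180)
  tbl <- dplyr::bind_rows(lapply(1:5, function(a)
    make_table(1.2 + 0.003 * t, t, lesion = a, animal = a)))
  tbl$normalized_volume <- tbl$volume_mL
  fit <- suppressMessages(fit_lmm(tbl))
  expect_equal(fit$beta0, 1.2, tolerance = 1e-6)
  expect_equal(fit$beta1, 0.003, tolerance = 1e-6)
  expect_lt(fit$var_animal, 1e-8)
  expect_equal(fit$n_lesions, 5L)
})

test_that("degenerate designs are refused with explicit errors", {
  t <- c(10, 90, 180)
  one_animal <- dplyr::bind_rows(lapply(1:4, function(l)
    make_table(1 + 0.01 * t, t, lesion = l, animal = 1L)))
  one_animal$normalized_volume <- one_animal$volume_mL
  expect_error(fit_lmm(one_animal), "2 animals")
  two_lesions <- dplyr::bind_rows(lapply(1:2, function(l)
    make_table(1 + 0.01 * t, t, lesion = l, animal = l)))
  two_lesions$normalized_volume <- two_lesions$volume_mL
  expect_error(fit_lmm(two_lesions), "3 lesions")
})

test_that("with null animal variance the fixed effects match OLS", {
  set.seed(88)
  t_all <- c(); y_all <- c()
  rows <- lapply(1:8, function(l) {
    t <- sort(runif(4, 10, 180))
    y <- 1.1 + 0.002 * t + rnorm(4, 0, 0.05)   # no animal effect at all
    make_table(y, t, lesion = l, animal = l)
  })
  tbl <- dplyr::bind_rows(rows)
  tbl$normalized_volume <- tbl$volume_mL
  fit <- suppressMessages(fit_lmm(tbl))
  ols <- lm(normalized_volume ~ t_min, data = tbl)
  if (fit$var_animal < 1e-10) {
    expect_equal(fit$beta0, unname(coef(ols)[1]), tolerance = 1e-6)
    expect_equal(fit$beta1, unname(coef(ols)[2]), tolerance = 1e-6)
  } else {
    skip("animal variance not estimated at the boundary for this draw")
  }
})

test_that("slope recovery is unbiased over repeated simulated studies", {
  nsim <- 40
  slopes <- numeric(nsim)
  for (i in seq_len(nsim)) {
    tbl <- simulate_lmm_study(seed = 1000 + i)
    slopes[i] <- suppressMessages(fit_lmm(tbl))$beta1
  }
  mc_se <- sd(slopes) / sqrt(nsim)
  expect_lt(abs(mean(slopes) - 0.003), 2 * mc_se)
})

test_that("population predictions reproduce the printed model estimates", {
  fit_e <- structure(list(beta0 = 1.20, beta1 = 0.003), class = "lmm_fit")
  expect_equal(predict_fixed(fit_e, 180), 1.74)
  expect_equal(round(predict_fixed(fit_e, 180), 1), 1.7)
  fit_l <- structure(list(beta0 = 1.01, beta1 = -0.0006), class = "lmm_fit")
  expect_equal(predict_fixed(fit_l, 180), 0.902)
  expect_equal(round(predict_fixed(fit_l, 180), 1), 0.9)
  expect_equal(predict_fixed(fit_e, 0), 1.20)
  # affine in t
  tt <- c(0, 60, 120, 180)
  expect_equal(diff(predict_fixed(fit_e, tt)), rep(0.003 * 60, 3))
})

test_that("interval ratios summarize matched pairs correctly", {
  # identical tables give unit ratios and a non-significant test
  e <- dplyr::bind_rows(lapply(1:4, function(l)
    make_table(c(0.8, 1.0), c(12, 70), lesion = l)))
  out <- interval_ratio(e, e)
  expect_true(all(out$pairs$ratio == 1))
  expect_true(all(out$summary$p_greater_than_1 >= 0.99))
  # constant ratios of 2: mean 2, sd 0, decisively greater than 1
  l <- e; l$volume_mL <- e$volume_mL / 2
  out2 <- interval_ratio(e, l)
  expect_equal(out2$summary$mean, rep(2, nrow(out2$summary)))
  expect_equal(out2$summary$sd, rep(0, nrow(out2$summary)))
  expect_true(all(out2$summary$p_greater_than_1 < 0.05))
  # scale invariance
  e2 <- e; e2$volume_mL <- e2$volume_mL * 3.7
  l2 <- l; l2$volume_mL <- l2$volume_mL * 3.7
  out3 <- interval_ratio(e2, l2)
  expect_equal(out3$pairs$ratio, out2$pairs$ratio)
})

test_that("pairs match nearest in time and sparse intervals are dropped", {
  e <- make_table(c(1.0, 1.2), c(10, 24))
  l <- make_table(c(0.5, 0.6), c(12, 23), contrast = "T1-lesion")
  out <- suppressMessages(interval_ratio(e, l))
  # one pair per lesion-interval, matched nearest in time (24 vs 23)
  expect_equal(nrow(out$pairs), 1L)
  expect_equal(out$pairs$t_edema, 24)
  expect_equal(out$pairs$t_lesion, 23)
  expect_equal(out$pairs$ratio, 1.2 / 0.6)
  # a single-pair interval is excluded from the summary with a message
  expect_message(interval_ratio(e, l), "excluded")
  expect_equal(nrow(out$summary), 0L)
  # observations in the 25-60 min gap belong to no interval
  e2 <- make_table(c(1, 1.1, 1.2, 1.3), c(10, 40, 70, 100), lesion = 2L)
  l2 <- make_table(c(0.5, 0.55, 0.6, 0.6), c(11, 41, 71, 101),
                   lesion = 2L, contrast = "T1-lesion")
  out2 <- suppressMessages(interval_ratio(e2, l2))
  expect_false(40 %in% out2$pairs$t_edema)
})

test_that("ROI time courses recover scheduled phantom T2 within 1 ms", {
  cfg <- small_config(t2_schedule = default_t2_schedule())
  maps <- list(); times <- c(10, 70, 120)
  lab0 <- build_label_volume(cfg, times[1])
  myo <- class_mask(lab0, "myocardium")
  masks <- list(healthy = reference_roi_mask(lab0),
                lesion = class_mask(lab0, "lesion"),
                edema = class_mask(lab0, "edema_rim"))
  for (i in seq_along(times)) {
    lab <- build_label_volume(cfg, times[i])
    maps[[i]] <- fit_t2_map(simulate_t2prep_series(lab, cfg), myo)
  }
  tc <- roi_t2_timecourse(maps, times, masks)
  stats_e <- tc[tc$region == "edema", ]
  expect_equal(stats_e$mean_t2[match(c("0-25", "60-80", "80-185"),
                                     stats_e$interval)],
               c(53, 58, 56), tolerance = 1 / 53)
  stats_l <- tc[tc$region == "lesion", ]
  expect_equal(stats_l$mean_t2[match(c("0-25", "60-80", "80-185"),
                                     stats_l$interval)],
               c(53, 55, 53), tolerance = 1 / 53)
  expect_true(all(abs(tc$mean_t2[tc$region == "healthy"] - 39) < 0.1))
  # a hand-computed 3-voxel ROI mean matches
  vals <- array(c(50, 60, 70, rep(40, 22)), dim = c(5, 5, 1))
  m3 <- fake_t2_map(vals)
  roi3 <- array(FALSE, dim = dim(vals)); roi3[1:3] <- TRUE
  expect_equal(roi_mean_t2(m3, roi3), 60)
})

test_that("time-course aggregation flags changes and non-changes", {
  # deterministic pattern with zero mean interval differences per
  # lesion: paired tests must not flag a change
  rows <- list()
  for (les in 1:6) for (ii in 1:3) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      lesion_id = les, t_min = c(12, 70, 120)[ii], interval = NA,
      region = "edema",
      mean_t2 = 50 + 0.3 * les + 0.2 * ((les %% 3) - 1) * (ii - 2))
  }
  smp <- dplyr::bind_rows(rows)
  smp$interval <- rflesion:::assign_interval(smp$t_min)
  out <- t2_timecourse_stats(smp)
  expect_true(all(is.na(out$tests$p) | out$tests$p > 0.5))
  # a genuine step change is detected
  smp2 <- smp
  step <- smp2$interval == "60-80"
  smp2$mean_t2[step] <- smp2$mean_t2[step] + 8
  out2 <- t2_timecourse_stats(smp2)
  p_step <- out2$tests$p[grepl("0-25 vs 60-80", out2$tests$comparison)]
  expect_true(all(p_step < 0.01))
})

test_that("Bland-Altman agreement behaves per definition", {
  b <- bland_altman(c(1, 2, 3), c(0.9, 2.1, 2.9))
  expect_equal(b$bias, mean(c(0.1, -0.1, 0.1)), tolerance = 1e-12)
  expect_equal(b$sd_diff, sd(c(0.1, -0.1, 0.1)))
  expect_equal(b$loa, b$bias + c(-1.96, 1.96) * b$sd_diff)
  # identical inputs: zero bias, degenerate limits, p undefined
  b0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(b0$bias, 0)
  expect_equal(b0$loa, c(0, 0))
  expect_true(is.na(b0$p))
  # antisymmetry
  b2 <- bland_altman(c(0.9, 2.1, 2.9), c(1, 2, 3))
  expect_equal(b2$bias, -b$bias)
  expect_equal(b2$loa, rev(-b$loa))
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("correlation handles monotone nonlinearity and degeneracy", {
  x <- 1:10
  y <- exp(x / 2)
  expect_equal(correlate_volumes(x, y, "spearman")$r, 1)
  expect_lt(correlate_volumes(x, y, "pearson")$r, 1)
  p <- correlate_volumes(x, 2 * x + 1, "pearson")
  expect_equal(p$slope, 2, tolerance = 1e-10)
  expect_equal(p$intercept, 1, tolerance = 1e-10)
  expect_true(correlate_volumes(rep(1, 5), 1:5)$flagged)
})
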