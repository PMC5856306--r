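#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis: study
#' design, phantom template, acquisition schedules, segmentation
#' thresholds and cleanup, statistical options, and the master seed.
#' With the master seed fixed the whole run is deterministic.
#'
#' @param n_lesions,n_animals,times_per_lesion study design passed to
#'   [generate_study()].
#' @param times optional list of per-lesion imaging times (min).
#' @param base_config template [phantom_config()].
#' @param edema_baseline,lesion_volume `c(mean, sd)` (mL) of the true
#'   volume distributions across lesions.
#' @param TEs,TIs acquisition schedules (ms).
#' @param ir_select_ti the lesion is segmented on the first IR image
#'   with TI at or above this value (ms).
#' @param interp_matrix in-plane matrix size images are interpolated to
#'   before fitting and segmentation, for data that carry a real
#'   acquisition point-spread. The default `NULL` keeps the whole chain
#'   on the acquisition grid: phantom tissue is piecewise constant, so
#'   interpolation would only manufacture artificial partial-volume
#'   mixtures that a signal-intensity threshold then misclassifies.
#' @param k_edema,k_lesion SD multipliers for the T2-edema and
#'   T1-lesion thresholds.
#' @param cleanup a [cleanup_params()] for the edema channel; the
#'   default closing bridges noise gaps in the thin suprathreshold rim.
#' @param cleanup_lesion a [cleanup_params()] for the lesion channel;
#'   the lesion core is a compact blob, so no closing is applied there
#'   (at the liberal 2 SD threshold a closing would fuse scattered
#'   noise voxels into retained components).
#' @param ref_sd_t2,ref_sd_ir optional injected reference SDs (ms /
#'   signal units) used in place of the measured ROI SD; keeps the SD
#'   thresholds meaningful on noiseless runs.
#' @param intervals analysis windows for ratios and time courses.
#' @param predict_at time (min) for the population LMM prediction.
#' @param stages subset of `c("segment", "analyze")`; dropping
#'   `"analyze"` omits the statistics section from the report.
#' @param seed master seed.
#' @param out_dir optional directory for stage artifacts (report JSON,
#'   volume CSV, per-acquisition NIfTI when `write_images = TRUE`).
#' @param write_images write simulated series and label maps as NIfTI.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_lesions = 13, n_animals = 11,
                            times_per_lesion = 5, times = NULL,
                            base_config = phantom_config(snr = 30),
                            edema_baseline = c(0.77, 0.55),
                            lesion_volume = c(0.48, 0.23),
                            TEs = c(3, 25, 75, 184),
                            TIs = c(400, 600, 831),
                            ir_select_ti = 700,
                            interp_matrix = NULL,
                            k_edema = 3, k_lesion = 2,
                            cleanup = cleanup_params(),
                            cleanup_lesion = cleanup_params(closing_radius = 0),
                            ref_sd_t2 = NULL, ref_sd_ir = NULL,
                            intervals = default_intervals(),
                            predict_at = 180,
                            stages = c("segment", "analyze"),
                            seed = 1, out_dir = NULL,
                            write_images = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

## nearest-neighbour interpolation of a logical 3D mask to a target
## in-plane matrix
interp_mask3d <- function(mask, target) {
  d <- dim(mask)
  out <- array(FALSE, dim = c(target, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- interpolate_to_matrix(mask[, , k] * 1, target,
                                        method = "nearest")$image > 0.5
  out
}

interp_series_or_not <- function(series, target) {
  if (is.null(target)) series else interpolate_series(series, target)
}

#' Run the end-to-end lesion assessment pipeline
#'
#' Executes simulate, fit, segment and analyze in order: generates the
#' synthetic study, fits T2 maps, segments the T2-derived edematous
#' region (`mean + k_edema * SD` of healthy T2) and the T1-derived
#' lesion (`k_lesion` SDs above healthy signal on the long-TI IR
#' image), assembles the longitudinal volume table, and fits the
#' mixed-model and interval statistics. A stage failure aborts with the
#' stage name; partial artifacts written so far are preserved.
#'
#' @param pc a [pipeline_config()].
#' @return A report list: `volumes` (longitudinal table), per-contrast
#'   `lmm` fits with predictions, `ratios`, `t2_timecourse`,
#'   `transmurality`, and run metadata (`seed`, parameters).
#' @export
run_pipeline <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(pc$out_dir))
    dir.create(pc$out_dir, recursive = TRUE, showWarnings = FALSE)

  study <- stage("simulate", generate_study(
    n_lesions = pc$n_lesions, n_animals = pc$n_animals,
    times = pc$times, times_per_lesion = pc$times_per_lesion,
    edema_baseline = pc$edema_baseline, lesion_volume = pc$lesion_volume,
    base_config = pc$base_config, TEs = pc$TEs, TIs = pc$TIs,
    seed = pc$seed))

  vol_rows <- list()
  tc_samples <- list()
  trans <- c()
  for (les in study$lesions) {
    maps <- list()
    edema_masks <- list()
    lesion_mask_baseline <- NULL
    ref_mask_i <- healthy_mask_i <- myo_i <- NULL
    contours <- les$acquisitions[[1]]$label$contours
    spacing_i <- NULL
    for (j in seq_along(les$acquisitions)) {
      acq <- les$acquisitions[[j]]
      label <- acq$label
      myo <- class_mask(label, "myocardium")
      refm <- reference_roi_mask(label)
      healthy <- class_mask(label, "healthy")
      if (!is.null(pc$interp_matrix)) {
        myo <- interp_mask3d(myo, pc$interp_matrix)
        refm <- interp_mask3d(refm, pc$interp_matrix)
        healthy <- interp_mask3d(healthy, pc$interp_matrix)
      }
      if (j == 1) { myo_i <- myo; ref_mask_i <- refm; healthy_mask_i <- healthy }

      ## --- T2 branch: map, reference stats, edema segmentation
      t2series <- interp_series_or_not(acq$t2prep, pc$interp_matrix)
      map <- stage("fit-t2", fit_t2_map(t2series, mask = myo))
      spacing_i <- map$spacing_mm
      ref <- stage("segment", estimate_reference_stats(map, refm))
      if (!is.null(pc$ref_sd_t2))
        ref <- reference_stats(ref$mean, pc$ref_sd_t2, ref$n)
      seg_e <- stage("segment", segment_hyperintense(
        map, ref, pc$k_edema, myo, cleanup = pc$cleanup))
      maps[[j]] <- map
      edema_masks[[j]] <- seg_e$mask
      vol_rows[[length(vol_rows) + 1L]] <- tibble(
        animal_id = les$animal_id, lesion_id = les$lesion_id,
        contrast = "T2-edema", t_min = acq$t_min,
        volume_mL = seg_e$volume_mL, threshold = seg_e$threshold)

      ## --- IR branch: long-TI image, lesion segmentation
      if (!is.null(acq$ir)) {
        sel <- which(acq$ir$values >= pc$ir_select_ti)
        if (length(sel) == 0)
          stop("pipeline stage 'segment' failed: no IR image with TI >= ",
               pc$ir_select_ti, " ms", call. = FALSE)
        irs <- interp_series_or_not(acq$ir, pc$interp_matrix)
        ir_img <- array(irs$data[, , , sel[1]], dim = dim(irs$data)[1:3])
        ref_ir <- stage("segment", estimate_reference_stats(ir_img, refm))
        if (!is.null(pc$ref_sd_ir))
          ref_ir <- reference_stats(ref_ir$mean, pc$ref_sd_ir, ref_ir$n)
        seg_l <- stage("segment", segment_hyperintense(
          ir_img, ref_ir, pc$k_lesion, myo, cleanup = pc$cleanup_lesion,
          spacing_mm = irs$spacing_mm))
        vol_rows[[length(vol_rows) + 1L]] <- tibble(
          animal_id = les$animal_id, lesion_id = les$lesion_id,
          contrast = "T1-lesion", t_min = acq$t_min,
          volume_mL = seg_l$volume_mL, threshold = seg_l$threshold)
        if (j == 1) {
          lesion_mask_baseline <- seg_l$mask
          tm <- measure_transmurality(seg_l$mask, contours,
                                      irs$spacing_mm)
          trans <- c(trans, tm$max)
        }
      }
      if (!is.null(pc$out_dir) && pc$write_images) {
        pfx <- file.path(pc$out_dir,
                         sprintf("lesion%02d_t%03d", les$lesion_id,
                                 round(acq$t_min)))
        write_image_series(acq$t2prep, paste0(pfx, "_t2prep"),
                           extra = list(lesion_id = les$lesion_id,
                                        animal_id = les$animal_id))
        if (!is.null(acq$ir))
          write_image_series(acq$ir, paste0(pfx, "_ir"),
                             extra = list(lesion_id = les$lesion_id,
                                          animal_id = les$animal_id))
        write_label_volume(label, paste0(pfx, "_labels"))
      }
    }
    ## frozen ROIs for the T2 time course: healthy reference sector,
    ## baseline lesion segmentation, and the largest edematous
    ## segmentation with the lesion core excluded (the two injury ROIs
    ## are reported separately, and the edematous region always
    ## encompasses the lesion)
    if ("analyze" %in% pc$stages && length(maps) > 0) {
      biggest <- which.max(vapply(edema_masks, sum, numeric(1)))
      rois <- list(healthy = ref_mask_i)
      if (!is.null(lesion_mask_baseline) && sum(lesion_mask_baseline) > 0)
        rois$lesion <- lesion_mask_baseline
      edema_roi <- edema_masks[[biggest]]
      if (!is.null(lesion_mask_baseline))
        edema_roi <- edema_roi & !lesion_mask_baseline
      if (sum(edema_roi) > 0)
        rois$edema <- edema_roi
      tc_samples[[length(tc_samples) + 1L]] <- roi_t2_timecourse(
        maps, les$times, rois, pc$intervals, lesion_id = les$lesion_id)
    }
  }
  volumes <- bind_rows(vol_rows)
  report <- list(seed = study$seed,
                 n_lesions = pc$n_lesions, n_animals = pc$n_animals,
                 truth = study$truth, volumes = volumes,
                 transmurality = if (length(trans))
                   list(per_lesion = trans, mean = mean(trans, na.rm = TRUE))
                 else NULL)

  if ("analyze" %in% pc$stages) {
    report <- c(report, stage("analyze", {
      volumes_n <- normalize_to_baseline(volumes)
      lmm <- list()
      for (ct in unique(volumes_n$contrast)) {
        fit <- tryCatch(fit_lmm(volumes_n, contrast = ct),
                        error = function(e) conditionMessage(e))
        lmm[[ct]] <- if (inherits(fit, "lmm_fit")) {
          list(beta0 = fit$beta0, beta0_se = fit$beta0_se,
               beta1 = fit$beta1, beta1_se = fit$beta1_se,
               beta1_p = fit$beta1_p, var_animal = fit$var_animal,
               var_resid = fit$var_resid,
               predicted = setNames(predict_fixed(fit, pc$predict_at),
                                    paste0("t", pc$predict_at)))
        } else list(skipped = fit)
      }
      ratios <- interval_ratio(
        volumes[volumes$contrast == "T2-edema", ],
        volumes[volumes$contrast == "T1-lesion", ], pc$intervals)
      tc <- if (length(tc_samples))
        t2_timecourse_stats(bind_rows(tc_samples)) else NULL
      list(volumes_normalized = volumes_n, lmm = lmm,
           ratios = ratios[c("summary", "anova_p")],
           t2_timecourse = tc)
    }))
  }

  if (!is.null(pc$out_dir)) {
    write_volume_table(volumes, file.path(pc$out_dir, "volumes.csv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(pc$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

## flatten a pipeline report into JSON-friendly structures
report_to_json <- function(report) {
  conv <- function(x) {
    if (inherits(x, "data.frame")) return(as.list(as.data.frame(x)))
    if (is.list(x)) return(lapply(x, conv))
    x
  }
  conv(report)
}
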