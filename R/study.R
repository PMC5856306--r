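#' Solve the teardrop width that yields a target lesion-core volume
#'
#' Bisects the lesion surface width until the rasterized lesion-core
#' volume matches the target to the nearest voxel. The through-slice
#' height is scaled with the width (keeping the teardrop's aspect)
#' unless the configuration fixes it.
#'
#' @param config a [phantom_config()]; its lesion depth fraction, angle
#'   and shape are kept.
#' @param target_mL desired lesion-core volume (mL).
#' @param w_range search bracket for the width (mm).
#' @return width in mm.
#' @export
lesion_width_for_volume <- function(config, target_mL, w_range = c(2, 60)) {
  assert_scalar_pos(target_mL, "target_mL")
  coords <- grid_coords(config)
  myo <- coords$r >= config$r_endo_mm & coords$r < config$r_epi_mm
  vox_mm3 <- prod(c(config$spacing_mm, config$slice_thickness_mm))
  count_for <- function(w) {
    cfg <- config
    cfg$lesion$width_mm <- w
    cfg$lesion$height_mm <- w
    sum(rasterize_lesion(cfg, coords, myo, width_mm = w))
  }
  target_n <- round(target_mL * 1000 / vox_mm3)
  lo <- w_range[1]; hi <- w_range[2]
  if (count_for(hi) < target_n)
    stop("target lesion volume is not reachable within the width bracket",
         call. = FALSE)
  if (count_for(lo) > target_n)
    stop("target lesion volume is smaller than the narrowest lesion in ",
         "the width bracket", call. = FALSE)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (count_for(mid) < target_n) lo <- mid else hi <- mid
    if (hi - lo < 0.005) break
  }
  ## the voxel count is a step function of width; scan the bracket
  ## neighbourhood and return the width whose count is closest
  ws <- seq(max(w_range[1], hi - 0.3), min(w_range[2], hi + 0.3),
            by = 0.01)
  counts <- vapply(ws, count_for, numeric(1))
  ws[which.min(abs(counts - target_n))]
}

## moment-matched lognormal draws for positive volume distributions;
## "stratified" takes the n mid-probability quantiles so a small study
## represents the target distribution without Monte-Carlo mean drift
draw_volumes <- function(n, mean, sd, draw = c("stratified", "random")) {
  draw <- match.arg(draw)
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  if (draw == "stratified") {
    qlnorm((seq_len(n) - 0.5) / n, meanlog, sqrt(sdlog2))
  } else {
    stats::rlnorm(n, meanlog, sqrt(sdlog2))
  }
}

#' Generate a multi-lesion imaging study
#'
#' Builds a reproducible synthetic study mirroring the in-vivo design:
#' lesions clustered in animals (two animals carry two lesions when 13
#' lesions are spread over 11 animals), each lesion imaged at several
#' times post-ablation with T2-prepared and/or inversion-recovery
#' series. Per-lesion true lesion-core and baseline edematous-region
#' volumes are drawn from moment-matched lognormal distributions about
#' the study means and realized geometrically (the teardrop width is
#' calibrated per lesion; the edema rim is grown to the target volume).
#'
#' @param n_lesions,n_animals study design.
#' @param lesion_ids optional identifiers; duplicates are rejected.
#' @param times list of per-lesion time vectors (min), or `NULL` to
#'   draw: a baseline time in `baseline_window` plus
#'   `times_per_lesion - 1` times up to `t_max`.
#' @param times_per_lesion number of imaging times per lesion.
#' @param baseline_window window (min) for the earliest imaging time.
#' @param t_max latest imaging time (min); times must lie in 0-250 min.
#' @param edema_baseline `c(mean, sd)` (mL) of the true baseline
#'   edematous-region volume across lesions.
#' @param edema_ratio if non-`NULL`, overrides `edema_baseline`: each
#'   lesion's baseline edematous-region volume is set to `edema_ratio`
#'   times its rasterized lesion-core volume, so the true baseline
#'   edema-to-lesion ratio is exactly this value.
#' @param lesion_volume `c(mean, sd)` (mL) of the true lesion-core
#'   volume across lesions.
#' @param draw `"stratified"` (default; mid-probability quantiles) or
#'   `"random"` lognormal draws.
#' @param base_config template [phantom_config()]; per-lesion configs
#'   vary the lesion angle, width and edema baseline.
#' @param TEs,TIs acquisition schedules (ms).
#' @param simulate which series to simulate: subset of
#'   `c("t2prep", "ir")`; empty to generate labels only.
#' @param seed master seed; two runs with the same master seed produce
#'   identical truth and voxel data.
#' @return A `lesion_study`: list with `lesions` (per-lesion config,
#'   times and acquisitions, each acquisition holding the label volume
#'   and simulated series) and a `truth` tibble (animal_id, lesion_id,
#'   t_min, class, volume_mL).
#' @export
generate_study <- function(n_lesions = 13, n_animals = 11,
                           lesion_ids = NULL,
                           times = NULL, times_per_lesion = 5,
                           baseline_window = c(5, 15), t_max = 180,
                           edema_baseline = c(0.77, 0.55),
                           edema_ratio = NULL,
                           lesion_volume = c(0.48, 0.23),
                           draw = c("stratified", "random"),
                           base_config = phantom_config(),
                           TEs = c(3, 25, 75, 184),
                           TIs = c(400, 600, 831),
                           simulate = c("t2prep", "ir"),
                           seed = 1) {
  draw <- match.arg(draw)
  lesion_ids <- lesion_ids %||% seq_len(n_lesions)
  if (anyDuplicated(lesion_ids))
    stop("duplicate lesion identifiers", call. = FALSE)
  stopifnot(length(lesion_ids) == n_lesions, n_animals >= 1)
  if (!is.null(times)) {
    stopifnot(length(times) == n_lesions)
    if (any(unlist(times) < 0 | unlist(times) > 250))
      stop("imaging times must lie within 0-250 min", call. = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    animal <- ((seq_len(n_lesions) - 1) %% n_animals) + 1L
    v_les <- sort(draw_volumes(n_lesions, lesion_volume[1],
                               lesion_volume[2], draw))
    v_ed <- sort(draw_volumes(n_lesions, edema_baseline[1],
                              edema_baseline[2], draw))
    ## the edematous region must encompass the lesion core with a rim
    v_ed <- pmax(v_ed, 1.15 * v_les)
    angles <- runif(n_lesions, 0, 360)
    if (is.null(times)) {
      times <- lapply(seq_len(n_lesions), function(i) {
        t0 <- runif(1, baseline_window[1], baseline_window[2])
        extra <- if (times_per_lesion > 1)
          sort(runif(times_per_lesion - 1, baseline_window[2] + 5, t_max))
        else numeric(0)
        c(t0, extra)
      })
    }
    sim_seeds <- matrix(sample.int(2^31 - 2, n_lesions * 2),
                        nrow = n_lesions)

    lesions <- vector("list", n_lesions)
    truth_rows <- list()
    for (i in seq_len(n_lesions)) {
      cfg <- base_config
      cfg$lesion$angle_deg <- angles[i]
      w <- lesion_width_for_volume(cfg, v_les[i])
      cfg$lesion$width_mm <- w
      cfg$lesion$height_mm <- w
      if (!is.null(edema_ratio)) {
        ## calibrate to the rasterized core so the true ratio is exact
        coords_i <- grid_coords(cfg)
        myo_i <- coords_i$r >= cfg$r_endo_mm & coords_i$r < cfg$r_epi_mm
        core_mL <- sum(rasterize_lesion(cfg, coords_i, myo_i)) *
          prod(c(cfg$spacing_mm, cfg$slice_thickness_mm)) / 1000
        v_ed[i] <- edema_ratio * core_mL
      }
      cfg$edema$baseline_volume_mL <- v_ed[i]
      cfg$seed <- sim_seeds[i, 1]
      acq <- vector("list", length(times[[i]]))
      for (j in seq_along(times[[i]])) {
        t <- times[[i]][j]
        label <- build_label_volume(cfg, t)
        a <- list(t_min = t, label = label)
        if ("t2prep" %in% simulate)
          a$t2prep <- simulate_t2prep_series(label, cfg, TEs,
                                             seed = sim_seeds[i, 1] + j)
        if ("ir" %in% simulate)
          a$ir <- simulate_ir_series(label, cfg, TIs,
                                     seed = sim_seeds[i, 2] + j)
        acq[[j]] <- a
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          animal_id = animal[i], lesion_id = lesion_ids[i], t_min = t,
          class = c("lesion", "edematous_region"),
          volume_mL = c(label$truth$lesion, label$truth$edematous_region))
      }
      lesions[[i]] <- list(animal_id = animal[i],
                           lesion_id = lesion_ids[i],
                           config = cfg, times = times[[i]],
                           true_lesion_mL = v_les[i],
                           true_edema_baseline_mL = v_ed[i],
                           acquisitions = acq)
    }
    structure(list(lesions = lesions, truth = bind_rows(truth_rows),
                   n_animals = n_animals, seed = as.integer(seed)),
              class = "lesion_study")
  })
}

#' @export
print.lesion_study <- function(x, ...) {
  n_acq <- sum(vapply(x$lesions, function(l) length(l$acquisitions),
                      integer(1)))
  cat("<lesion_study> ", length(x$lesions), " lesions in ", x$n_animals,
      " animals, ", n_acq, " acquisitions (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
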