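#' Tissue relaxometry table
#'
#' Default relaxation parameters for the four tissue classes of the
#' short-axis phantom at 1.5 T. Healthy myocardium T2 is set to the
#' in-vivo value typical of swine LV (39 ms); the lesion core and edema
#' rim carry the elevated T2 seen around acute ablation sites, and the
#' lesion core has a shorter T1 than healthy myocardium so that it
#' hyper-enhances on inversion-recovery images at long TI. Blood and the
#' non-lesion T1 values are plausible 1.5 T figures and are not critical
#' to any derived quantity.
#'
#' @param blood,healthy,lesion,edema numeric vectors `c(t1_ms, t2_ms, pd)`.
#' @return data.frame with columns `class`, `name`, `t1`, `t2`, `pd`.
#' @export
tissue_table <- function(blood   = c(1600, 250, 1.2),
                         healthy = c(1100,  39, 1.0),
                         lesion  = c( 800,  53, 1.0),
                         edema   = c(1150,  58, 1.0)) {
  tab <- rbind(blood, healthy, lesion, edema)
  stopifnot(ncol(tab) == 3, all(tab > 0))
  data.frame(class = 1:4,
             name = c("blood", "healthy", "lesion", "edema"),
             t1 = tab[, 1], t2 = tab[, 2], pd = tab[, 3],
             row.names = NULL)
}

#' Interval schedule of ablation-site T2
#'
#' Acute ablation injury shows a transient T2 rise: both the lesion core
#' and the surrounding edema peak at 60-80 min post-ablation before
#' settling. This helper builds the default step schedules used when a
#' phantom is simulated with time-varying T2 (lesion 53 / 55 / 53 ms and
#' edema 53 / 58 / 56 ms over the 0-60, 60-80 and 80+ min windows).
#'
#' @return named list of data.frames with columns `from_min`, `t2_ms`.
#' @export
default_t2_schedule <- function() {
  list(
    lesion = data.frame(from_min = c(0, 60, 80), t2_ms = c(53, 55, 53)),
    edema  = data.frame(from_min = c(0, 60, 80), t2_ms = c(53, 58, 56))
  )
}

## T2 for a tissue class at time t, honouring an optional schedule
scheduled_t2 <- function(config, class_name, t) {
  sched <- config$t2_schedule[[class_name]]
  base <- config$tissues$t2[config$tissues$name == class_name]
  if (is.null(sched)) return(base)
  ok <- sched$from_min <= t
  if (!any(ok)) return(base)
  sched$t2_ms[max(which(ok))]
}

#' Lesion geometry specification
#'
#' The acute RF lesion is modelled as a teardrop: a half-ellipsoid
#' attached at the endocardial border, its long axis along the local
#' radial direction, widest at the catheter contact point and tapering
#' into the wall. An annular-sector shape with a closed-form volume is
#' also available for geometric validation.
#'
#' @param angle_deg angular position of the catheter contact point (deg).
#' @param width_mm tangential surface width of the lesion (mm).
#' @param depth_fraction lesion depth as a fraction of wall thickness,
#'   in (0, 1].
#' @param height_mm through-slice extent of the teardrop (mm); defaults
#'   to `width_mm`.
#' @param shape `"teardrop"` (default) or `"sector"`.
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(angle_deg = 0, width_mm = 14.8,
                        depth_fraction = 0.52, height_mm = NULL,
                        shape = c("teardrop", "sector")) {
  shape <- match.arg(shape)
  if (!(depth_fraction > 0 && depth_fraction <= 1))
    stop("lesion depth_fraction must lie in (0, 1]", call. = FALSE)
  assert_scalar_pos(width_mm, "width_mm")
  structure(list(angle_deg = angle_deg, width_mm = width_mm,
                 depth_fraction = depth_fraction,
                 height_mm = height_mm %||% width_mm,
                 shape = shape),
            class = "lesion_spec")
}

#' Edema growth specification
#'
#' The ground-truth edematous region (lesion core plus rim) starts at a
#' baseline volume and grows linearly in time,
#' `V(t) = V0 * (1 + g * max(0, t - t0))`, realized geometrically by
#' thickening the rim around the fixed lesion core.
#'
#' @param baseline_volume_mL total edematous-region volume at `t = t0` (mL).
#' @param growth_rate fractional growth rate g (per min).
#' @param start_offset_min time t0 at which growth starts (min).
#' @return list of class `edema_spec`.
#' @export
edema_spec <- function(baseline_volume_mL = 0.77, growth_rate = 0.003,
                       start_offset_min = 0) {
  assert_scalar_pos(baseline_volume_mL, "baseline_volume_mL")
  stopifnot(is.numeric(growth_rate), length(growth_rate) == 1L,
            start_offset_min >= 0)
  structure(list(baseline_volume_mL = baseline_volume_mL,
                 growth_rate = growth_rate,
                 start_offset_min = start_offset_min),
            class = "edema_spec")
}

#' Short-axis LV phantom configuration
#'
#' Parametric description of the digital phantom: grid geometry, LV
#' annulus, lesion and edema specification, tissue relaxometry, and
#' acquisition noise. Defaults follow the acquisition used for acute
#' lesion imaging: 1.3 x 1.3 mm in-plane resolution, 6 mm slices, three
#' adjacent short-axis slices covering the lesion, and an 8 mm wall
#' (endocardial radius 25 mm, epicardial 33 mm).
#'
#' @param matrix_size integer c(nx, ny) voxels.
#' @param spacing_mm in-plane voxel spacing c(dx, dy) in mm.
#' @param slice_thickness_mm slice thickness (mm).
#' @param n_slices number of adjacent short-axis slices.
#' @param center_mm LV centre in physical mm; defaults to grid centre.
#' @param r_endo_mm,r_epi_mm endocardial / epicardial radii (mm).
#' @param lesion a [lesion_spec()].
#' @param edema an [edema_spec()].
#' @param tissues a [tissue_table()].
#' @param t2_schedule optional named list of per-class T2 step schedules
#'   (see [default_t2_schedule()]); `NULL` keeps T2 constant in time.
#' @param snr signal-to-noise ratio, defined as the healthy-myocardium
#'   signal at TE = 0 divided by the Gaussian channel noise sigma;
#'   `Inf` for noiseless simulation.
#' @param seed default RNG seed for simulations from this configuration.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(matrix_size = c(128L, 128L),
                           spacing_mm = c(1.3, 1.3),
                           slice_thickness_mm = 6,
                           n_slices = 3L,
                           center_mm = NULL,
                           r_endo_mm = 25, r_epi_mm = 33,
                           lesion = lesion_spec(),
                           edema = edema_spec(),
                           tissues = tissue_table(),
                           t2_schedule = NULL,
                           snr = Inf,
                           seed = 1L) {
  stopifnot(length(matrix_size) == 2L, all(matrix_size >= 16),
            length(spacing_mm) == 2L, all(spacing_mm > 0),
            n_slices >= 1L)
  assert_scalar_pos(slice_thickness_mm, "slice_thickness_mm")
  assert_scalar_pos(r_endo_mm, "r_endo_mm")
  assert_scalar_pos(r_epi_mm, "r_epi_mm")
  assert_scalar_pos(snr, "snr", allow_inf = TRUE)
  if (r_epi_mm <= r_endo_mm)
    stop("epicardial radius must exceed endocardial radius", call. = FALSE)
  stopifnot(inherits(lesion, "lesion_spec"), inherits(edema, "edema_spec"))
  if (!all(c(tissues$t1, tissues$t2, tissues$pd) > 0))
    stop("all tissue T1, T2 and PD values must be positive", call. = FALSE)
  if (is.null(center_mm))
    center_mm <- (matrix_size - 1) / 2 * spacing_mm
  cfg <- structure(list(
    matrix_size = as.integer(matrix_size),
    spacing_mm = spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    n_slices = as.integer(n_slices),
    center_mm = center_mm,
    r_endo_mm = r_endo_mm, r_epi_mm = r_epi_mm,
    lesion = lesion, edema = edema,
    tissues = tissues, t2_schedule = t2_schedule,
    snr = snr, seed = as.integer(seed)), class = "phantom_config")
  ## the epicardium must fit inside the field of view
  fov <- matrix_size * spacing_mm
  if (any(center_mm - r_epi_mm < 0) || any(center_mm + r_epi_mm > fov))
    stop("epicardium does not fit inside the field of view", call. = FALSE)
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> ", x$matrix_size[1], "x", x$matrix_size[2], "x",
      x$n_slices, " @ ", x$spacing_mm[1], "x", x$spacing_mm[2], "x",
      x$slice_thickness_mm, " mm\n", sep = "")
  cat(sprintf("  annulus: endo %.1f mm, epi %.1f mm (wall %.1f mm)\n",
              x$r_endo_mm, x$r_epi_mm, x$r_epi_mm - x$r_endo_mm))
  cat(sprintf("  lesion: %s at %g deg, width %.1f mm, depth fraction %.2f\n",
              x$lesion$shape, x$lesion$angle_deg, x$lesion$width_mm,
              x$lesion$depth_fraction))
  cat(sprintf("  edema: V0 %.2f mL, growth %.4f /min\n",
              x$edema$baseline_volume_mL, x$edema$growth_rate))
  cat(sprintf("  SNR %s, seed %d\n",
              if (is.finite(x$snr)) format(x$snr) else "Inf (noiseless)",
              x$seed))
  invisible(x)
}
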