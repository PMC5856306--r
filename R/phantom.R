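## Label codes for the phantom tissue classes
LBL_BACKGROUND <- 0L
LBL_BLOOD <- 1L
LBL_HEALTHY <- 2L
LBL_LESION <- 3L
LBL_EDEMA <- 4L

## physical voxel-centre coordinate arrays for a config: list(x, y, z, r,
## theta) where r/theta are polar coordinates about the LV centre,
## replicated over the full 3D grid
grid_coords <- function(config) {
  nx <- config$matrix_size[1]; ny <- config$matrix_size[2]
  nz <- config$n_slices
  x <- axis_coords(nx, config$spacing_mm[1])
  y <- axis_coords(ny, config$spacing_mm[2])
  z <- axis_coords(nz, config$slice_thickness_mm)
  X <- array(rep(x, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(y, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), dim = c(nx, ny, nz))
  dx <- X - config$center_mm[1]
  dy <- Y - config$center_mm[2]
  list(X = X, Y = Y, Z = Z,
       r = sqrt(dx^2 + dy^2), theta = atan2(dy, dx))
}

## rasterize the lesion core over an existing myocardium mask;
## returns a logical array
rasterize_lesion <- function(config, coords, myo, width_mm = NULL) {
  les <- config$lesion
  w <- width_mm %||% les$width_mm
  theta0 <- les$angle_deg * pi / 180
  wall <- config$r_epi_mm - config$r_endo_mm
  a <- les$depth_fraction * wall
  if (les$shape == "sector") {
    half_ang <- (w / 2) / config$r_endo_mm
    return(myo &
             (coords$r - config$r_endo_mm) <= a &
             abs(wrap_angle(coords$theta - theta0)) <= half_ang)
  }
  ## teardrop: half-ellipsoid attached at the endocardial border, long
  ## axis along the local radial direction
  er <- c(cos(theta0), sin(theta0))
  p0 <- config$center_mm + config$r_endo_mm * er
  ddx <- coords$X - p0[1]
  ddy <- coords$Y - p0[2]
  d_r <- ddx * er[1] + ddy * er[2]
  d_t <- -ddx * er[2] + ddy * er[1]
  zmid <- (config$n_slices - 1) / 2 * config$slice_thickness_mm
  d_z <- coords$Z - zmid
  b <- w / 2
  cc <- les$height_mm / 2
  myo & d_r >= 0 &
    (d_r / a)^2 + (d_t / b)^2 + (d_z / cc)^2 <= 1
}

## closed-form volume (mL) of the annular-sector lesion shape, used to
## validate rasterization against analytic geometry
sector_volume_analytic <- function(config) {
  stopifnot(config$lesion$shape == "sector")
  wall <- config$r_epi_mm - config$r_endo_mm
  a <- config$lesion$depth_fraction * wall
  ang <- config$lesion$width_mm / config$r_endo_mm   # full angular width
  area <- 0.5 * ang * ((config$r_endo_mm + a)^2 - config$r_endo_mm^2)
  area * config$n_slices * config$slice_thickness_mm / 1000
}

#' Build a phantom label volume at a given time post-ablation
#'
#' Rasterizes the short-axis anatomy (background, blood pool, myocardial
#' annulus), places the lesion core, and grows the edema rim so that the
#' ground-truth edematous region (lesion plus rim) has volume
#' `V0 * (1 + g * max(0, t - t0))` to within one voxel. The rim is the
#' set of annulus voxels nearest (in 3D physical distance) to the lesion
#' core, which keeps the edematous region connected and encompassing the
#' lesion at all times.
#'
#' @param config a [phantom_config()].
#' @param t time post-ablation (min), `t >= 0`.
#' @return A `label_volume`: list with integer `labels` array (codes 0
#'   background, 1 blood, 2 healthy myocardium, 3 lesion core, 4 edema
#'   rim), `spacing_mm` (dx, dy, dz), time `t_min`, LV `contours`
#'   (centre and radii), and a `truth` list of per-class volumes (mL).
#' @export
build_label_volume <- function(config, t) {
  stopifnot(inherits(config, "phantom_config"), t >= 0)
  coords <- grid_coords(config)
  labels <- array(LBL_BACKGROUND, dim = dim(coords$r))
  blood <- coords$r < config$r_endo_mm
  myo <- coords$r >= config$r_endo_mm & coords$r < config$r_epi_mm
  labels[blood] <- LBL_BLOOD
  labels[myo] <- LBL_HEALTHY

  lesion <- rasterize_lesion(config, coords, myo)
  labels[lesion] <- LBL_LESION

  spacing <- c(config$spacing_mm, config$slice_thickness_mm)
  vox_mm3 <- prod(spacing)
  n_lesion <- sum(lesion)
  if (n_lesion == 0L)
    stop("lesion rasterized to zero voxels; widen or deepen the lesion",
         call. = FALSE)

  ## target edematous-region (lesion + rim) volume at time t
  ed <- config$edema
  v_target <- ed$baseline_volume_mL *
    (1 + ed$growth_rate * max(0, t - ed$start_offset_min))
  k_total <- round(v_target * 1000 / vox_mm3)
  n_annulus <- sum(myo)
  if (k_total > n_annulus)
    stop(sprintf(paste0("requested edematous-region volume %.2f mL exceeds ",
                        "the myocardial annulus capacity (%.2f mL)"),
                 v_target, n_annulus * vox_mm3 / 1000), call. = FALSE)
  if (k_total < n_lesion)
    stop(sprintf(paste0("requested edematous-region volume %.2f mL is below ",
                        "the lesion-core volume (%.2f mL); the edematous ",
                        "region must encompass the lesion"),
                 v_target, n_lesion * vox_mm3 / 1000), call. = FALSE)

  if (k_total > n_lesion) {
    cand <- which(myo & !lesion)
    pts <- cbind(coords$X[cand], coords$Y[cand], coords$Z[cand])
    lp <- cbind(coords$X[lesion], coords$Y[lesion], coords$Z[lesion])
    ## min distance from each candidate annulus voxel to the lesion core
    d2 <- rep(Inf, length(cand))
    for (j in seq_len(nrow(lp))) {
      dj <- (pts[, 1] - lp[j, 1])^2 + (pts[, 2] - lp[j, 2])^2 +
        (pts[, 3] - lp[j, 3])^2
      d2 <- pmin(d2, dj)
    }
    ## edema wets the lesion's in-plane boundary first (the interface
    ## layer), then thickens outward by distance; ties are spread
    ## evenly by a deterministic low-discrepancy hash so no slice is
    ## systematically starved of rim when the budget is tight
    d <- dim(labels)
    nxy <- d[1] * d[2]
    contact <- vapply(cand, function(v) {
      k <- (v - 1L) %/% nxy
      i <- ((v - 1L) %% nxy) %% d[1] + 1L
      j <- ((v - 1L) %% nxy) %/% d[1] + 1L
      any(lesion[pmax(i - 1L, 1L):pmin(i + 1L, d[1]),
                 pmax(j - 1L, 1L):pmin(j + 1L, d[2]), k + 1L])
    }, logical(1))
    tie <- (cand * 0.6180339887498949) %% 1
    ord <- order(!contact, round(sqrt(d2), 3), tie)
    rim <- cand[ord[seq_len(k_total - n_lesion)]]
    labels[rim] <- LBL_EDEMA
  }

  truth <- vapply(c(blood = LBL_BLOOD, healthy = LBL_HEALTHY,
                    lesion = LBL_LESION, edema_rim = LBL_EDEMA),
                  function(l) sum(labels == l) * vox_mm3 / 1000, numeric(1))
  truth <- as.list(truth)
  truth$edematous_region <- truth$lesion + truth$edema_rim
  truth$target_edematous_region <- v_target

  structure(list(labels = labels, spacing_mm = spacing, t_min = t,
                 contours = lv_contours(config$center_mm, config$r_endo_mm,
                                        config$r_epi_mm),
                 lesion_angle_deg = config$lesion$angle_deg,
                 truth = truth),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = "x"),
      " @ t = ", x$t_min, " min\n", sep = "")
  cat(sprintf("  lesion %.3f mL, edematous region %.3f mL\n",
              x$truth$lesion, x$truth$edematous_region))
  invisible(x)
}

#' Extract a tissue-class mask from a label volume
#'
#' @param label a `label_volume`.
#' @param class one of `"blood"`, `"healthy"`, `"lesion"`, `"edema_rim"`,
#'   `"edematous_region"` (lesion plus rim) or `"myocardium"` (all
#'   annulus classes).
#' @return logical array.
#' @export
class_mask <- function(label, class = c("lesion", "edema_rim",
                                        "edematous_region", "healthy",
                                        "blood", "myocardium")) {
  class <- match.arg(class)
  l <- label$labels
  switch(class,
         blood = l == LBL_BLOOD,
         healthy = l == LBL_HEALTHY,
         lesion = l == LBL_LESION,
         edema_rim = l == LBL_EDEMA,
         edematous_region = l == LBL_LESION | l == LBL_EDEMA,
         myocardium = l >= LBL_HEALTHY)
}

## per-voxel tissue parameter lookup arrays for a label volume
tissue_param_array <- function(label, config, param, t = label$t_min) {
  tis <- config$tissues
  vals <- c(0, tis[[param]])               # background maps to 0
  if (param == "t2" && !is.null(config$t2_schedule)) {
    for (nm in names(config$t2_schedule)) {
      i <- which(tis$name == nm)
      if (length(i)) vals[i + 1] <- scheduled_t2(config, nm, t)
    }
  }
  array(vals[label$labels + 1L], dim = dim(label$labels))
}

## apply Rician (magnitude) noise: magnitude of the complex signal after
## adding independent Gaussian noise of sd sigma to each channel
rician_noise <- function(signal, sigma) {
  if (sigma <= 0) return(signal)
  n <- length(signal)
  e1 <- rnorm(n, 0, sigma)
  e2 <- rnorm(n, 0, sigma)
  array(sqrt((signal + e1)^2 + e2^2), dim = dim(signal))
}

new_image_series <- function(data, contrast, values, t_min, spacing_mm, snr) {
  structure(list(data = data, contrast = contrast, values = values,
                 t_min = t_min, spacing_mm = spacing_mm, snr = snr),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat("<image_series> ", paste(dim(x$data)[1:3], collapse = "x"), ", ",
      length(x$values), " ", x$contrast, "s (",
      paste(format(x$values), collapse = ", "), " ms) @ t = ",
      x$t_min, " min\n", sep = "")
  invisible(x)
}

check_contrast_values <- function(values, what) {
  if (length(values) == 0 || any(values <= 0))
    stop(sprintf("%s values must be positive", what), call. = FALSE)
  if (length(values) > 1 && any(diff(values) <= 0))
    stop(sprintf("%s values must be strictly increasing", what),
         call. = FALSE)
}

#' Simulate a T2-prepared multi-echo image series
#'
#' Noiseless voxel signal follows the mono-exponential preparation decay
#' `S(TE) = PD * exp(-TE / T2)` of the voxel's tissue class (with the
#' scheduled T2 when the configuration carries a schedule). Magnitude
#' (Rician) noise is applied with channel sigma equal to the healthy
#' myocardium TE = 0 signal divided by the configured SNR.
#'
#' @param label a `label_volume` from [build_label_volume()].
#' @param config the [phantom_config()] used to build it.
#' @param TEs echo times (ms), strictly increasing.
#' @param seed RNG seed; defaults to the configuration seed. Simulation
#'   is deterministic for a fixed seed.
#' @return An `image_series` with a 4D data array (x, y, slice, TE).
#' @export
simulate_t2prep_series <- function(label, config, TEs = c(3, 25, 75, 184),
                                   seed = NULL) {
  stopifnot(inherits(label, "label_volume"),
            inherits(config, "phantom_config"))
  check_contrast_values(TEs, "TE")
  pd <- tissue_param_array(label, config, "pd")
  t2 <- tissue_param_array(label, config, "t2")
  nz <- dim(label$labels)
  data <- array(0, dim = c(nz, length(TEs)))
  inside <- label$labels > 0L
  for (i in seq_along(TEs)) {
    s <- array(0, dim = nz)
    s[inside] <- pd[inside] * exp(-TEs[i] / t2[inside])
    data[, , , i] <- s
  }
  data <- add_series_noise(data, config, seed)
  new_image_series(data, "TE", TEs, label$t_min, label$spacing_mm,
                   config$snr)
}

#' Simulate an inversion-recovery image series
#'
#' Simplified inversion-recovery magnitude signal
#' `S(TI) = PD * |1 - 2 * exp(-TI / T1)|`; the bSSFP steady-state
#' readout is deliberately not modelled. With the default tissue table
#' the lesion core (short T1) hyper-enhances relative to healthy
#' myocardium at TI of roughly 700 ms and beyond, which is the contrast
#' the lesion segmentation relies on.
#'
#' @inheritParams simulate_t2prep_series
#' @param TIs inversion times (ms), strictly increasing.
#' @return An `image_series` with a 4D data array (x, y, slice, TI).
#' @export
simulate_ir_series <- function(label, config, TIs = c(400, 600, 831),
                               seed = NULL) {
  stopifnot(inherits(label, "label_volume"),
            inherits(config, "phantom_config"))
  check_contrast_values(TIs, "TI")
  tis <- config$tissues
  if (tis$t1[tis$name == "lesion"] >= tis$t1[tis$name == "healthy"])
    stop("lesion T1 must be shorter than healthy T1 for hyper-enhancement",
         call. = FALSE)
  pd <- tissue_param_array(label, config, "pd")
  t1 <- tissue_param_array(label, config, "t1")
  nz <- dim(label$labels)
  data <- array(0, dim = c(nz, length(TIs)))
  inside <- label$labels > 0L
  for (i in seq_along(TIs)) {
    s <- array(0, dim = nz)
    s[inside] <- pd[inside] * abs(1 - 2 * exp(-TIs[i] / t1[inside]))
    data[, , , i] <- s
  }
  data <- add_series_noise(data, config, seed)
  new_image_series(data, "TI", TIs, label$t_min, label$spacing_mm,
                   config$snr)
}

add_series_noise <- function(data, config, seed) {
  if (!is.finite(config$snr)) return(data)
  pd_healthy <- config$tissues$pd[config$tissues$name == "healthy"]
  sigma <- pd_healthy / config$snr
  withr::with_seed(as.integer(seed %||% config$seed),
                   rician_noise(data, sigma))
}
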