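#' Circular LV contour description
#'
#' Endocardial and epicardial contours used for wall-thickness and
#' transmurality measurements. The phantom LV is circular, so contours
#' are stored as a centre and two radii.
#'
#' @param center_mm in-plane LV centre (mm).
#' @param r_endo_mm,r_epi_mm endocardial / epicardial radii (mm).
#' @return list of class `lv_contours`.
#' @export
lv_contours <- function(center_mm, r_endo_mm, r_epi_mm) {
  stopifnot(r_epi_mm > r_endo_mm, r_endo_mm > 0)
  structure(list(center_mm = center_mm, r_endo_mm = r_endo_mm,
                 r_epi_mm = r_epi_mm), class = "lv_contours")
}

## pull values + validity out of a t2_map or a plain numeric array
segmentation_values <- function(x) {
  if (inherits(x, "t2_map")) {
    list(values = x$t2, valid = x$flag == FLAG_VALID,
         spacing_mm = x$spacing_mm)
  } else {
    list(values = x, valid = is.finite(x), spacing_mm = NULL)
  }
}

#' Reference statistics from a healthy-tissue ROI
#'
#' Arithmetic mean and sample SD of the reference quantity (T2 in ms for
#' a map, signal intensity for a weighted image) over a reference ROI.
#' Flagged-invalid map voxels are excluded and the reported voxel count
#' reflects the exclusion. A floor on the ROI size guards against
#' unstable SD estimates.
#'
#' @param x a `t2_map` or numeric array (weighted image).
#' @param reference_mask logical array, disjoint from any suspected
#'   injury.
#' @param min_voxels smallest acceptable ROI (default 30 voxels).
#' @return list of class `reference_stats` with `mean`, `sd`, `n`.
#' @export
estimate_reference_stats <- function(x, reference_mask, min_voxels = 30) {
  sv <- segmentation_values(x)
  vals <- sv$values[reference_mask & sv$valid]
  if (length(vals) < min_voxels)
    stop(sprintf(paste0("reference ROI has %d usable voxels; at least %d ",
                        "are required for a stable SD"),
                 length(vals), min_voxels), call. = FALSE)
  structure(list(mean = mean(vals), sd = sd(vals), n = length(vals)),
            class = "reference_stats")
}

#' Construct reference statistics directly
#'
#' For noiseless phantom runs the measured reference SD is zero; to keep
#' the SD-multiple thresholds meaningful the in-vivo spread can be
#' injected explicitly (e.g. the 5 ms healthy-myocardium T2 SD).
#'
#' @param mean,sd reference mean and SD.
#' @param n nominal voxel count.
#' @return list of class `reference_stats`.
#' @export
reference_stats <- function(mean, sd, n = NA_integer_) {
  stopifnot(sd >= 0)
  structure(list(mean = mean, sd = sd, n = n), class = "reference_stats")
}

#' Automatic reference-ROI placement
#'
#' Places the healthy reference ROI as an angular sector of the
#' myocardial annulus diametrically opposite the configured lesion
#' angle, remote from the injury.
#'
#' @param label a `label_volume`.
#' @param width_deg full angular width of the sector (default 60).
#' @param offset_deg offset from the lesion angle (default 180).
#' @return logical array selecting healthy-myocardium voxels.
#' @export
reference_roi_mask <- function(label, width_deg = 60, offset_deg = 180) {
  stopifnot(inherits(label, "label_volume"))
  d <- dim(label$labels)
  ct <- label$contours
  x <- axis_coords(d[1], label$spacing_mm[1]) - ct$center_mm[1]
  y <- axis_coords(d[2], label$spacing_mm[2]) - ct$center_mm[2]
  theta <- array(atan2(rep(rep(y, each = d[1]), d[3]),
                       rep(x, times = d[2] * d[3])), dim = d)
  target <- (label$lesion_angle_deg + offset_deg) * pi / 180
  sector <- abs(wrap_angle(theta - target)) <= (width_deg / 2) * pi / 180
  sector & label$labels == LBL_HEALTHY
}

#' Morphological cleanup parameters
#'
#' @param min_component_voxels components smaller than this (per slice,
#'   8-connected) are removed as noise.
#' @param closing_radius radius (voxels) of a binary closing applied to
#'   the raw mask; bridges single-voxel gaps that noise opens in the
#'   thin edematous rim so hole filling can operate. 0 disables it.
#' @param opening_radius radius (voxels) of an optional binary opening
#'   applied before component analysis; 0 disables it (the default: at
#'   baseline the edema rim is only about one voxel thick and an
#'   opening would erase it; small-component removal plays the
#'   denoising role instead).
#' @param fill_holes fill enclosed regions within each retained
#'   component (holes are complement regions of the analysis region
#'   disconnected from its main body).
#' @param max_iter cleanup is iterated to a fixed point; safety cap.
#' @return list of class `cleanup_params`.
#' @export
cleanup_params <- function(min_component_voxels = 5, closing_radius = 2,
                           opening_radius = 0,
                           fill_holes = TRUE, max_iter = 5) {
  structure(list(min_component_voxels = min_component_voxels,
                 closing_radius = closing_radius,
                 opening_radius = opening_radius,
                 fill_holes = fill_holes, max_iter = max_iter),
            class = "cleanup_params")
}

## one cleanup pass on a single 2D slice
cleanup_slice_once <- function(sl, region, p) {
  if (p$closing_radius > 0 && any(sl)) {
    kern <- EBImage::makeBrush(2 * p$closing_radius + 1, shape = "diamond")
    sl <- EBImage::closing(sl * 1, kern) > 0 & region
  }
  if (p$opening_radius > 0 && any(sl)) {
    kern <- EBImage::makeBrush(2 * p$opening_radius + 1, shape = "diamond")
    sl <- EBImage::opening(sl * 1, kern) > 0 & region
  }
  if (any(sl) && p$min_component_voxels > 1) {
    lab <- label_components_2d(sl, connectivity = 8)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= p$min_component_voxels)
    sl <- array(lab %in% keep, dim = dim(sl)) & sl
  }
  if (p$fill_holes && any(sl)) {
    comp <- label_components_2d(region & !sl, connectivity = 4)
    ncomp <- max(comp)
    if (ncomp >= 2) {
      sizes <- tabulate(comp[comp > 0])
      bulk <- which.max(sizes)          # main healthy body of the region
      holes <- comp > 0 & comp != bulk
      sl <- sl | holes
    }
  }
  sl
}

#' Clean a binary mask slice-by-slice
#'
#' Removes small noise components and fills regions they enclose,
#' iterated to a fixed point so re-running the cleanup on its own output
#' changes nothing. Holes are defined per slice as connected regions of
#' the analysis region, outside the mask, that are disconnected from the
#' region's main body: for an edematous rim this captures the enclosed
#' lesion core even where the rim opens onto the endocardial border.
#'
#' @param mask logical 3D array (raw threshold mask).
#' @param analysis_region logical 3D array the mask lives in
#'   (myocardium).
#' @param params a [cleanup_params()].
#' @return cleaned logical array.
#' @export
cleanup_mask <- function(mask, analysis_region, params = cleanup_params()) {
  stopifnot(identical(dim(mask), dim(analysis_region)))
  d <- dim(mask)
  out <- mask & analysis_region
  for (k in seq_len(d[3])) {
    sl <- out[, , k]
    region <- analysis_region[, , k]
    for (it in seq_len(params$max_iter)) {
      nxt <- cleanup_slice_once(sl, region, params)
      if (identical(nxt, sl)) break
      sl <- nxt
    }
    out[, , k] <- sl
  }
  out
}

#' Segment a hyperintense region by a reference-SD threshold
#'
#' Thresholds the map (or weighted image) at `mean + k * SD` of the
#' healthy reference statistics within the analysis region, then applies
#' the morphological cleanup. The T2-derived edematous region uses
#' `k = 3` on a T2 map; the T1-derived lesion uses `k = 2` on the
#' selected long-TI inversion-recovery image. An empty result is a valid
#' outcome, not an error.
#'
#' @param x a `t2_map` or numeric array (weighted image).
#' @param ref a `reference_stats`.
#' @param k SD multiplier.
#' @param analysis_region logical array (the myocardium).
#' @param cleanup a [cleanup_params()].
#' @param spacing_mm voxel dimensions; taken from the map when `x` is a
#'   `t2_map`.
#' @return A `segmentation_result`: `mask` (cleaned), `raw_mask` (pure
#'   threshold result before cleanup), `volume_mL`,
#'   `per_slice_area_mm2`, `threshold`, `k`, `cleanup`.
#' @export
segment_hyperintense <- function(x, ref, k, analysis_region,
                                 cleanup = cleanup_params(),
                                 spacing_mm = NULL) {
  stopifnot(inherits(ref, "reference_stats"))
  sv <- segmentation_values(x)
  spacing_mm <- spacing_mm %||% sv$spacing_mm
  if (is.null(spacing_mm))
    stop("spacing_mm is required when segmenting a plain array",
         call. = FALSE)
  stopifnot(identical(dim(sv$values), dim(analysis_region)))
  threshold <- ref$mean + k * ref$sd
  raw <- analysis_region & sv$valid & (sv$values > threshold)
  raw[is.na(raw)] <- FALSE
  mask <- cleanup_mask(raw, analysis_region, cleanup)
  d <- dim(mask)
  areas <- vapply(seq_len(d[3]),
                  function(kk) sum(mask[, , kk]) * prod(spacing_mm[1:2]),
                  numeric(1))
  structure(list(mask = mask, raw_mask = raw,
                 volume_mL = compute_volume(mask, spacing_mm),
                 per_slice_area_mm2 = areas, threshold = threshold, k = k,
                 spacing_mm = spacing_mm, cleanup = cleanup),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %.3f mL (%d voxels), threshold %.2f (k = %g)\n",
              x$volume_mL, sum(x$mask), x$threshold, x$k))
  invisible(x)
}

#' Volume of a binary mask
#'
#' Voxel count times voxel volume, exactly; no partial-volume weighting.
#'
#' @param mask logical array.
#' @param spacing_mm voxel dimensions c(dx, dy, dz) in mm.
#' @return volume in mL (cm^3).
#' @export
compute_volume <- function(mask, spacing_mm) {
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0))
  sum(mask) * prod(spacing_mm) / 1000
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of equal shape.
#' @return Dice coefficient in `[0, 1]` (`NaN` when both empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

## trace the radial ray at angle theta (rad) and return the largest
## radius at which the mask slice is hit (NA when never hit)
ray_max_radius <- function(sl, contours, spacing_mm, theta, step = 0.05) {
  rs <- seq(contours$r_endo_mm, contours$r_epi_mm, by = step)
  px <- contours$center_mm[1] + rs * cos(theta)
  py <- contours$center_mm[2] + rs * sin(theta)
  i <- round(px / spacing_mm[1]) + 1L
  j <- round(py / spacing_mm[2]) + 1L
  ok <- i >= 1L & i <= nrow(sl) & j >= 1L & j <= ncol(sl)
  hit <- ok & sl[cbind(pmax(i, 1L), pmax(j, 1L))]
  if (!any(hit)) return(NA_real_)
  max(rs[hit])
}

#' Lesion transmurality from a segmentation mask
#'
#' Transmurality is the lesion depth from the endocardial border divided
#' by the wall thickness, measured along the radial ray through the
#' mask's in-plane centroid angle. Depth includes a half-voxel edge
#' correction for the rasterized boundary. Reported per slice and as the
#' maximum across slices; slices whose ray misses the mask are flagged
#' undefined.
#'
#' @param mask logical 3D array within the annulus.
#' @param contours an [lv_contours()].
#' @param spacing_mm voxel dimensions (mm).
#' @return list with `per_slice` (fraction, `NA` where undefined),
#'   `max` and `flagged` (any undefined slice containing mask voxels).
#' @export
measure_transmurality <- function(mask, contours, spacing_mm) {
  stopifnot(inherits(contours, "lv_contours"))
  d <- dim(mask)
  half_vox <- mean(spacing_mm[1:2]) / 2
  thickness <- contours$r_epi_mm - contours$r_endo_mm
  per_slice <- rep(NA_real_, d[3])
  flagged <- FALSE
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    cx <- mean((idx[, 1] - 1) * spacing_mm[1]) - contours$center_mm[1]
    cy <- mean((idx[, 2] - 1) * spacing_mm[2]) - contours$center_mm[2]
    theta <- atan2(cy, cx)
    rmax <- ray_max_radius(sl, contours, spacing_mm, theta)
    if (is.na(rmax)) { flagged <- TRUE; next }
    depth <- rmax + half_vox - contours$r_endo_mm
    per_slice[k] <- min(max(depth / thickness, 0), 1.05)
  }
  list(per_slice = per_slice,
       max = if (all(is.na(per_slice))) NA_real_
             else max(per_slice, na.rm = TRUE),
       flagged = flagged)
}

#' Wall thickness along a radial ray
#'
#' @param contours an [lv_contours()].
#' @param angle_deg ray angle (deg).
#' @return endocardial-to-epicardial distance (mm).
#' @export
measure_wall_thickness <- function(contours, angle_deg = 0) {
  stopifnot(inherits(contours, "lv_contours"))
  contours$r_epi_mm - contours$r_endo_mm
}

#' Maximum in-plane diameter of a mask
#'
#' Largest pairwise in-plane extent of mask voxel centres plus one
#' in-plane voxel size, maximized over slices.
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel dimensions (mm).
#' @return list with `diameter_mm` (`NA` when the mask is empty, with
#'   `flagged = TRUE`) and `per_slice`.
#' @export
measure_diameter <- function(mask, spacing_mm) {
  d <- dim(mask)
  per_slice <- rep(NA_real_, d[3])
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    pts <- cbind((idx[, 1] - 1) * spacing_mm[1],
                 (idx[, 2] - 1) * spacing_mm[2])
    per_slice[k] <- if (nrow(pts) == 1) 0 else max(stats::dist(pts))
    per_slice[k] <- per_slice[k] + mean(spacing_mm[1:2])
  }
  empty <- all(is.na(per_slice))
  list(diameter_mm = if (empty) NA_real_ else max(per_slice, na.rm = TRUE),
       per_slice = per_slice, flagged = empty)
}
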