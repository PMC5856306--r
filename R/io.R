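## NIfTI + sidecar-JSON I/O. Voxel data travel as NIfTI-1 with spacing
## in the header; acquisition metadata (TE/TI lists, time post-ablation,
## identifiers, seed) live in a JSON sidecar next to each volume.

write_nifti_vol <- function(arr, spacing_mm, file) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write an image series as NIfTI plus a JSON sidecar
#'
#' @param series an `image_series`.
#' @param prefix path prefix; writes `<prefix>.nii.gz` (4D: x, y,
#'   slice, contrast) and `<prefix>.json`.
#' @param extra named list merged into the sidecar (identifiers, seed).
#' @return the prefix, invisibly.
#' @export
write_image_series <- function(series, prefix, extra = list()) {
  stopifnot(inherits(series, "image_series"))
  write_nifti_vol(series$data, c(series$spacing_mm, 1),
                  paste0(prefix, ".nii.gz"))
  meta <- c(list(contrast = series$contrast, values_ms = series$values,
                 t_min = series$t_min, spacing_mm = series$spacing_mm,
                 snr = if (is.finite(series$snr)) series$snr else "Inf"),
            extra)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read an image series written by [write_image_series()]
#'
#' @param prefix path prefix used at write time.
#' @return an `image_series`.
#' @export
read_image_series <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  snr <- if (identical(meta$snr, "Inf")) Inf else as.numeric(meta$snr)
  new_image_series(array(as.numeric(arr), dim = dim(arr)), meta$contrast,
                   meta$values_ms, meta$t_min, meta$spacing_mm, snr)
}

#' Write a label volume as a NIfTI label map plus a JSON sidecar
#'
#' @param label a `label_volume`.
#' @param prefix path prefix.
#' @param extra named list merged into the sidecar.
#' @return the prefix, invisibly.
#' @export
write_label_volume <- function(label, prefix, extra = list()) {
  stopifnot(inherits(label, "label_volume"))
  write_nifti_vol(label$labels, label$spacing_mm,
                  paste0(prefix, ".nii.gz"))
  meta <- c(list(t_min = label$t_min, spacing_mm = label$spacing_mm,
                 center_mm = label$contours$center_mm,
                 r_endo_mm = label$contours$r_endo_mm,
                 r_epi_mm = label$contours$r_epi_mm,
                 lesion_angle_deg = label$lesion_angle_deg,
                 truth = label$truth), extra)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a label volume written by [write_label_volume()]
#'
#' @param prefix path prefix used at write time.
#' @return a `label_volume`.
#' @export
read_label_volume <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  structure(list(labels = array(as.integer(arr), dim = dim(arr)),
                 spacing_mm = meta$spacing_mm, t_min = meta$t_min,
                 contours = lv_contours(meta$center_mm, meta$r_endo_mm,
                                        meta$r_epi_mm),
                 lesion_angle_deg = meta$lesion_angle_deg,
                 truth = meta$truth),
            class = "label_volume")
}

#' Write / read the longitudinal volume table as CSV
#'
#' @param table data frame with the longitudinal column schema
#'   (`animal_id`, `lesion_id`, `contrast`, `t_min`, `volume_mL`, ...).
#' @param file CSV path.
#' @return `file` / the table as a tibble.
#' @export
write_volume_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_volume_table
#' @export
read_volume_table <- function(file) {
  as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
}
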