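#' Extract one structure's ROI from an image and label volume
#'
#' The mask is the set of voxels whose label equals `label_id`; the image and
#' label grids must match exactly (no resampling is attempted — a mismatch is
#' an error, because silently resampling would change texture).
#'
#' @param image 3D numeric array of intensities.
#' @param labels 3D integer array of structure labels, same dimensions.
#' @param label_id integer label to extract.
#' @param structure,hemisphere names used in error messages and the result.
#' @return list with `mask` (logical array), `intensities` (numeric vector in
#'   array order), `n_voxels`, `structure`, `hemisphere`.
#' @export
extract_roi <- function(image, labels, label_id, structure = NA, hemisphere = NA) {
  if (!identical(dim(image), dim(labels))) {
    stop_pdtex("image grid %s does not match label grid %s",
               paste(dim(image), collapse = "x"),
               paste(dim(labels), collapse = "x"))
  }
  mask <- labels == label_id
  if (!any(mask)) {
    stop_pdtex("empty ROI: label %s (%s, %s) not present in label volume",
               label_id, structure, hemisphere)
  }
  list(mask = mask, intensities = image[mask], n_voxels = sum(mask),
       structure = structure, hemisphere = hemisphere)
}

#' ROI volume in cubic centimetres
#'
#' Whole-voxel volume: voxel count times voxel volume. Intensities play no
#' role; only the mask and the spacing matter.
#'
#' @param mask logical array or an [extract_roi()] result.
#' @param spacing_mm positive numeric triple of voxel sizes in mm.
#' @return volume in cm^3.
#' @export
roi_volume_cm3 <- function(mask, spacing_mm) {
  if (is.list(mask)) mask <- mask$mask
  if (any(spacing_mm <= 0)) stop_pdtex("voxel spacing must be positive")
  n <- sum(mask)
  if (n == 0) stop_pdtex("empty mask has no volume")
  n * prod(spacing_mm) / 1000
}

#' Normalize a structure volume by intracranial volume
#'
#' @param volume_cm3 structure volume, cm^3.
#' @param tiv_cm3 total intracranial volume, cm^3; must be positive.
#' @return dimensionless ratio volume / TIV.
#' @export
normalize_volume <- function(volume_cm3, tiv_cm3) {
  if (any(tiv_cm3 <= 0)) stop_pdtex("intracranial volume must be positive")
  volume_cm3 / tiv_cm3
}

#' Per-structure volumetry table for one subject
#'
#' @param image,labels image and label arrays on the same grid.
#' @param label_map data frame with `structure`, `hemisphere`, `label`.
#' @param spacing_mm voxel spacing, mm.
#' @param tiv_cm3 the subject's intracranial volume, or `NA` to skip
#'   normalization.
#' @return data frame: structure, hemisphere, n_voxels, volume_cm3,
#'   normalized_volume.
#' @export
subject_volumetry <- function(image, labels, label_map, spacing_mm, tiv_cm3 = NA) {
  rows <- lapply(seq_len(nrow(label_map)), function(i) {
    roi <- extract_roi(image, labels, label_map$label[i],
                       label_map$structure[i], label_map$hemisphere[i])
    vol <- roi_volume_cm3(roi$mask, spacing_mm)
    data.frame(structure = label_map$structure[i],
               hemisphere = label_map$hemisphere[i],
               n_voxels = roi$n_voxels,
               volume_cm3 = vol,
               normalized_volume = if (is.na(tiv_cm3)) NA_real_
                                   else normalize_volume(vol, tiv_cm3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
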