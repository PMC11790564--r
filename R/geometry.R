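#' Physical-unit Euclidean distance transform of a 3D mask
#'
#' Computes, for every voxel of the grid, the Euclidean distance in
#' millimetres from its center to the center of the nearest voxel belonging
#' to `mask`. Voxel anisotropy is handled in physical units: a step along an
#' axis costs that axis's voxel dimension. Distances are voxel-center to
#' voxel-center, not to an interpolated sub-voxel surface.
#'
#' @param mask 3D array (logical or 0/1) marking the source structure.
#' @param voxel_size_mm numeric length-3, voxel dimensions in mm.
#' @return numeric 3D array of distances in mm; exactly 0 on source voxels.
#' @export
distance_transform <- function(mask, voxel_size_mm) {
  m <- as_mask(mask)
  vs <- check_voxel_size(voxel_size_mm)
  d2 <- cpp_edt3d_sq(as.logical(m), dim(m), vs)
  array(sqrt(pmax(d2, 0)), dim = dim(m))
}

#' Distance map from the ventricular surface
#'
#' Thin wrapper around [distance_transform()] that refuses an empty
#' ventricle mask, since the juxtaventricular / periventricular / deep
#' partition is undefined without one.
#'
#' @inheritParams distance_transform
#' @param ventricle 3D ventricle mask.
#' @return numeric 3D array of ventricular distances in mm.
#' @export
ventricular_distance <- function(ventricle, voxel_size_mm) {
  m <- as_mask(ventricle, "ventricle")
  if (!any(m))
    stop("ventricle mask is empty: ventricular distance (and the JV/PV/D ",
         "bands) are undefined", call. = FALSE)
  distance_transform(m, voxel_size_mm)
}

#' Band codes used throughout the package
#'
#' Integer coding of the three white-matter compartments by ventricular
#' distance: 1 = JV (juxtaventricular), 2 = PV (periventricular),
#' 3 = D (deep). 0 marks voxels outside the region of interest.
#' @return named integer vector.
#' @export
band_codes <- function() c(JV = 1L, PV = 2L, D = 3L)

band_name <- function(code) names(band_codes())[match(code, band_codes())]

# classify a vector of distances into band codes; boundary convention:
# d <= lo -> JV, lo < d <= hi -> PV, d > hi -> D
classify_band <- function(d, thresholds_mm = c(3, 10)) {
  ifelse(d <= thresholds_mm[1], 1L, ifelse(d <= thresholds_mm[2], 2L, 3L))
}

#' Partition white matter into juxtaventricular / periventricular / deep bands
#'
#' Labels every voxel of `mask` (typically WM plus WMH) by its ventricular
#' distance: JV for d <= 3 mm, PV for 3 < d <= 10 mm, D for d > 10 mm.
#' Boundaries are closed on the inner side so the three bands are an exact
#' partition of the mask.
#'
#' @param dist distance map from [ventricular_distance()], in mm.
#' @param mask 3D mask of the voxels to band (WM plus WMH).
#' @param thresholds_mm the two band thresholds, default `c(3, 10)`.
#' @return integer 3D array: 0 outside `mask`, else a [band_codes()] value.
#' @export
band_regions <- function(dist, mask, thresholds_mm = c(3, 10)) {
  m <- as_mask(mask)
  check_same_grid(dist, m, "distance map", "mask")
  out <- array(0L, dim = dim(m))
  out[m] <- classify_band(dist[m], thresholds_mm)
  out
}

#' Penumbra shells around white matter hyperintensities
#'
#' Builds the 4- and 8-mm penumbra masks: white-matter voxels whose physical
#' distance to the nearest WMH voxel is positive and at most the shell
#' radius. All WMH voxels are excluded from both shells. In `cumulative`
#' mode (the default) the 8-mm shell contains the 4-mm shell; in `annular`
#' mode the second shell covers only the 4-8 mm ring.
#'
#' @param wmh 3D WMH mask (a single lesion or the union of all lesions).
#' @param wm 3D white-matter mask.
#' @param voxel_size_mm voxel dimensions in mm.
#' @param radii_mm shell radii, default `c(4, 8)`.
#' @param mode `"cumulative"` or `"annular"`.
#' @param exclude additional mask to remove from the shells (e.g. the union
#'   of all lesions when `wmh` is a single lesion); default none.
#' @return list with logical arrays `P4`, `P8`, the distance map `dist`,
#'   plus `radii_mm` and `mode`.
#' @export
penumbra_shells <- function(wmh, wm, voxel_size_mm, radii_mm = c(4, 8),
                            mode = c("cumulative", "annular"),
                            exclude = NULL) {
  mode <- match.arg(mode)
  wmh_m <- as_mask(wmh, "wmh")
  wm_m <- as_mask(wm, "wm")
  check_same_grid(wmh_m, wm_m, "wmh", "wm")
  if (!any(wmh_m)) {
    warning("WMH mask is empty; penumbra shells are empty")
    empty <- array(FALSE, dim = dim(wm_m))
    return(list(P4 = empty, P8 = empty,
                dist = array(Inf, dim = dim(wm_m)),
                radii_mm = radii_mm, mode = mode))
  }
  d <- distance_transform(wmh_m, voxel_size_mm)
  drop_mask <- wmh_m
  if (!is.null(exclude)) drop_mask <- drop_mask | as_mask(exclude, "exclude")
  p4 <- wm_m & !drop_mask & d > 0 & d <= radii_mm[1]
  p8 <- wm_m & !drop_mask & d > 0 & d <= radii_mm[2]
  if (mode == "annular") p8 <- p8 & d > radii_mm[1]
  list(P4 = p4, P8 = p8, dist = d, radii_mm = radii_mm, mode = mode)
}

#' Normal-appearing white matter mask
#'
#' NAWM is white matter with all WMH voxels and the full 8-mm penumbra
#' removed. Banded NAWM is obtained by intersecting the result with
#' [band_regions()].
#'
#' @param wm white-matter mask.
#' @param wmh WMH mask.
#' @param p8 the 8-mm (cumulative) penumbra mask.
#' @return logical 3D array.
#' @export
nawm_mask <- function(wm, wmh, p8) {
  wm_m <- as_mask(wm, "wm")
  wmh_m <- as_mask(wmh, "wmh")
  p8_m <- as_mask(p8, "p8")
  check_same_grid(wm_m, wmh_m, "wm", "wmh")
  check_same_grid(wm_m, p8_m, "wm", "p8")
  wm_m & !wmh_m & !p8_m
}
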