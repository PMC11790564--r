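#' Extract mean rCBF and volume for every tissue-by-region ROI
#'
#' Builds the long measurement table for one subject and session: one row
#' per (tissue, region) with the arithmetic mean rCBF over the ROI and its
#' volume. Tissues: GM, WM (the full white-matter mask), WMH, P4, P8, NAWM.
#' Regions: `whole`, plus the JV/PV/D bands for the white-matter tissues.
#' Empty ROIs (e.g. a subject with no deep WMH) yield a row with `NA` mean
#' and reason code rather than being silently dropped.
#'
#' @param rcbf 3D rCBF volume (total-brain normalized).
#' @param anatomy list with `gm`, `wm`, `brain` masks (e.g. from
#'   [generate_anatomy()] or [read_subject()]).
#' @param wmh WMH mask for the session.
#' @param bands integer band map from [band_regions()] over WM + WMH.
#' @param voxel_size_mm voxel dimensions.
#' @param subject,session identifiers copied into the rows.
#' @param radii_mm penumbra radii.
#' @param mode penumbra mode, `"cumulative"` (default) or `"annular"`.
#' @return tibble: `subject`, `session`, `tissue`, `region`, `mean_rcbf`,
#'   `volume_mm3`, `n_voxels`, `reason` (NA unless the ROI is empty).
#' @export
extract_roi_means <- function(rcbf, anatomy, wmh, bands, voxel_size_mm,
                              subject = 1L, session = "baseline",
                              radii_mm = c(4, 8),
                              mode = c("cumulative", "annular")) {
  mode <- match.arg(mode)
  vs <- check_voxel_size(voxel_size_mm)
  voxvol <- prod(vs)
  wmh_m <- as_mask(wmh, "wmh")
  wm_m <- as_mask(anatomy$wm, "wm")
  check_same_grid(rcbf, wm_m, "rcbf", "wm")

  sh <- if (any(wmh_m)) {
    penumbra_shells(wmh_m, wm_m, vs, radii_mm, mode)
  } else {
    list(P4 = array(FALSE, dim(wm_m)), P8 = array(FALSE, dim(wm_m)))
  }
  nawm <- wm_m & !wmh_m & !sh$P8
  tissues <- list(GM = as_mask(anatomy$gm, "gm"), WM = wm_m, WMH = wmh_m,
                  P4 = sh$P4, P8 = sh$P8, NAWM = nawm)

  rows <- list()
  for (tn in names(tissues)) {
    tm <- tissues[[tn]]
    regions <- if (tn == "GM") "whole" else c("whole", names(band_codes()))
    for (rg in regions) {
      sel <- if (rg == "whole") tm else tm & bands == band_codes()[[rg]]
      v <- rcbf[sel]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subject, session = session, tissue = tn, region = rg,
        mean_rcbf = if (length(v)) mean(v) else NA_real_,
        volume_mm3 = sum(sel) * voxvol,
        n_voxels = sum(sel),
        reason = if (length(v)) NA_character_ else "empty ROI")
    }
  }
  out <- do.call(rbind, rows)
  brain_vol <- sum(as_mask(anatomy$brain, "brain")) * voxvol
  attr(out, "brain_volume_mm3") <- brain_vol
  out
}

#' Add log-transformed and centered columns to a measurement table
#'
#' Appends `rvol` (ROI volume over total brain volume), `log_rcbf`,
#' `log_rvol`, and `log_rvol_centered` (log rVol minus the mean log WMH
#' volume over the analysis set, computed once and stored as an attribute).
#' Rows with nonpositive rCBF or volume cannot be log-transformed; they are
#' flagged in `transform_ok` and excluded from the centering constant.
#'
#' @param rows measurement table with `mean_rcbf` and `volume_mm3` columns.
#' @param brain_volume_mm3 per-row total brain volume (recycled scalar or
#'   vector); defaults to the attribute left by [extract_roi_means()].
#' @param center_on rows used for the centering constant: a logical vector,
#'   default the WMH whole-region rows.
#' @param base logarithm base (default natural).
#' @return the table with new columns; centering constant in attribute
#'   `log_rvol_center`.
#' @export
transform_measurements <- function(rows, brain_volume_mm3 = NULL,
                                   center_on = NULL, base = exp(1)) {
  if (is.null(brain_volume_mm3))
    brain_volume_mm3 <- attr(rows, "brain_volume_mm3")
  if (is.null(brain_volume_mm3))
    stop("total brain volume is required to form rVol", call. = FALSE)
  rows$rvol <- rows$volume_mm3 / brain_volume_mm3
  ok <- is.finite(rows$mean_rcbf) & rows$mean_rcbf > 0 & rows$rvol > 0
  rows$transform_ok <- ok
  rows$log_rcbf <- ifelse(ok, log(rows$mean_rcbf, base = base), NA_real_)
  rows$log_rvol <- ifelse(rows$rvol > 0, log(rows$rvol, base = base),
                          NA_real_)
  if (is.null(center_on))
    center_on <- rows$tissue == "WMH" & rows$region == "whole"
  ctr_vals <- rows$log_rvol[center_on & is.finite(rows$log_rvol)]
  ctr <- if (length(ctr_vals)) mean(ctr_vals) else 0
  rows$log_rvol_centered <- rows$log_rvol - ctr
  attr(rows, "log_rvol_center") <- ctr
  attr(rows, "log_base") <- base
  rows
}
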