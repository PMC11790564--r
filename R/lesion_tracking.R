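#' Label individual WMH lesions by connected components
#'
#' Partitions a WMH mask into individual lesions: maximal sets of voxels
#' connected in a three-dimensional neighborhood (26-connectivity by
#' default, i.e. face, edge and corner neighbors). Clusters smaller than
#' `min_volume_mm3` are discarded; a cluster of exactly the floor volume is
#' kept (strict "<" exclusion).
#'
#' @param wmh 3D WMH mask.
#' @param voxel_size_mm voxel dimensions in mm.
#' @param connectivity 6, 18 or 26.
#' @param min_volume_mm3 exclusion floor in mm3 (default 10).
#' @param dist optional ventricular distance map; if supplied, each
#'   cluster's centroid ventricular distance and band are recorded.
#' @param band_thresholds_mm band thresholds for the centroid band.
#' @return tibble with one row per kept cluster (`id`, `n_voxels`,
#'   `volume_mm3`, centroid coordinates in mm, and if `dist` was given
#'   `centroid_distance_mm` and `band`), with the relabeled integer cluster
#'   map as attribute `label_map` (ids match the `id` column).
#' @export
label_clusters <- function(wmh, voxel_size_mm, connectivity = 26L,
                           min_volume_mm3 = 10,
                           dist = NULL, band_thresholds_mm = c(3, 10)) {
  m <- as_mask(wmh, "wmh")
  vs <- check_voxel_size(voxel_size_mm)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  voxvol <- prod(vs)
  lab <- array(cpp_label3d(as.logical(m), dim(m), as.integer(connectivity)),
               dim = dim(m))
  empty <- tibble::tibble(id = integer(0), n_voxels = integer(0),
                          volume_mm3 = numeric(0), cx_mm = numeric(0),
                          cy_mm = numeric(0), cz_mm = numeric(0))
  if (max(lab) == 0L) {
    attr(empty, "label_map") <- lab
    return(empty)
  }
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * voxvol >= min_volume_mm3)
  if (length(keep) == 0L) {
    attr(empty, "label_map") <- array(0L, dim = dim(m))
    return(empty)
  }
  # relabel kept clusters 1..K in original raster order
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  out_map <- array(0L, dim = dim(m))
  nz <- lab > 0L
  out_map[nz] <- remap[lab[nz]]

  idx <- which(out_map > 0L)
  ids <- out_map[idx]
  ai <- arrayInd(idx, dim(m))
  coords <- sweep(ai - 0.5, 2L, vs, `*`)
  cx <- tapply(coords[, 1], ids, mean)
  cy <- tapply(coords[, 2], ids, mean)
  cz <- tapply(coords[, 3], ids, mean)
  res <- tibble::tibble(
    id = seq_along(keep),
    n_voxels = counts[keep],
    volume_mm3 = counts[keep] * voxvol,
    cx_mm = as.numeric(cx), cy_mm = as.numeric(cy), cz_mm = as.numeric(cz))
  if (!is.null(dist)) {
    check_same_grid(dist, m, "dist", "wmh")
    res$centroid_distance_mm <- vapply(seq_along(keep), function(k) {
      sel <- idx[ids == k]
      ctr <- round(colMeans(arrayInd(sel, dim(m))))
      dist[ctr[1], ctr[2], ctr[3]]
    }, numeric(1))
    res$band <- names(band_codes())[
      classify_band(res$centroid_distance_mm, band_thresholds_mm)]
  }
  attr(res, "label_map") <- out_map
  res
}

#' Assign a ventricular-distance band to a lesion cluster
#'
#' Two rules are supported. `centroid` (default): the band of the cluster
#' centroid's ventricular distance. `majority`: the modal voxelwise band
#' over the cluster. Both labels and a disagreement flag are always
#' returned, and the centroid distance is recorded for use as a continuous
#' covariate.
#'
#' @param cluster_voxels linear indices (or logical mask) of the cluster.
#' @param dist ventricular distance map (mm).
#' @param rule `"centroid"` or `"majority"`.
#' @param thresholds_mm band thresholds.
#' @return list: `band` (per `rule`), `band_centroid`, `band_majority`,
#'   `centroid_distance_mm`, `rules_disagree`.
#' @export
assign_band <- function(cluster_voxels, dist,
                        rule = c("centroid", "majority"),
                        thresholds_mm = c(3, 10)) {
  rule <- match.arg(rule)
  if (is.logical(cluster_voxels) || !is.null(dim(cluster_voxels)))
    cluster_voxels <- which(as_mask(cluster_voxels, "cluster_voxels"))
  if (length(cluster_voxels) == 0L)
    stop("empty cluster", call. = FALSE)
  ai <- arrayInd(cluster_voxels, dim(dist))
  ctr <- round(colMeans(ai))
  cdist <- dist[ctr[1], ctr[2], ctr[3]]
  b_centroid <- classify_band(cdist, thresholds_mm)
  vox_bands <- classify_band(dist[cluster_voxels], thresholds_mm)
  tab <- tabulate(vox_bands, nbins = 3L)
  b_majority <- which.max(tab)
  nm <- names(band_codes())
  list(band = nm[if (rule == "centroid") b_centroid else b_majority],
       band_centroid = nm[b_centroid],
       band_majority = nm[b_majority],
       centroid_distance_mm = cdist,
       rules_disagree = b_centroid != b_majority)
}

#' Match lesion clusters across two sessions
#'
#' A follow-up cluster is matched to the baseline cluster with which it
#' shares at least `min_overlap` voxels (default 1); when it overlaps
#' several baseline clusters (a merge), the baseline cluster with maximal
#' overlap volume wins, ties going to the lower baseline id. Unmatched
#' follow-up clusters are `new`; unmatched baseline clusters are
#' `vanished`.
#'
#' @param baseline,followup cluster tables from [label_clusters()] (their
#'   `label_map` attributes are used).
#' @param min_overlap minimum shared voxel count to accept a match.
#' @param threshold growth-classification threshold, see [categorize()].
#' @return tibble with one row per trajectory: `baseline_id`,
#'   `followup_id` (NA where absent), volumes, `volume_change_fraction`,
#'   `category`, `merge_flag`.
#' @export
match_clusters <- function(baseline, followup, min_overlap = 1L,
                           threshold = 0.10) {
  map_bl <- attr(baseline, "label_map")
  map_fu <- attr(followup, "label_map")
  if (is.null(map_bl) || is.null(map_fu))
    stop("cluster tables must carry their 'label_map' attribute",
         call. = FALSE)
  check_same_grid(map_bl, map_fu, "baseline map", "followup map")

  n_bl <- nrow(baseline); n_fu <- nrow(followup)
  overlap <- matrix(0L, nrow = max(n_bl, 1L), ncol = max(n_fu, 1L))
  both <- map_bl > 0L & map_fu > 0L
  if (any(both)) {
    tab <- table(bl = map_bl[both], fu = map_fu[both])
    overlap[cbind(as.integer(rownames(tab))[row(tab)],
                  as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  }

  rows <- list()
  matched_bl <- logical(n_bl)
  for (j in seq_len(n_fu)) {
    ov <- if (n_bl) overlap[, j] else integer(0)
    cand <- which(ov >= min_overlap)
    if (length(cand) == 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        baseline_id = NA_integer_, followup_id = j,
        volume_bl_mm3 = NA_real_,
        volume_fu_mm3 = followup$volume_mm3[j],
        volume_change_fraction = NA_real_,
        category = "new", merge_flag = FALSE)
      next
    }
    best <- cand[order(-ov[cand], cand)][1]
    matched_bl[best] <- TRUE
    vb <- baseline$volume_mm3[best]
    vf <- followup$volume_mm3[j]
    stopifnot(vb > 0)
    frac <- (vf - vb) / vb
    rows[[length(rows) + 1L]] <- tibble::tibble(
      baseline_id = best, followup_id = j,
      volume_bl_mm3 = vb, volume_fu_mm3 = vf,
      volume_change_fraction = frac,
      category = categorize(vb, vf, threshold),
      merge_flag = length(cand) > 1L)
  }
  for (i in which(!matched_bl)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      baseline_id = i, followup_id = NA_integer_,
      volume_bl_mm3 = baseline$volume_mm3[i], volume_fu_mm3 = NA_real_,
      volume_change_fraction = NA_real_,
      category = "vanished", merge_flag = FALSE)
  }
  if (length(rows) == 0L)
    return(tibble::tibble(baseline_id = integer(0), followup_id = integer(0),
                          volume_bl_mm3 = numeric(0),
                          volume_fu_mm3 = numeric(0),
                          volume_change_fraction = numeric(0),
                          category = character(0), merge_flag = logical(0)))
  do.call(rbind, rows)
}

#' Classify a matched lesion's longitudinal trajectory
#'
#' Growth fraction is `(V_followup - V_baseline) / V_baseline`. Strictly
#' more than +10% is `growing`; at or below -10% is `shrinking`; everything
#' in between (including exactly +10%) is `stagnant`.
#'
#' @param volume_bl,volume_fu volumes (any consistent unit).
#' @param threshold classification threshold, default 0.10.
#' @return character category.
#' @export
categorize <- function(volume_bl, volume_fu, threshold = 0.10) {
  stopifnot(volume_bl > 0)
  frac <- (volume_fu - volume_bl) / volume_bl
  if (frac > threshold) "growing"
  else if (frac <= -threshold) "shrinking"
  else "stagnant"
}

#' Lesion-specific penumbra regions of interest
#'
#' Builds the 4- and 8-mm penumbra shells around one lesion while excluding
#' the voxels of every lesion (not just this one), so that adjacent lesions
#' never contaminate each other's penumbra.
#'
#' @param lesion_mask mask (or linear indices) of the single lesion.
#' @param wmh_all union mask of all WMH voxels in the session.
#' @param wm white-matter mask.
#' @param voxel_size_mm voxel dimensions.
#' @param radii_mm shell radii, default `c(4, 8)`.
#' @param mode `"cumulative"` or `"annular"`.
#' @return list with `lesion`, `P4`, `P8` logical masks.
#' @export
lesion_rois <- function(lesion_mask, wmh_all, wm, voxel_size_mm,
                        radii_mm = c(4, 8),
                        mode = c("cumulative", "annular")) {
  mode <- match.arg(mode)
  wm_m <- as_mask(wm, "wm")
  if (!is.logical(lesion_mask) || is.null(dim(lesion_mask))) {
    idx <- lesion_mask
    lesion_mask <- array(FALSE, dim = dim(wm_m))
    lesion_mask[idx] <- TRUE
  }
  sh <- penumbra_shells(lesion_mask, wm_m, voxel_size_mm, radii_mm, mode,
                        exclude = wmh_all)
  list(lesion = as_mask(lesion_mask), P4 = sh$P4, P8 = sh$P8)
}

#' Sample baseline perfusion under a new lesion's footprint
#'
#' For lesions present only at follow-up, measures baseline rCBF in the
#' tissue that later converted: the follow-up lesion footprint (and
#' optionally its penumbra) sampled in the baseline rCBF volume. Voxels
#' outside the baseline brain mask are excluded and counted.
#'
#' @param footprint follow-up lesion mask or linear indices.
#' @param baseline_rcbf baseline rCBF volume.
#' @param brain_mask baseline brain mask.
#' @return list: `mean_rcbf` (NA if the footprint is empty after masking),
#'   `n_voxels`, `n_excluded`.
#' @export
backproject_new <- function(footprint, baseline_rcbf, brain_mask) {
  m <- as_mask(brain_mask, "brain_mask")
  if (!is.logical(footprint) || is.null(dim(footprint))) {
    idx <- footprint
    footprint <- array(FALSE, dim = dim(m))
    footprint[idx] <- TRUE
  }
  check_same_grid(footprint, baseline_rcbf, "footprint", "baseline_rcbf")
  inside <- footprint & m
  n_exc <- sum(footprint) - sum(inside)
  vals <- baseline_rcbf[inside]
  vals <- vals[is.finite(vals)]
  list(mean_rcbf = if (length(vals)) mean(vals) else NA_real_,
       n_voxels = length(vals), n_excluded = n_exc)
}

#' Track lesions across two sessions and build the lesion-level table
#'
#' End-to-end longitudinal lesion analysis for one subject: connected-
#' component labeling at each session, cross-session matching and
#' categorization, per-lesion band assignment, lesion-specific penumbra
#' ROIs, rCBF extraction at both sessions, and baseline back-projection for
#' new lesions. A follow-up cluster whose baseline partner fell below the
#' volume floor is treated as new and flagged.
#'
#' @param wmh_bl,wmh_fu baseline and follow-up WMH masks.
#' @param wm white-matter mask (assumed stable across sessions).
#' @param dist ventricular distance map (mm).
#' @param rcbf_bl,rcbf_fu baseline and follow-up rCBF volumes.
#' @param brain_mask brain mask.
#' @param voxel_size_mm voxel dimensions.
#' @param connectivity,min_volume_mm3,radii_mm,threshold see
#'   [label_clusters()], [lesion_rois()], [categorize()].
#' @return tibble, one row per lesion-session-tissue: `lesion_uid`,
#'   `session`, `tissue` (WMH/P4/P8), `category`, `band`,
#'   `centroid_distance_mm`, `volume_mm3`, `mean_rcbf`.
#' @export
track_lesions <- function(wmh_bl, wmh_fu, wm, dist, rcbf_bl, rcbf_fu,
                          brain_mask, voxel_size_mm,
                          connectivity = 26L, min_volume_mm3 = 10,
                          radii_mm = c(4, 8), threshold = 0.10) {
  bl <- label_clusters(wmh_bl, voxel_size_mm, connectivity, min_volume_mm3,
                       dist = dist)
  fu <- label_clusters(wmh_fu, voxel_size_mm, connectivity, min_volume_mm3,
                       dist = dist)
  traj <- match_clusters(bl, fu, threshold = threshold)
  map_bl <- attr(bl, "label_map")
  map_fu <- attr(fu, "label_map")
  wmh_all_bl <- map_bl > 0L
  wmh_all_fu <- map_fu > 0L

  rows <- list()
  add_row <- function(uid, session, tissue, category, band, cdist, vol,
                      mean_rcbf) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      lesion_uid = uid, session = session, tissue = tissue,
      category = category, band = band, centroid_distance_mm = cdist,
      volume_mm3 = vol, mean_rcbf = mean_rcbf)
  }
  roi_mean <- function(vol, mask) {
    v <- vol[mask]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }

  for (k in seq_len(nrow(traj))) {
    tr <- traj[k, ]
    if (tr$category == "vanished") next
    uid <- sprintf("fu%03d", tr$followup_id)
    fu_mask <- map_fu == tr$followup_id
    info_fu <- fu[fu$id == tr$followup_id, ]
    band <- info_fu$band
    cdist <- info_fu$centroid_distance_mm
    rois_fu <- lesion_rois(fu_mask, wmh_all_fu, wm, voxel_size_mm, radii_mm)

    # follow-up session measurements
    add_row(uid, "followup", "WMH", tr$category, band, cdist,
            tr$volume_fu_mm3, roi_mean(rcbf_fu, fu_mask))
    add_row(uid, "followup", "P4", tr$category, band, cdist,
            sum(rois_fu$P4) * prod(voxel_size_mm),
            roi_mean(rcbf_fu, rois_fu$P4))
    add_row(uid, "followup", "P8", tr$category, band, cdist,
            sum(rois_fu$P8) * prod(voxel_size_mm),
            roi_mean(rcbf_fu, rois_fu$P8))

    if (tr$category == "new") {
      # pre-lesional tissue: follow-up footprint sampled at baseline
      bp <- backproject_new(fu_mask, rcbf_bl, brain_mask)
      add_row(uid, "baseline", "WMH", "new", band, cdist,
              tr$volume_fu_mm3, bp$mean_rcbf)
      add_row(uid, "baseline", "P4", "new", band, cdist,
              sum(rois_fu$P4) * prod(voxel_size_mm),
              roi_mean(rcbf_bl, rois_fu$P4))
      add_row(uid, "baseline", "P8", "new", band, cdist,
              sum(rois_fu$P8) * prod(voxel_size_mm),
              roi_mean(rcbf_bl, rois_fu$P8))
    } else {
      bl_mask <- map_bl == tr$baseline_id
      rois_bl <- lesion_rois(bl_mask, wmh_all_bl, wm, voxel_size_mm,
                             radii_mm)
      add_row(uid, "baseline", "WMH", tr$category, band, cdist,
              tr$volume_bl_mm3, roi_mean(rcbf_bl, bl_mask))
      add_row(uid, "baseline", "P4", tr$category, band, cdist,
              sum(rois_bl$P4) * prod(voxel_size_mm),
              roi_mean(rcbf_bl, rois_bl$P4))
      add_row(uid, "baseline", "P8", tr$category, band, cdist,
              sum(rois_bl$P8) * prod(voxel_size_mm),
              roi_mean(rcbf_bl, rois_bl$P8))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    lesion_uid = character(0), session = character(0), tissue = character(0),
    category = character(0), band = character(0),
    centroid_distance_mm = numeric(0), volume_mm3 = numeric(0),
    mean_rcbf = numeric(0))
  attr(out, "trajectories") <- traj
  out
}
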