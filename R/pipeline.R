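#' Analysis configuration
#'
#' All thresholds and options of the analysis pipeline in one validated
#' list. Defaults are the standard values used throughout: 3/10 mm band
#' thresholds, 4/8 mm cumulative penumbra, 26-connectivity, a 10 mm3 lesion
#' floor and a 10% growth threshold.
#'
#' @param band_thresholds_mm JV/PV and PV/D thresholds (mm).
#' @param penumbra_radii_mm shell radii (mm).
#' @param penumbra_mode `"cumulative"` or `"annular"`.
#' @param connectivity 6, 18 or 26.
#' @param min_lesion_volume_mm3 exclusion floor.
#' @param growth_threshold growth classification threshold.
#' @param quant a [quant_params()] object (used when quantifying raw ASL).
#' @param p_adjust_method multiplicity correction method.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(band_thresholds_mm = c(3, 10),
                            penumbra_radii_mm = c(4, 8),
                            penumbra_mode = "cumulative",
                            connectivity = 26L,
                            min_lesion_volume_mm3 = 10,
                            growth_threshold = 0.10,
                            quant = quant_params(),
                            p_adjust_method = "BH") {
  stopifnot(all(band_thresholds_mm > 0),
            band_thresholds_mm[1] < band_thresholds_mm[2],
            all(penumbra_radii_mm > 0),
            penumbra_radii_mm[1] < penumbra_radii_mm[2],
            min_lesion_volume_mm3 > 0, growth_threshold > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Analyze one session's volumes into ROI measurements
#'
#' The core cross-sectional pipeline for one subject-session, working only
#' from raw mask and CBF volumes: normalize CBF to the total-brain mean,
#' compute the ventricular distance map and JV/PV/D bands, build penumbra
#' shells and NAWM, and extract the tissue-by-region mean-rCBF table.
#'
#' @param vols list with `ventricle`, `wm`, `gm`, `brain`, `wmh`, `cbf`
#'   arrays and `voxel_size_mm` (e.g. from [read_subject()]).
#' @param config a [pipeline_config()].
#' @param subject,session identifiers for the output rows.
#' @return the [extract_roi_means()] tibble, with the band map, distance
#'   map and rCBF volume attached as attributes.
#' @export
analyze_session <- function(vols, config = pipeline_config(),
                            subject = 1L, session = "baseline") {
  vs <- vols$voxel_size_mm
  rcbf <- relative_cbf(vols$cbf, vols$brain)
  dist <- ventricular_distance(vols$ventricle, vs)
  wmh <- as_mask(vols$wmh, "wmh")
  bands <- band_regions(dist, as_mask(vols$wm) | wmh,
                        config$band_thresholds_mm)
  rows <- extract_roi_means(rcbf, vols, wmh, bands, vs,
                            subject = subject, session = session,
                            radii_mm = config$penumbra_radii_mm,
                            mode = config$penumbra_mode)
  attr(rows, "bands") <- bands
  attr(rows, "dist") <- dist
  attr(rows, "rcbf") <- rcbf
  rows
}

#' Run the full pipeline over a synthetic cohort held in memory
#'
#' Simulates every subject of `spec`, then re-derives all geometry from the
#' raw masks (never from the generator's internal labels): ROI tables per
#' session and, for longitudinal subjects, tracked lesion-level tables.
#'
#' @param spec a [cohort_spec()].
#' @param config a [pipeline_config()].
#' @param progress print a dot per subject.
#' @return list: `roi` (cross-sectional and longitudinal ROI rows),
#'   `lesions` (lesion-level rows with subject ids), `truth` (generator
#'   truth rows), `demographics`.
#' @export
run_cohort <- function(spec, config = pipeline_config(), progress = FALSE) {
  roi <- list(); les <- list(); truth <- list(); demo <- list()
  for (i in seq_len(spec$n_subjects)) {
    subj <- simulate_subject(spec, i)
    vs <- subj$anatomy$voxel_size_mm
    base_vols <- c(subj$anatomy[c("ventricle", "wm", "gm", "csf", "brain")],
                   list(voxel_size_mm = vs))
    for (ses in names(subj$cbf)) {
      labels <- if (ses == "baseline") subj$lesions$labels_bl
                else subj$lesions$labels_fu
      vols <- c(base_vols, list(wmh = labels > 0L, cbf = subj$cbf[[ses]]))
      rows <- analyze_session(vols, config, subject = i, session = ses)
      bv <- attr(rows, "brain_volume_mm3")
      rows <- tibble::as_tibble(rows)
      rows$brain_volume_mm3 <- bv
      roi[[length(roi) + 1L]] <- rows
    }
    if (subj$longitudinal) {
      dist <- ventricular_distance(subj$anatomy$ventricle, vs)
      rcbf_bl <- relative_cbf(subj$cbf$baseline, subj$anatomy$brain)
      rcbf_fu <- relative_cbf(subj$cbf$followup, subj$anatomy$brain)
      lt <- track_lesions(
        subj$lesions$labels_bl > 0L, subj$lesions$labels_fu > 0L,
        subj$anatomy$wm, dist, rcbf_bl, rcbf_fu, subj$anatomy$brain, vs,
        connectivity = config$connectivity,
        min_volume_mm3 = config$min_lesion_volume_mm3,
        radii_mm = config$penumbra_radii_mm,
        threshold = config$growth_threshold)
      if (nrow(lt)) {
        lt$subject <- i
        les[[length(les) + 1L]] <- tibble::as_tibble(lt)
      }
    }
    tr <- subj$lesions$truth
    if (!is.null(tr) && nrow(tr)) {
      tr$subject <- i
      truth[[length(truth) + 1L]] <- tr
    }
    demo[[length(demo) + 1L]] <- subj$demographics
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  list(roi = do.call(rbind, roi),
       lesions = if (length(les)) do.call(rbind, les) else NULL,
       truth = do.call(rbind, truth),
       demographics = do.call(rbind, demo))
}

#' Run the analysis pipeline over an emitted cohort directory
#'
#' Disk-based counterpart of [run_cohort()]: scans `dir` for
#' `sub-*/ses-*` directories written by [emit_cohort()] (or arranged the
#' same way from real data), reads each session's mask and CBF volumes,
#' and produces the same ROI and lesion-level tables, re-deriving all
#' geometry from the raw volumes.
#'
#' @param dir cohort directory.
#' @param config a [pipeline_config()].
#' @return list with `roi` and `lesions` tibbles.
#' @export
run_cohort_dir <- function(dir, config = pipeline_config()) {
  subs <- sort(list.files(dir, pattern = "^sub-"))
  if (!length(subs)) stop("no sub-* directories under ", dir, call. = FALSE)
  roi <- list(); les <- list()
  for (sd in subs) {
    i <- as.integer(sub("sub-", "", sd))
    sessions <- sort(list.files(file.path(dir, sd), pattern = "^ses-"))
    vols <- list()
    for (ses in sessions) {
      nm <- if (ses == "ses-1") "baseline" else "followup"
      vols[[nm]] <- read_subject(dir, i, nm)
      rows <- analyze_session(vols[[nm]], config, subject = i, session = nm)
      bv <- attr(rows, "brain_volume_mm3")
      rows <- tibble::as_tibble(rows)
      rows$brain_volume_mm3 <- bv
      roi[[length(roi) + 1L]] <- rows
    }
    if (!is.null(vols$followup)) {
      b <- vols$baseline; f <- vols$followup
      vs <- b$voxel_size_mm
      dist <- ventricular_distance(b$ventricle, vs)
      lt <- track_lesions(b$wmh != 0, f$wmh != 0, b$wm != 0, dist,
                          relative_cbf(b$cbf, b$brain),
                          relative_cbf(f$cbf, f$brain),
                          b$brain != 0, vs,
                          connectivity = config$connectivity,
                          min_volume_mm3 = config$min_lesion_volume_mm3,
                          radii_mm = config$penumbra_radii_mm,
                          threshold = config$growth_threshold)
      if (nrow(lt)) {
        lt$subject <- i
        les[[length(les) + 1L]] <- tibble::as_tibble(lt)
      }
    }
  }
  list(roi = do.call(rbind, roi),
       lesions = if (length(les)) do.call(rbind, les) else NULL)
}

#' Cohort summary of per-subject ROI means
#'
#' Averages each subject's ROI mean rCBF, then summarizes across subjects
#' (mean and SEM per tissue-region cell), the form in which tissue and
#' band perfusion profiles are usually reported.
#'
#' @param roi ROI table from [run_cohort()].
#' @param session which session to summarize.
#' @return tibble with `tissue`, `region`, `n`, `mean_rcbf`, `sem`.
#' @export
summarize_cohort <- function(roi, session = "baseline") {
  d <- roi[roi$session == session & is.finite(roi$mean_rcbf), ]
  key <- interaction(d$tissue, d$region, drop = TRUE)
  agg <- lapply(split(d, key), function(g) {
    tibble::tibble(tissue = g$tissue[1], region = g$region[1],
                   n = nrow(g), mean_rcbf = mean(g$mean_rcbf),
                   sem = sd(g$mean_rcbf) / sqrt(nrow(g)))
  })
  out <- do.call(rbind, agg)
  out[order(out$tissue, out$region), ]
}
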