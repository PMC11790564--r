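#' Default tissue rCBF painting factors
#'
#' Dimensionless perfusion factors, relative to the nominal total-brain mean,
#' used to paint synthetic CBF volumes. The whole-tissue set carries one
#' factor per tissue class (GM, WMH, the 4-mm penumbra, the cumulative 8-mm
#' penumbra, and NAWM). The banded set instead carries separate WMH and NAWM
#' factors for the juxtaventricular, periventricular and deep compartments,
#' emulating the strong ventricular-distance gradient seen in elderly
#' cohorts.
#'
#' @param banded if `TRUE`, WMH and NAWM factors are per-band named vectors
#'   `c(JV=, PV=, D=)`; otherwise scalars.
#' @return list with elements `gm`, `wmh`, `p4`, `p8_cum`, `nawm`.
#' @export
tissue_factor_defaults <- function(banded = FALSE) {
  if (banded) {
    list(gm = 1.315,
         wmh = c(JV = 0.495, PV = 0.592, D = 0.892),
         p4 = 0.845, p8_cum = 0.880,
         nawm = c(JV = 0.816, PV = 0.973, D = 1.156))
  } else {
    list(gm = 1.315, wmh = 0.814, p4 = 0.845, p8_cum = 0.880, nawm = 1.067)
  }
}

#' Specification of a synthetic two-session cohort
#'
#' Collects every tunable of the synthetic cohort generator: grid geometry,
#' tissue perfusion factors, noise level, lesion size/count/category
#' distributions, growth factors, inter-scan interval and demographics.
#' Defaults emulate an elderly cohort imaged on a ~1 x 1 x 2 mm FLAIR-space
#' grid with follow-up roughly two years later.
#'
#' @param n_subjects number of subjects (all have a baseline session).
#' @param n_longitudinal how many of them also have a follow-up session.
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_size_mm positive triple of voxel dimensions (mm).
#' @param tissue_rcbf_factors see [tissue_factor_defaults()].
#' @param nominal_brain_cbf nominal total-brain CBF in ml/100g/min.
#' @param voxel_noise_cv coefficient of variation of voxelwise Gaussian
#'   noise on painted CBF.
#' @param lesion_count_lambda,lesion_count_min lesions per subject are
#'   `lesion_count_min + Poisson(lesion_count_lambda)`.
#' @param lesion_radius_meanlog,lesion_radius_sdlog log-normal parameters of
#'   the nominal lesion radius (mm); radii are clamped to
#'   `lesion_radius_range_mm`.
#' @param lesion_radius_range_mm allowed radius range (mm).
#' @param category_fractions named fractions over
#'   `stagnant/growing/new/shrinking`; must sum to 1.
#' @param growth_meanlog,growth_sdlog log-normal parameters of the
#'   follow-up/baseline volume ratio of growing lesions; draws below
#'   `growth_min` are redrawn (rejection), keeping planted ratios clear of
#'   the 10% classification boundary.
#' @param growth_min lower truncation of the growth ratio.
#' @param shrink_factor volume ratio applied to shrinking lesions.
#' @param category_log_offsets named additive log-rCBF offsets applied to a
#'   lesion's (pre-)lesional footprint in the baseline session, by category.
#' @param inter_scan_years_mean,inter_scan_years_sd inter-scan interval.
#' @param age_mean,age_sd,mmse_mean,mmse_sd,female_fraction demographics.
#' @param min_lesion_voxels smallest baseline (or new-lesion follow-up)
#'   lesion size in voxels; keeps growth-ratio granularity within 2% of any
#'   planted ratio.
#' @param ventricle_semi_mm nominal ventricle ellipsoid semi-axes (mm);
#'   jittered per subject.
#' @param penumbra_radii_mm,band_thresholds_mm geometry constants the
#'   generator shares with the analysis pipeline.
#' @param seed integer master seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 300,
                        n_longitudinal = 90,
                        grid_shape = c(96L, 96L, 48L),
                        voxel_size_mm = c(1, 1, 2),
                        tissue_rcbf_factors = tissue_factor_defaults(),
                        nominal_brain_cbf = 40,
                        voxel_noise_cv = 0.05,
                        lesion_count_lambda = 5,
                        lesion_count_min = 3L,
                        lesion_radius_meanlog = log(3.2),
                        lesion_radius_sdlog = 0.30,
                        lesion_radius_range_mm = c(2.3, 6),
                        category_fractions = c(stagnant = 0.5, growing = 0.3,
                                               new = 0.2, shrinking = 0),
                        growth_meanlog = log(1.35),
                        growth_sdlog = 0.15,
                        growth_min = 1.15,
                        shrink_factor = 0.7,
                        category_log_offsets = c(stagnant = 0, growing = 0,
                                                 new = 0, shrinking = 0),
                        inter_scan_years_mean = 1.9,
                        inter_scan_years_sd = 0.7,
                        age_mean = 77, age_sd = 7.9,
                        mmse_mean = 28, mmse_sd = 2.4,
                        female_fraction = 199 / 300,
                        min_lesion_voxels = 25L,
                        ventricle_semi_mm = c(10, 20, 9),
                        penumbra_radii_mm = c(4, 8),
                        band_thresholds_mm = c(3, 10),
                        seed = 1L) {
  spec <- as.list(environment())
  vs <- check_voxel_size(voxel_size_mm)
  if (abs(sum(category_fractions) - 1) > 1e-9)
    stop("category_fractions must sum to 1", call. = FALSE)
  if (any(category_fractions < 0))
    stop("category_fractions must be non-negative", call. = FALSE)
  if (voxel_noise_cv < 0) stop("voxel_noise_cv must be >= 0", call. = FALSE)
  f <- tissue_rcbf_factors
  if (any(unlist(f) <= 0))
    stop("tissue_rcbf_factors must all be positive", call. = FALSE)
  needed <- c("gm", "wmh", "p4", "p8_cum", "nawm")
  if (!all(needed %in% names(f)))
    stop("tissue_rcbf_factors must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (n_longitudinal > n_subjects)
    stop("n_longitudinal cannot exceed n_subjects", call. = FALSE)
  spec$grid_shape <- as.integer(grid_shape)
  spec$voxel_size_mm <- vs
  structure(spec, class = "cohort_spec")
}

# per-subject, per-stage RNG stream; kept well below .Machine$integer.max
subject_seed <- function(spec, subject_index, stage) {
  base <- (as.numeric(spec$seed) %% 100000) * 20011
  as.integer((base + subject_index * 613 + stage * 97) %% 214748329)
}

#' Generate the anatomical label set for one synthetic subject
#'
#' Builds a brain phantom of nested ellipsoids on the spec's grid: an outer
#' sulcal-CSF shell, a gray-matter shell, a white-matter core, and a
#' connected central ventricular system. Per-subject jitter of the ellipsoid
#' semi-axes provides anatomical variability. Labels are mutually disjoint
#' and tile the brain mask exactly.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 1-based subject number.
#' @return list with logical arrays `ventricle`, `wm`, `gm`, `csf`, `brain`,
#'   the ventricular distance map `vent_dist` (mm), and `voxel_size_mm`.
#' @export
generate_anatomy <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  dims <- spec$grid_shape
  vs <- spec$voxel_size_mm
  extent <- dims * vs
  with_local_seed(subject_seed(spec, subject_index, 1L), {
    jitter_brain <- runif(3, 0.97, 1.0)
    jitter_vent <- runif(3, 0.92, 1.08)

    brain_semi <- (extent / 2 - 2) * jitter_brain
    vent_semi <- spec$ventricle_semi_mm * jitter_vent

    # honor the deep band: >10 mm of WM must fit between ventricle and GM
    wm_semi <- brain_semi * 0.80
    gap <- wm_semi - vent_semi
    if (any(gap < 12)) {
      ax <- c("x", "y", "z")[which.min(gap)]
      stop(sprintf(paste0("grid too small along %s to honor the 10-mm deep ",
                          "band: only %.1f mm of WM around the ventricle"),
                   ax, min(gap)), call. = FALSE)
    }

    ctr <- extent / 2
    x <- (seq_len(dims[1]) - 0.5) * vs[1] - ctr[1]
    y <- (seq_len(dims[2]) - 0.5) * vs[2] - ctr[2]
    z <- (seq_len(dims[3]) - 0.5) * vs[3] - ctr[3]

    radial <- function(semi) {
      r2 <- outer(outer((x / semi[1])^2, (y / semi[2])^2, `+`),
                  (z / semi[3])^2, `+`)
      sqrt(r2)
    }
    rb <- radial(brain_semi)
    rv <- radial(vent_semi)

    brain <- rb <= 1
    csf <- brain & rb > 0.94          # sulcal CSF, outer shell
    gm <- brain & rb <= 0.94 & rb > 0.80
    ventricle <- rv <= 1
    wm <- brain & rb <= 0.80 & !ventricle

    vent_dist <- ventricular_distance(ventricle, vs)
    if (max(vent_dist[wm]) <= spec$band_thresholds_mm[2])
      stop("grid too small: no WM deeper than the outer band threshold",
           call. = FALSE)

    list(ventricle = ventricle, wm = wm, gm = gm, csf = csf, brain = brain,
         vent_dist = vent_dist, voxel_size_mm = vs)
  })
}

# grow a connected, roughly spherical blob of n_target voxels inside `wm`,
# by geodesic accretion ordered by physical distance to the seed center.
# Returns full-grid linear indices in accretion order, or NULL if the
# region cannot hold n_target voxels within the local search box.
geodesic_ball <- function(wm, center, n_target, voxel_size_mm,
                          box_margin_mm = 14) {
  dims <- dim(wm)
  half <- ceiling(box_margin_mm / voxel_size_mm)
  lo <- pmax(center - half, 1L)
  hi <- pmin(center + half, dims)
  sub <- wm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sd_ <- dim(sub)
  c0 <- center - lo + 1L
  ax <- ((seq_len(sd_[1]) - c0[1]) * voxel_size_mm[1])^2
  ay <- ((seq_len(sd_[2]) - c0[2]) * voxel_size_mm[2])^2
  az <- ((seq_len(sd_[3]) - c0[3]) * voxel_size_mm[3])^2
  d2 <- outer(outer(ax, ay, `+`), az, `+`)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]

  start <- c0[1] + (c0[2] - 1L) * sd_[1] + (c0[3] - 1L) * sd_[1] * sd_[2]
  if (!sub[start]) return(NULL)

  in_set <- logical(length(sub))
  in_cand <- logical(length(sub))
  cand <- integer(0)
  in_cand[start] <- TRUE
  cand <- start
  picked <- integer(n_target)
  n_picked <- 0L

  while (n_picked < n_target && length(cand) > 0L) {
    j <- cand[which.min(d2[cand])]
    cand <- cand[cand != j]
    in_cand[j] <- FALSE
    in_set[j] <- TRUE
    n_picked <- n_picked + 1L
    picked[n_picked] <- j
    ai <- arrayInd(j, sd_)
    nb <- sweep(offs, 2L, as.integer(ai), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= sd_[1] &
      nb[, 2] >= 1 & nb[, 2] <= sd_[2] &
      nb[, 3] >= 1 & nb[, 3] <= sd_[3]
    nb <- nb[ok, , drop = FALSE]
    nbl <- nb[, 1] + (nb[, 2] - 1L) * sd_[1] + (nb[, 3] - 1L) * sd_[1] * sd_[2]
    new_c <- nbl[sub[nbl] & !in_set[nbl] & !in_cand[nbl]]
    if (length(new_c)) {
      in_cand[new_c] <- TRUE
      cand <- c(cand, new_c)
    }
  }
  if (n_picked < n_target) return(NULL)

  ai <- arrayInd(picked, sd_)
  gi <- sweep(ai, 2L, lo - 1L, `+`)
  as.integer(gi[, 1] + (gi[, 2] - 1L) * dims[1] +
               (gi[, 3] - 1L) * dims[1] * dims[2])
}

# mark a voxel index set plus its 26-neighborhood in a logical array
mark_with_halo <- function(occ, idx) {
  dims <- dim(occ)
  ai <- arrayInd(idx, dims)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    sh <- cbind(pmin(pmax(ai[, 1] + dx, 1L), dims[1]),
                pmin(pmax(ai[, 2] + dy, 1L), dims[2]),
                pmin(pmax(ai[, 3] + dz, 1L), dims[3]))
    occ[sh] <- TRUE
  }
  occ
}

#' Plant lesions with known longitudinal trajectories
#'
#' Places connected lesion blobs in white matter, cycling deterministically
#' through the three target bands (JV, PV, D) so every compartment is
#' populated, with per-lesion category (stagnant / growing / new /
#' shrinking) drawn from the spec's fractions. Growing lesions are enlarged
#' at follow-up by geodesic dilation inside WM to hit the sampled volume
#' ratio within 2%; new lesions exist only at follow-up; stagnant lesions
#' are voxel-identical across sessions.
#'
#' @param anatomy output of [generate_anatomy()].
#' @param spec a [cohort_spec()].
#' @param subject_index 1-based subject number.
#' @param longitudinal if `FALSE`, every lesion is treated as baseline-only
#'   (categories still drawn, used for painting offsets only at baseline).
#' @return list with integer label arrays `labels_bl`, `labels_fu` (0 =
#'   background, k = lesion id) and a `truth` tibble (one row per lesion:
#'   id, category, planted band, centroid ventricular distance mm, baseline
#'   and follow-up volumes mm3, planted volume ratio, baseline log-rCBF
#'   offset).
#' @export
plant_lesions <- function(anatomy, spec, subject_index, longitudinal = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  dims <- dim(anatomy$wm)
  vs <- anatomy$voxel_size_mm
  voxvol <- prod(vs)
  with_local_seed(subject_seed(spec, subject_index, 2L), {
    n_lesions <- spec$lesion_count_min + rpois(1, spec$lesion_count_lambda)
    cats <- sample(names(spec$category_fractions), n_lesions, replace = TRUE,
                   prob = spec$category_fractions)
    if (!longitudinal) cats[] <- "stagnant"
    bands <- rep(c("JV", "PV", "D"), length.out = n_lesions)

    band_code_map <- band_codes()
    vox_band <- band_regions(anatomy$vent_dist, anatomy$wm,
                             spec$band_thresholds_mm)

    labels_bl <- array(0L, dim = dims)
    labels_fu <- array(0L, dim = dims)
    occupied <- array(FALSE, dim = dims)

    rows <- vector("list", n_lesions)
    for (k in seq_len(n_lesions)) {
      r <- rlnorm(1, spec$lesion_radius_meanlog, spec$lesion_radius_sdlog)
      r <- min(max(r, spec$lesion_radius_range_mm[1]),
               spec$lesion_radius_range_mm[2])
      n_bl <- max(spec$min_lesion_voxels,
                  as.integer(round(4 / 3 * pi * r^3 / voxvol)))
      ratio <- switch(cats[k],
        stagnant = 1,
        growing = {
          g <- rlnorm(1, spec$growth_meanlog, spec$growth_sdlog)
          while (g < spec$growth_min)
            g <- rlnorm(1, spec$growth_meanlog, spec$growth_sdlog)
          g
        },
        new = 1,
        shrinking = spec$shrink_factor)
      n_fu <- max(spec$min_lesion_voxels, as.integer(round(n_bl * ratio)))
      n_max <- max(n_bl, n_fu)

      eligible <- which(anatomy$wm & !occupied &
                          vox_band == band_code_map[[bands[k]]])
      placed <- FALSE
      for (try in seq_len(50L)) {
        if (length(eligible) == 0L) break
        ctr_lin <- eligible[sample.int(length(eligible), 1L)]
        ctr <- as.integer(arrayInd(ctr_lin, dims))
        vox <- geodesic_ball(anatomy$wm, ctr, n_max, vs)
        if (is.null(vox) || any(occupied[vox])) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place lesion %d in band %s after 50 tries",
                     k, bands[k]), call. = FALSE)

      vox_bl <- if (cats[k] == "new") integer(0) else vox[seq_len(n_bl)]
      vox_fu <- switch(cats[k],
        stagnant = vox[seq_len(n_bl)],
        growing = vox[seq_len(n_fu)],
        new = vox[seq_len(n_fu)],
        shrinking = vox[seq_len(n_fu)])
      footprint <- vox[seq_len(n_max)]

      labels_bl[vox_bl] <- k
      labels_fu[vox_fu] <- k
      occupied <- mark_with_halo(occupied, footprint)

      ref_vox <- if (length(vox_bl)) vox_bl else vox_fu
      ai <- arrayInd(ref_vox, dims)
      centroid_mm <- colMeans(sweep(ai - 0.5, 2L, vs, `*`))
      cdist <- mean_centroid_distance(anatomy$vent_dist, ref_vox, dims, vs)
      band_planted <- names(band_code_map)[
        classify_band(cdist, spec$band_thresholds_mm)]

      rows[[k]] <- tibble::tibble(
        lesion_id = k, category = cats[k], band = band_planted,
        target_band = bands[k], centroid_distance_mm = cdist,
        volume_bl_mm3 = length(vox_bl) * voxvol,
        volume_fu_mm3 = length(vox_fu) * voxvol,
        planted_ratio = ratio,
        log_offset = unname(spec$category_log_offsets[cats[k]]))
    }
    list(labels_bl = labels_bl, labels_fu = labels_fu,
         truth = do.call(rbind, rows))
  })
}

# ventricular distance at the (continuous) centroid, approximated by
# trilinear-free nearest sampling of the distance map at the centroid voxel
mean_centroid_distance <- function(vent_dist, vox, dims, vs) {
  ai <- arrayInd(vox, dims)
  ctr <- round(colMeans(ai))
  vent_dist[ctr[1], ctr[2], ctr[3]]
}

#' Paint a synthetic CBF volume over anatomy and lesions
#'
#' Assigns each brain voxel a CBF value equal to the nominal brain CBF times
#' its tissue factor, then adds voxelwise independent Gaussian noise with
#' the spec's coefficient of variation. Tissue precedence inside WM:
#' WMH lesion voxels (band-specific factor if the spec's factors are
#' banded), then the 0-4 mm penumbra, then the 4-8 mm annulus, then NAWM
#' (band-specific if banded). The 4-8 mm annulus value is solved per volume
#' so that the cumulative 0-8 mm penumbra mean equals the spec's `p8_cum`
#' factor. CSF and ventricular voxels are painted at a single calibrated
#' value chosen so the noise-free brain-mask mean equals the nominal brain
#' CBF exactly.
#'
#' Baseline sessions additionally apply each lesion's category log-offset to
#' its (pre-)lesional footprint: for `new` lesions the follow-up footprint
#' is offset at baseline, emulating hypoperfused tissue that later converts.
#'
#' @param anatomy output of [generate_anatomy()].
#' @param lesions output of [plant_lesions()].
#' @param spec a [cohort_spec()].
#' @param subject_index subject number (seeds the noise stream).
#' @param session `"baseline"` or `"followup"`.
#' @return numeric 3D CBF array (ml/100g/min); attributes `csf_value`
#'   (painted CSF factor), `p8_annulus_factor`, and `factor_map` (the
#'   noise-free factor volume).
#' @export
paint_cbf <- function(anatomy, lesions, spec, subject_index,
                      session = c("baseline", "followup")) {
  session <- match.arg(session)
  stopifnot(inherits(spec, "cohort_spec"))
  f <- spec$tissue_rcbf_factors
  dims <- dim(anatomy$wm)
  vs <- anatomy$voxel_size_mm
  labels <- if (session == "baseline") lesions$labels_bl else lesions$labels_fu
  wmh <- labels > 0L

  vox_band <- band_regions(anatomy$vent_dist, anatomy$wm | wmh,
                           spec$band_thresholds_mm)
  shells <- if (any(wmh)) {
    penumbra_shells(wmh, anatomy$wm, vs, spec$penumbra_radii_mm, "cumulative")
  } else {
    list(P4 = array(FALSE, dims), P8 = array(FALSE, dims))
  }
  annulus <- shells$P8 & !shells$P4

  factor_map <- array(0, dim = dims)
  factor_map[anatomy$gm] <- f$gm

  banded <- length(f$wmh) == 3L
  nawm_vox <- anatomy$wm & !wmh & !shells$P8
  if (banded) {
    for (b in names(band_codes())) {
      sel <- wmh & vox_band == band_codes()[[b]]
      factor_map[sel] <- f$wmh[[b]]
      seln <- nawm_vox & vox_band == band_codes()[[b]]
      factor_map[seln] <- f$nawm[[b]]
    }
  } else {
    factor_map[wmh] <- f$wmh
    factor_map[nawm_vox] <- f$nawm
  }
  factor_map[shells$P4] <- f$p4

  # solve the 4-8 mm annulus factor so the cumulative 0-8 mm mean = p8_cum
  n4 <- sum(shells$P4); n48 <- sum(annulus)
  ann_factor <- if (n48 > 0) {
    (f$p8_cum * (n4 + n48) - f$p4 * n4) / n48
  } else f$p8_cum
  if (ann_factor <= 0)
    stop("penumbra factors inconsistent: solved 4-8 mm annulus factor is ",
         "not positive", call. = FALSE)
  factor_map[annulus] <- ann_factor

  # baseline-session category offsets on (pre-)lesional footprints
  if (session == "baseline" && any(spec$category_log_offsets != 0) &&
      nrow(lesions$truth) > 0) {
    for (k in seq_len(nrow(lesions$truth))) {
      off <- lesions$truth$log_offset[k]
      if (off == 0) next
      id <- lesions$truth$lesion_id[k]
      fp <- if (lesions$truth$category[k] == "new") {
        lesions$labels_fu == id
      } else {
        lesions$labels_bl == id
      }
      factor_map[fp] <- factor_map[fp] * exp(off)
    }
  }

  # calibrate CSF + ventricle so the noise-free brain-mask mean is exact
  csf_all <- anatomy$csf | anatomy$ventricle
  n_brain <- sum(anatomy$brain)
  n_csf <- sum(csf_all)
  tissue_sum <- sum(factor_map[anatomy$brain & !csf_all])
  csf_value <- (n_brain - tissue_sum) / n_csf
  if (csf_value < 0)
    stop("tissue rCBF factors are inconsistent with a total-brain ",
         "normalizer of 1: calibrated CSF value would be negative",
         call. = FALSE)
  factor_map[csf_all] <- csf_value

  cbf <- factor_map * spec$nominal_brain_cbf
  if (spec$voxel_noise_cv > 0) {
    stage <- if (session == "baseline") 3L else 4L
    with_local_seed(subject_seed(spec, subject_index, stage), {
      noise <- rnorm(sum(anatomy$brain), 0, spec$voxel_noise_cv)
      cbf[anatomy$brain] <- cbf[anatomy$brain] * (1 + noise)
    })
  }
  attr(cbf, "csf_value") <- csf_value
  attr(cbf, "p8_annulus_factor") <- ann_factor
  attr(cbf, "factor_map") <- factor_map
  cbf
}

#' Simulate one complete subject
#'
#' Convenience wrapper: anatomy, lesions, painted CBF for each session, and
#' demographics, all deterministic given `(spec$seed, subject_index)`.
#'
#' @inheritParams plant_lesions
#' @return list with `anatomy`, `lesions`, `cbf` (named list of sessions),
#'   `demographics` (one-row tibble), and `longitudinal` flag.
#' @export
simulate_subject <- function(spec, subject_index) {
  longitudinal <- subject_index <= spec$n_longitudinal
  anatomy <- generate_anatomy(spec, subject_index)
  lesions <- plant_lesions(anatomy, spec, subject_index, longitudinal)
  cbf <- list(baseline = paint_cbf(anatomy, lesions, spec, subject_index,
                                   "baseline"))
  if (longitudinal)
    cbf$followup <- paint_cbf(anatomy, lesions, spec, subject_index,
                              "followup")
  demo <- with_local_seed(subject_seed(spec, subject_index, 5L), {
    tibble::tibble(
      subject = subject_index,
      age = max(65, rnorm(1, spec$age_mean, spec$age_sd)),
      sex = if (runif(1) < spec$female_fraction) "F" else "M",
      mmse = min(30, round(rnorm(1, spec$mmse_mean, spec$mmse_sd))),
      interval_years = if (longitudinal)
        max(0.5, rnorm(1, spec$inter_scan_years_mean,
                       spec$inter_scan_years_sd)) else NA_real_,
      longitudinal = longitudinal)
  })
  list(anatomy = anatomy, lesions = lesions, cbf = cbf,
       demographics = demo, longitudinal = longitudinal)
}

#' Write a synthetic cohort to disk
#'
#' One directory per subject and session holding gzipped NIfTI volumes
#' (anatomy masks, lesion labels, CBF) with voxel dimensions in the header,
#' plus cohort-level truth tables (`truth_lesions.csv`,
#' `participants.csv`) and a JSON manifest recording the spec and seed.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
emit_cohort <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  truth_all <- list()
  demo_all <- list()
  for (i in seq_len(spec$n_subjects)) {
    subj <- simulate_subject(spec, i)
    sessions <- names(subj$cbf)
    for (ses in sessions) {
      sdir <- file.path(dir, sprintf("sub-%03d", i),
                        if (ses == "baseline") "ses-1" else "ses-2")
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      labels <- if (ses == "baseline") subj$lesions$labels_bl
                else subj$lesions$labels_fu
      vols <- list(ventricle = subj$anatomy$ventricle,
                   wm = subj$anatomy$wm, gm = subj$anatomy$gm,
                   csf = subj$anatomy$csf, brain = subj$anatomy$brain,
                   wmh = labels > 0L, lesion_labels = labels,
                   cbf = subj$cbf[[ses]])
      for (nm in names(vols)) {
        v <- vols[[nm]]
        storage <- if (is.logical(v)) "uint8"
                   else if (is.integer(v)) "int16" else "float"
        arr <- array(if (is.logical(v)) as.integer(v) else as.vector(v),
                     dim = dim(v))
        attr(arr, "pixdim") <- subj$anatomy$voxel_size_mm
        img <- RNifti::asNifti(arr, datatype = storage)
        RNifti::writeNifti(img, file.path(sdir, paste0(nm, ".nii.gz")))
      }
    }
    tr <- subj$lesions$truth
    if (!is.null(tr) && nrow(tr)) {
      tr$subject <- i
      truth_all[[i]] <- tr
    }
    demo_all[[i]] <- subj$demographics
  }
  truth <- do.call(rbind, truth_all)
  write.csv(truth, file.path(dir, "truth_lesions.csv"), row.names = FALSE)
  write.csv(do.call(rbind, demo_all), file.path(dir, "participants.csv"),
            row.names = FALSE)
  manifest <- list(package = "wmhperf",
                   created = format(Sys.time(), tz = "UTC"),
                   seed = spec$seed,
                   spec = spec[!vapply(spec, is.function, logical(1))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read one emitted subject session back from disk
#'
#' @param dir cohort directory written by [emit_cohort()].
#' @param subject subject number.
#' @param session `"baseline"` or `"followup"`.
#' @return list of arrays (`ventricle`, `wm`, `gm`, `csf`, `brain`, `wmh`,
#'   `lesion_labels`, `cbf`) plus `voxel_size_mm`.
#' @export
read_subject <- function(dir, subject, session = c("baseline", "followup")) {
  session <- match.arg(session)
  sdir <- file.path(dir, sprintf("sub-%03d", subject),
                    if (session == "baseline") "ses-1" else "ses-2")
  if (!dir.exists(sdir)) stop("no such subject/session directory: ", sdir,
                              call. = FALSE)
  nm <- c("ventricle", "wm", "gm", "csf", "brain", "wmh", "lesion_labels",
          "cbf")
  out <- lapply(nm, function(n) {
    img <- RNifti::readNifti(file.path(sdir, paste0(n, ".nii.gz")))
    a <- array(as.vector(img), dim = dim(img))
    if (n %in% c("lesion_labels")) a <- array(as.integer(a), dim = dim(a))
    a
  })
  names(out) <- nm
  out$voxel_size_mm <- as.numeric(RNifti::pixdim(
    RNifti::readNifti(file.path(sdir, "wm.nii.gz"))))[1:3]
  out
}
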