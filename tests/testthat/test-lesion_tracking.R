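test_that("cluster labeling respects the 10 mm3 floor and connectivity", {
  vs <- c(1, 1, 2)   # voxel volume 2 mm3
  m <- array(FALSE, c(12, 12, 6))
  expect_equal(nrow(label_clusters(m, vs)), 0)
  m[2:5, 2, 2] <- TRUE            # 4 voxels = 8 mm3 -> dropped
  m[8:12, 8, 4] <- TRUE           # 5 voxels = 10 mm3 -> kept (floor inclusive)
  cl <- label_clusters(m, vs)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$volume_mm3, 10)
})

test_that("diagonal contact merges at 26- but not 6-connectivity, per flood-fill oracle", {
  m <- array(FALSE, c(10, 10, 6))
  m[2:4, 2:4, 2:3] <- TRUE
  m[5:7, 5:7, 4:5] <- TRUE        # touches only at the corner voxel diagonal
  for (conn in c(6L, 26L)) {
    cl <- label_clusters(m, c(1, 1, 1), connectivity = conn,
                         min_volume_mm3 = 0)
    oracle <- flood_fill_labels(m, conn)
    expect_equal(nrow(cl), max(oracle))
    # identical partition of voxels, up to label order
    lm <- attr(cl, "label_map")
    expect_equal(length(unique(paste(lm[m], oracle[m]))), max(oracle))
  }
})

test_that("band assignment records both rules and flags disagreement", {
  dims <- c(30, 5, 5)
  vent <- array(FALSE, dims); vent[1, , ] <- TRUE
  d <- ventricular_distance(vent, c(1, 1, 1))
  # compact lesion entirely within JV
  les1 <- array(FALSE, dims); les1[2:3, 2:3, 2:3] <- TRUE
  a1 <- assign_band(les1, d)
  expect_equal(a1$band, "JV")
  expect_false(a1$rules_disagree)
  expect_equal(a1$band_centroid, a1$band_majority)
  # dumbbell lesion: mass at the JV and D ends, centroid in PV
  les2 <- array(FALSE, dims)
  les2[c(2, 3, 16, 17), 3, 3] <- TRUE     # distances 1, 2, 15, 16 mm
  a2 <- assign_band(les2, d)
  vox_d <- d[les2]
  counts <- table(cut(vox_d, c(-1, 3, 10, Inf), labels = c("JV", "PV", "D")))
  maj <- names(counts)[which.max(counts)]  # brute-force voxel count
  expect_equal(a2$band_majority, maj)
  expect_equal(a2$band_centroid, "PV")
  expect_true(a2$rules_disagree)
  expect_equal(a2$band, a2$band_centroid)
  expect_equal(assign_band(les2, d, rule = "majority")$band, maj)
})

test_that("centroid distance 2 mm from the ventricular surface is juxtaventricular", {
  dims <- c(20, 9, 9)
  vent <- array(FALSE, dims); vent[1:2, , ] <- TRUE
  d <- ventricular_distance(vent, c(1, 1, 1))
  les <- array(FALSE, dims); les[4, 4:6, 4:6] <- TRUE   # 2 mm from x = 2
  expect_equal(assign_band(les, d)$centroid_distance_mm, 2)
  expect_equal(assign_band(les, d)$band, "JV")
})

test_that("identical sessions match one-to-one with zero change", {
  m <- array(FALSE, c(14, 14, 8))
  m[3:5, 3:5, 3:4] <- TRUE
  m[9:11, 9:11, 5:6] <- TRUE
  cl <- label_clusters(m, c(1, 1, 2))
  tr <- match_clusters(cl, cl)
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$category == "stagnant"))
  expect_true(all(tr$volume_change_fraction == 0))
  expect_equal(tr$baseline_id, tr$followup_id)
})

test_that("unmatched clusters become new and vanished", {
  bl <- array(FALSE, c(14, 14, 8)); bl[3:5, 3:5, 3:4] <- TRUE
  fu <- array(FALSE, c(14, 14, 8)); fu[9:11, 9:11, 5:6] <- TRUE
  tr <- match_clusters(label_clusters(bl, c(1, 1, 2)),
                       label_clusters(fu, c(1, 1, 2)))
  expect_setequal(tr$category, c("new", "vanished"))
  newrow <- tr[tr$category == "new", ]
  expect_true(is.na(newrow$baseline_id))
})

test_that("merges resolve to the larger-overlap parent, per exhaustive overlap table", {
  bl <- array(FALSE, c(20, 10, 6))
  bl[2:5, 2:5, 2:3] <- TRUE       # baseline lesion 1: 32 voxels
  bl[8:9, 2:3, 2:3] <- TRUE       # baseline lesion 2: 8 voxels
  fu <- array(FALSE, c(20, 10, 6))
  fu[2:9, 2:5, 2:3] <- TRUE       # follow-up spans both
  clb <- label_clusters(bl, c(1, 1, 2))
  clf <- label_clusters(fu, c(1, 1, 2))
  # exhaustive pairwise overlap counts
  ov <- sapply(seq_len(nrow(clb)), function(i)
    sum(attr(clb, "label_map") == i & attr(clf, "label_map") == 1))
  tr <- match_clusters(clb, clf)
  matched <- tr[!is.na(tr$followup_id), ]
  expect_equal(matched$baseline_id, which.max(ov))
  expect_true(matched$merge_flag)
  # the losing baseline cluster is reported as vanished
  expect_true("vanished" %in% tr$category)
})

test_that("growth categorization follows the strict 10% rule table", {
  expect_equal(categorize(50, 56), "growing")    # +12%
  expect_equal(categorize(50, 54), "stagnant")   # +8%
  expect_equal(categorize(50, 50), "stagnant")
  expect_equal(categorize(50, 55), "stagnant")   # exactly +10%: strict ">"
  expect_equal(categorize(50, 55 + 1e-9), "growing")
  expect_equal(categorize(50, 45), "shrinking")  # exactly -10%
  expect_equal(categorize(50, 44), "shrinking")
})

test_that("lesion-specific shells exclude every lesion and match brute force", {
  dims <- c(20, 20, 10); vs <- c(1, 1, 2)
  wm <- array(TRUE, dims)
  l1 <- array(FALSE, dims); l1[5:6, 5:6, 5] <- TRUE
  l2 <- array(FALSE, dims); l2[9:10, 5:6, 5] <- TRUE   # 3 mm away
  all_wmh <- l1 | l2
  r1 <- lesion_rois(l1, all_wmh, wm, vs)
  expect_false(any(r1$P4 & l2))
  expect_false(any(r1$P8 & all_wmh))
  d_bf <- brute_force_edt(l1, vs)
  expect_equal(which(r1$P4), which(d_bf > 0 & d_bf <= 4 & !all_wmh))
  expect_equal(which(r1$P8), which(d_bf > 0 & d_bf <= 8 & !all_wmh))
})

test_that("back-projection samples baseline tissue under the new footprint", {
  dims <- c(10, 10, 5)
  brain <- array(TRUE, dims)
  rcbf <- array(0.9, dims)
  fp <- array(FALSE, dims); fp[4:6, 4:6, 3] <- TRUE
  bp <- backproject_new(fp, rcbf, brain)
  expect_equal(bp$mean_rcbf, 0.9)
  expect_equal(bp$n_voxels, 9)
  expect_equal(bp$n_excluded, 0)
  # footprint fully outside the brain -> missing value, not a crash
  brain2 <- brain; brain2[4:6, 4:6, 3] <- FALSE
  bp2 <- backproject_new(fp, rcbf, brain2)
  expect_true(is.na(bp2$mean_rcbf))
  expect_equal(bp2$n_excluded, 9)
})

test_that("tracking on a synthetic subject recovers every planted category", {
  spec <- small_spec(seed = 41, voxel_noise_cv = 0.03)
  s <- simulate_subject(spec, 1)
  an <- s$anatomy
  lt <- track_lesions(s$lesions$labels_bl > 0, s$lesions$labels_fu > 0,
                      an$wm, an$vent_dist,
                      relative_cbf(s$cbf$baseline, an$brain),
                      relative_cbf(s$cbf$followup, an$brain),
                      an$brain, an$voxel_size_mm)
  traj <- attr(lt, "trajectories")
  # every follow-up cluster in exactly one trajectory
  expect_equal(sort(traj$followup_id[!is.na(traj$followup_id)]),
               seq_len(max(traj$followup_id, na.rm = TRUE)))
  expect_false(any(duplicated(traj$baseline_id[!is.na(traj$baseline_id)])))
  # recovered categories match the planted truth (all ratios are planted
  # well clear of the 10% boundary)
  rec <- lt[lt$tissue == "WMH" & lt$session == "followup", ]
  lv <- c("stagnant", "growing", "new")
  expect_equal(as.vector(table(factor(rec$category, levels = lv))),
               as.vector(table(factor(s$lesions$truth$category,
                                      levels = lv))))
  # stored categories are reproducible from stored volumes
  m <- traj[!is.na(traj$baseline_id) & !is.na(traj$followup_id), ]
  recat <- mapply(categorize, m$volume_bl_mm3, m$volume_fu_mm3)
  expect_equal(unname(recat), m$category)
})
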