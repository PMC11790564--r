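test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(category_fractions = c(stagnant = 0.6,
                                                  growing = 0.3,
                                                  new = 0.2, shrinking = 0)),
               "sum to 1")
  expect_error(cohort_spec(voxel_noise_cv = -0.1), ">= 0")
  expect_error(cohort_spec(voxel_size_mm = c(1, 0, 2)), "positive")
  bad <- tissue_factor_defaults(); bad$gm <- -1
  expect_error(cohort_spec(tissue_rcbf_factors = bad), "positive")
})

test_that("subjects are bit-identical under seed replay", {
  spec <- small_spec(seed = 7)
  a <- simulate_subject(spec, 1)
  b <- simulate_subject(spec, 1)
  expect_identical(a$anatomy$wm, b$anatomy$wm)
  expect_identical(a$lesions$labels_fu, b$lesions$labels_fu)
  expect_identical(a$cbf$baseline, b$cbf$baseline)
  expect_identical(a$demographics, b$demographics)
})

test_that("anatomy labels are disjoint, tile the brain, and ventricle is connected", {
  an <- generate_anatomy(small_spec(), 1)
  overlap <- an$ventricle + an$wm + an$gm + an$csf
  expect_true(all(overlap[an$brain] == 1))   # exact tiling, no overlap
  expect_true(all(overlap[!an$brain] == 0))
  cl <- label_clusters(an$ventricle, an$voxel_size_mm, min_volume_mm3 = 0)
  expect_equal(nrow(cl), 1)
})

test_that("default grid leaves deep-band WM, verified by brute-force distance scan", {
  spec <- cohort_spec(n_subjects = 1, n_longitudinal = 0, seed = 5)
  an <- generate_anatomy(spec, 1)
  idx <- which(an$wm)
  set.seed(1)
  sel <- sample(idx, 400)
  src_mm <- sweep(which(an$ventricle, arr.ind = TRUE), 2,
                  an$voxel_size_mm, `*`)
  pt_mm <- sweep(arrayInd(sel, dim(an$wm)), 2, an$voxel_size_mm, `*`)
  d_bf <- apply(pt_mm, 1, function(p) sqrt(min(colSums((t(src_mm) - p)^2))))
  expect_true(any(d_bf > 10))
  expect_equal(an$vent_dist[sel], d_bf, tolerance = 1e-6)
})

test_that("a grid too small for the deep band reports the limiting dimension", {
  spec <- small_spec()
  spec$ventricle_semi_mm <- c(6, 22, 5)   # leaves <12 mm of WM along y
  expect_error(generate_anatomy(spec, 1), "along y")
})

test_that("planted trajectories honor their categories and ratios", {
  spec <- small_spec(seed = 21)
  an <- generate_anatomy(spec, 1)
  les <- plant_lesions(an, spec, 1, longitudinal = TRUE)
  tr <- les$truth
  voxvol <- prod(an$voxel_size_mm)
  expect_true(all(tr$volume_fu_mm3 >= 10))
  for (k in seq_len(nrow(tr))) {
    bl <- which(les$labels_bl == tr$lesion_id[k])
    fu <- which(les$labels_fu == tr$lesion_id[k])
    if (tr$category[k] == "stagnant") {
      expect_identical(bl, fu)
    } else if (tr$category[k] == "new") {
      expect_length(bl, 0)
      expect_gt(length(fu), 0)
    } else if (tr$category[k] == "growing") {
      achieved <- length(fu) / length(bl)
      expect_lt(abs(achieved - tr$planted_ratio[k]) / tr$planted_ratio[k],
                0.02)
      expect_gt(achieved, 1.10)
      expect_true(all(bl %in% fu))   # geodesic dilation grows outward
    }
    expect_true(all(fu %in% which(an$wm)))  # lesions live in WM only
  }
})

test_that("empirical category fractions sit inside binomial 99% bounds", {
  spec <- small_spec(seed = 33)
  cats <- character(0)
  i <- 0
  while (length(cats) < 150) {
    i <- i + 1
    an <- generate_anatomy(spec, i)
    les <- plant_lesions(an, spec, i, longitudinal = TRUE)
    cats <- c(cats, les$truth$category)
  }
  n <- length(cats)
  for (cc in c("stagnant", "growing", "new")) {
    p <- spec$category_fractions[[cc]]
    k <- sum(cats == cc)
    expect_gte(k, qbinom(0.005, n, p))
    expect_lte(k, qbinom(0.995, n, p))
  }
})

test_that("noise-free painting calibrates the brain mean exactly", {
  spec <- small_spec(voxel_noise_cv = 0, seed = 9)
  s <- simulate_subject(spec, 2)
  cbf <- s$cbf$baseline
  expect_equal(mean(cbf[s$anatomy$brain]) / spec$nominal_brain_cbf, 1,
               tolerance = 1e-9)
  # GM factor is recovered as a ratio to the brain mean
  expect_equal(mean(cbf[s$anatomy$gm]) / mean(cbf[s$anatomy$brain]),
               spec$tissue_rcbf_factors$gm, tolerance = 1e-9)
})

test_that("CSF calibration equals the hand-solved weighted-mean equation", {
  spec <- small_spec(voxel_noise_cv = 0, seed = 9)
  an <- generate_anatomy(spec, 1)
  les <- plant_lesions(an, spec, 1, longitudinal = FALSE)
  cbf <- paint_cbf(an, les, spec, 1, "baseline")
  fm <- attr(cbf, "factor_map")
  csf_all <- an$csf | an$ventricle
  # solve n_csf * x + sum(tissue factors) = n_brain * 1 by hand
  x <- (sum(an$brain) - sum(fm[an$brain & !csf_all])) / sum(csf_all)
  expect_equal(attr(cbf, "csf_value"), x, tolerance = 1e-12)
  expect_gt(x, 0)
  # cumulative 8-mm penumbra mean honors the p8_cum factor
  sh <- penumbra_shells(les$labels_bl > 0, an$wm, an$voxel_size_mm)
  expect_equal(mean(fm[sh$P8]), spec$tissue_rcbf_factors$p8_cum,
               tolerance = 1e-9)
  expect_equal(mean(fm[sh$P4]), spec$tissue_rcbf_factors$p4,
               tolerance = 1e-9)
})

test_that("factors incompatible with a unit brain mean are refused", {
  f <- tissue_factor_defaults()
  f$gm <- 3; f$nawm <- 3   # tissue average cannot reach 1 with positive CSF
  spec <- small_spec(tissue_rcbf_factors = f)
  an <- generate_anatomy(spec, 1)
  les <- plant_lesions(an, spec, 1)
  expect_error(paint_cbf(an, les, spec, 1, "baseline"), "negative")
})

test_that("emitted cohorts have the right session counts and replay identically", {
  spec <- small_spec(seed = 12)
  spec$n_subjects <- 3
  spec$n_longitudinal <- 2
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  emit_cohort(spec, d1)
  emit_cohort(spec, d2)
  ses1 <- length(list.files(d1, pattern = "^ses-1$", recursive = TRUE,
                            include.dirs = TRUE))
  ses2 <- length(list.files(d1, pattern = "^ses-2$", recursive = TRUE,
                            include.dirs = TRUE))
  expect_equal(ses1, 3)
  expect_equal(ses2, 2)
  t1 <- read.csv(file.path(d1, "truth_lesions.csv"))
  t2 <- read.csv(file.path(d2, "truth_lesions.csv"))
  expect_identical(t1, t2)
  # NIfTI round trip preserves masks, voxel sizes, and CBF values
  s <- simulate_subject(spec, 1)
  r <- read_subject(d1, 1, "baseline")
  expect_equal(r$voxel_size_mm, s$anatomy$voxel_size_mm)
  expect_identical(r$wm != 0, s$anatomy$wm)
  expect_identical(r$lesion_labels, s$lesions$labels_bl)
  expect_equal(r$cbf, as.vector(s$cbf$baseline) |> array(dim(r$cbf)),
               tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("demographic draws center on the cohort defaults", {
  spec <- small_spec(seed = 2)
  spec$n_subjects <- 12
  spec$n_longitudinal <- 0
  ages <- vapply(1:12, function(i) simulate_subject(spec, i)$demographics$age,
                 numeric(1))
  se <- spec$age_sd / sqrt(length(ages))
  expect_lt(abs(mean(ages) - spec$age_mean), 3 * se)
})
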