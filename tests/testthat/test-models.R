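test_that("balanced zero-noise designs are recovered exactly and equal OLS", {
  eff_t <- c(NAWM = 0, WMH = -0.4, P4 = -0.25, P8 = -0.18)
  eff_l <- c(JV = 0, PV = 0.012, D = 0.123)
  tbl <- simulate_tissue_location_table(n_subjects = 20,
                                        tissue_effects = eff_t,
                                        location_effects = eff_l,
                                        subject_sd = 0, resid_sd = 0,
                                        seed = 1)
  # a zero-variance design is deliberately degenerate for lmer; the
  # convergence warnings are expected and the estimates remain exact
  fit <- suppressWarnings(suppressMessages(fit_tissue_location_model(tbl)))
  expect_equal(fit$estimate[fit$term == "locationD"], 0.123,
               tolerance = 1e-6)
  expect_equal(fit$estimate[fit$term == "tissueWMH"], -0.4,
               tolerance = 1e-6)
  # OLS closed form on the same design gives identical fixed effects
  tbl$tissue <- stats::relevel(factor(tbl$tissue), "NAWM")
  tbl$location <- stats::relevel(factor(tbl$location), "JV")
  ols <- coef(lm(log_rcbf ~ tissue + location, data = tbl))
  expect_equal(fit$estimate[fit$term == "locationD"],
               unname(ols["locationD"]), tolerance = 1e-8)
})

test_that("volume-by-location model recovers planted slopes and interactions", {
  tbl <- simulate_volume_location_table(n_subjects = 200, seed = 4)
  fit <- fit_volume_location_model(tbl)
  est_jv <- fit$estimate[fit$term == "log_rvol_centered:locationJV"]
  est_pv <- fit$estimate[fit$term == "log_rvol_centered:locationPV"]
  expect_lt(abs(est_jv - (-0.2369)), 0.03)
  expect_lt(abs(est_pv - (-0.1897)), 0.03)
  sl <- attr(fit, "slopes")
  expect_equal(unname(sl["JV"] - sl["D"]), est_jv, tolerance = 1e-10)
  # single-location table degenerates to a simple slope = closed-form LS
  one <- tbl[tbl$location == "D", ]
  f1 <- suppressMessages(fit_volume_location_model(one))
  expect_equal(names(attr(f1, "slopes")), "D")
  ls <- coef(lm(log_rcbf ~ log_rvol_centered, data = one))
  expect_lt(abs(attr(f1, "slopes")[["D"]] -
                  unname(ls["log_rvol_centered"])), 0.01)
})

test_that("null location effects keep the Wald type-I error near 5%", {
  n_rep <- 150
  rejections <- 0
  for (r in seq_len(n_rep)) {
    tbl <- simulate_volume_location_table(
      n_subjects = 25,
      slopes = c(D = -0.1, JV = -0.1, PV = -0.1),
      intercepts = c(D = 0, JV = 0, PV = 0),
      subject_sd = 0.1, resid_sd = 0.1, seed = 1000 + r)
    fit <- suppressMessages(fit_volume_location_model(tbl))
    p <- fit$p[fit$term == "log_rvol_centered:locationJV"]
    if (is.finite(p) && p < 0.05) rejections <- rejections + 1
  }
  # binomial 99.5% bounds around 5% of 150
  expect_gte(rejections, qbinom(0.0025, n_rep, 0.05))
  expect_lte(rejections, qbinom(0.9975, n_rep, 0.05))
})

test_that("lesion longitudinal model recovers the baseline category contrast", {
  tbl <- simulate_lesion_longitudinal_table(n_subjects = 60, seed = 2)
  fit <- fit_lesion_longitudinal_model(tbl, "JV", "WMH")
  est <- fit$estimate[fit$term == "categorygrowing"]
  expect_lt(abs(est - (-0.127)), 0.05)
  expect_equal(attr(fit, "non_estimable"), character(0))
  # intercept is the stagnant baseline mean
  expect_lt(abs(fit$estimate[fit$term == "(Intercept)"] - (-0.295)), 0.05)
  # CI columns follow the Wald construction
  expect_equal(fit$ci_lo, fit$estimate - 1.96 * fit$se)
})

test_that("planted-effect CIs cover the truth in most seeded replicates", {
  n_rep <- 60
  cover <- 0
  for (r in seq_len(n_rep)) {
    tbl <- simulate_lesion_longitudinal_table(n_subjects = 30,
                                              seed = 5000 + r)
    fit <- suppressMessages(fit_lesion_longitudinal_model(tbl, "JV", "WMH"))
    lo <- fit$ci_lo[fit$term == "categorygrowing"]
    hi <- fit$ci_hi[fit$term == "categorygrowing"]
    if (lo <= -0.127 && -0.127 <= hi) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.85)
})

test_that("categories with too few lesions are reported non-estimable", {
  tbl <- simulate_lesion_longitudinal_table(
    n_subjects = 20, category_fractions = c(stagnant = 0.7, growing = 0.3,
                                            new = 0),
    seed = 3)
  fit <- suppressMessages(fit_lesion_longitudinal_model(tbl, "JV", "WMH"))
  expect_true("new" %in% attr(fit, "non_estimable"))
  expect_false("categorynew" %in% fit$term)
})

test_that("multiplicity corrections match hand computations", {
  expect_equal(correct_pvalues(0.03), 0.03)   # single p unchanged under BH
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  p9 <- c(0.002, rep(0.5, 8))
  expect_equal(correct_pvalues(p9, "bonferroni")[1], 0.018)
  expect_true(all(correct_pvalues(p9, "holm") >= p9))
  expect_error(correct_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(correct_pvalues(c(0.1, -0.2)), "\\[0, 1\\]")
})

test_that("centroid-distance model finds a planted perfusion gradient", {
  # noiseless linear data: exact slope recovery
  tbl <- tibble::tibble(subject = rep(1:20, each = 5),
                        lesion_uid = sprintf("l%03d", 1:100),
                        centroid_distance_mm = runif(100, 0, 20))
  tbl$log_rcbf <- -0.5 + 0.01 * tbl$centroid_distance_mm
  fit <- suppressMessages(centroid_distance_model(tbl))
  expect_equal(fit$estimate[fit$term == "centroid_distance_mm"], 0.01,
               tolerance = 1e-6)
  # with noise at n = 300 lesions, the slope is positive and significant
  set.seed(8)
  tbl2 <- tibble::tibble(subject = rep(1:60, each = 5),
                         lesion_uid = sprintf("m%03d", 1:300),
                         centroid_distance_mm = runif(300, 0, 20))
  u <- rnorm(60, 0, 0.05)
  tbl2$log_rcbf <- -0.5 + 0.015 * tbl2$centroid_distance_mm +
    u[tbl2$subject] + rnorm(300, 0, 0.1)
  fit2 <- centroid_distance_model(tbl2)
  expect_gt(fit2$estimate[fit2$term == "centroid_distance_mm"], 0)
  expect_lt(fit2$p[fit2$term == "centroid_distance_mm"], 0.05)
})

test_that("volume ANOVA behaves at its algebraic edges", {
  # two groups: F equals the squared two-sample (equal-variance) t
  set.seed(9)
  tbl <- tibble::tibble(location = rep(c("JV", "PV"), each = 30),
                        log_volume = rnorm(60))
  a <- anova_volume_by_location(tbl)
  tt <- t.test(log_volume ~ location, data = tbl, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # zero within-group variance with different means: p effectively 0
  tbl2 <- tibble::tibble(location = rep(c("JV", "PV", "D"), each = 10),
                         log_volume = rep(c(1, 2, 3), each = 10))
  a2 <- anova_volume_by_location(tbl2)
  expect_lt(a2$p, 1e-10)
  expect_error(anova_volume_by_location(
    tibble::tibble(location = "JV", log_volume = 1)), "2 locations")
})
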