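#' @importFrom lmerTest lmer
NULL

# tidy a lmerTest fit into the package's coefficient-table shape:
# estimate, SE, t, Wald 95% CI, raw p (Satterthwaite df)
tidy_lmm <- function(fit, model_id) {
  sm <- summary(fit)$coefficients
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  out <- tibble::tibble(
    model = model_id,
    term = rownames(sm),
    estimate = est,
    se = se,
    df = if ("df" %in% colnames(sm)) unname(sm[, "df"]) else NA_real_,
    t = unname(sm[, "t value"]),
    ci_lo = est - 1.96 * se,
    ci_hi = est + 1.96 * se,
    p = if ("Pr(>|t|)" %in% colnames(sm)) unname(sm[, "Pr(>|t|)"])
        else NA_real_)
  attr(out, "n_obs") <- nrow(fit@frame)
  attr(out, "n_groups") <- lme4::ngrps(fit)
  attr(out, "singular") <- lme4::isSingular(fit)
  attr(out, "fit") <- fit
  if (lme4::isSingular(fit))
    attr(out, "diagnostics") <- "singular random-effect fit"
  out
}

#' Mixed model of log rCBF on tissue type and brain location
#'
#' Fits `log_rcbf ~ tissue + location + (1 | subject)` by REML, with
#' configurable reference levels (defaults: tissue NAWM, location JV, so
#' the deep-location coefficient is the deep-vs-JV contrast).
#'
#' @param tbl table with columns `subject`, `tissue`, `location`,
#'   `log_rcbf` (one row per subject-tissue-location cell).
#' @param ref_tissue,ref_location reference factor levels.
#' @return coefficient tibble (estimate, SE, t, 95% Wald CI, p), fitted
#'   model in attribute `fit`; singular fits are flagged in attribute
#'   `diagnostics`.
#' @export
fit_tissue_location_model <- function(tbl, ref_tissue = "NAWM",
                                      ref_location = "JV") {
  tbl <- tbl[is.finite(tbl$log_rcbf), ]
  tbl$tissue <- stats::relevel(factor(tbl$tissue), ref = ref_tissue)
  tbl$location <- stats::relevel(factor(tbl$location), ref = ref_location)
  fit <- lmerTest::lmer(log_rcbf ~ tissue + location + (1 | subject),
                        data = tbl, REML = TRUE)
  tidy_lmm(fit, "tissue_location")
}

#' Mixed model of log rCBF on lesion volume by location
#'
#' Fits `log_rcbf ~ log_rvol_centered * location + (1 | subject)` with the
#' deep region as reference, so the `JV:` and `PV:` interaction terms are
#' the location-specific slope differences relative to deep. Per-location
#' slopes are the base slope plus the matching interaction. A table with a
#' single location degenerates to a simple-slope model. Locations
#' represented by fewer than 3 subjects are dropped with a warning.
#'
#' @param tbl table with `subject`, `location`, `log_rcbf`,
#'   `log_rvol_centered`.
#' @param ref_location reference location (default `"D"`).
#' @return coefficient tibble; per-location slopes in attribute `slopes`.
#' @export
fit_volume_location_model <- function(tbl, ref_location = "D") {
  tbl <- tbl[is.finite(tbl$log_rcbf) & is.finite(tbl$log_rvol_centered), ]
  counts <- tapply(tbl$subject, tbl$location,
                   function(s) length(unique(s)))
  thin <- names(counts)[counts < 3]
  if (length(thin)) {
    warning("dropping locations with <3 subjects: ",
            paste(thin, collapse = ", "))
    tbl <- tbl[!tbl$location %in% thin, ]
  }
  locs <- unique(tbl$location)
  if (length(locs) == 1L) {
    # degenerate design; with one row per subject the random intercept is
    # unidentifiable and the model collapses to ordinary least squares
    out <- if (max(table(tbl$subject)) < 2L) {
      fit <- lm(log_rcbf ~ log_rvol_centered, data = tbl)
      sm <- summary(fit)$coefficients
      tibble::tibble(
        model = "volume_location", term = rownames(sm),
        estimate = unname(sm[, "Estimate"]), se = unname(sm[, "Std. Error"]),
        df = fit$df.residual, t = unname(sm[, "t value"]),
        ci_lo = unname(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
        ci_hi = unname(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]),
        p = unname(sm[, "Pr(>|t|)"]))
    } else {
      fit <- lmerTest::lmer(log_rcbf ~ log_rvol_centered + (1 | subject),
                            data = tbl, REML = TRUE)
      tidy_lmm(fit, "volume_location")
    }
    sl <- out$estimate[out$term == "log_rvol_centered"]
    attr(out, "slopes") <- setNames(sl, locs)
    return(out)
  }
  tbl$location <- stats::relevel(factor(tbl$location), ref = ref_location)
  fit <- lmerTest::lmer(
    log_rcbf ~ log_rvol_centered * location + (1 | subject),
    data = tbl, REML = TRUE)
  out <- tidy_lmm(fit, "volume_location")
  base <- out$estimate[out$term == "log_rvol_centered"]
  slopes <- setNames(rep(base, length(levels(tbl$location))),
                     levels(tbl$location))
  for (lv in levels(tbl$location)[-1]) {
    term <- paste0("log_rvol_centered:location", lv)
    slopes[lv] <- base + out$estimate[out$term == term]
  }
  attr(out, "slopes") <- slopes
  out
}

#' Lesion-specific mixed model of rCBF on longitudinal category and session
#'
#' For one location and one tissue (WMH, P4 or P8), fits
#' `log_rcbf ~ category * session + (1 | subject)` over lesion-level rows,
#' with `stagnant` and `baseline` as references. The `categorygrowing` and
#' `categorynew` coefficients are then the baseline mean differences vs.
#' stagnant lesions (Wald 95% CI), the quantities tabulated per location
#' and tissue. Shrinking and vanished lesions are excluded. A category with
#' fewer than 2 lesions is reported as non-estimable.
#'
#' @param tbl lesion-level table (see [track_lesions()]) with columns
#'   `subject`, `lesion_uid`, `session`, `tissue`, `category`, `band`,
#'   `log_rcbf` (or `mean_rcbf`, logged here).
#' @param location band to analyze (`"JV"`, `"PV"` or `"D"`).
#' @param tissue tissue to analyze (`"WMH"`, `"P4"` or `"P8"`).
#' @return coefficient tibble; non-estimable contrasts listed in attribute
#'   `non_estimable`.
#' @export
fit_lesion_longitudinal_model <- function(tbl, location, tissue) {
  if (!"log_rcbf" %in% names(tbl))
    tbl$log_rcbf <- ifelse(is.finite(tbl$mean_rcbf) & tbl$mean_rcbf > 0,
                           log(tbl$mean_rcbf), NA_real_)
  d <- tbl[tbl$band == location & tbl$tissue == tissue &
             tbl$category %in% c("stagnant", "growing", "new") &
             is.finite(tbl$log_rcbf), ]
  if (nrow(d) == 0L) stop("no usable rows for ", location, " ", tissue,
                          call. = FALSE)
  d$category <- factor(d$category, levels = c("stagnant", "growing", "new"))
  d$session <- factor(d$session, levels = c("baseline", "followup"))
  n_per_cat <- tapply(d$lesion_uid, d$category,
                      function(x) length(unique(x)))
  n_per_cat[is.na(n_per_cat)] <- 0
  non_est <- names(n_per_cat)[n_per_cat < 2]
  d <- d[!d$category %in% non_est, ]
  d$category <- droplevels(d$category)
  fit <- lmerTest::lmer(log_rcbf ~ category * session + (1 | subject),
                        data = d, REML = TRUE)
  out <- tidy_lmm(fit, paste0(location, tissue))
  attr(out, "non_estimable") <- non_est
  attr(out, "location") <- location
  attr(out, "tissue") <- tissue
  out
}

#' Table of baseline category contrasts across locations and tissues
#'
#' Runs [fit_lesion_longitudinal_model()] for every location (JV, PV, D)
#' by tissue (WMH, P4, P8) combination present in the data and assembles
#' the familiar 9-row contrast table: stagnant intercept, growing and new
#' baseline mean differences with 95% CI and raw p, plus p-values corrected
#' within each category's family of 9 contrasts.
#'
#' @param tbl lesion-level table.
#' @param method multiplicity correction passed to [correct_pvalues()].
#' @return tibble with one row per location-tissue.
#' @export
longitudinal_contrast_table <- function(tbl, method = "BH") {
  combos <- expand.grid(location = c("JV", "PV", "D"),
                        tissue = c("WMH", "P4", "P8"),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    loc <- combos$location[i]; tis <- combos$tissue[i]
    res <- tryCatch(fit_lesion_longitudinal_model(tbl, loc, tis),
                    error = function(e) NULL)
    if (is.null(res)) next
    pick <- function(term, col) {
      v <- res[[col]][res$term == term]
      if (length(v)) v else NA_real_
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      location = loc, tissue = tis,
      intercept = pick("(Intercept)", "estimate"),
      growing_diff = pick("categorygrowing", "estimate"),
      growing_lo = pick("categorygrowing", "ci_lo"),
      growing_hi = pick("categorygrowing", "ci_hi"),
      growing_p = pick("categorygrowing", "p"),
      new_diff = pick("categorynew", "estimate"),
      new_lo = pick("categorynew", "ci_lo"),
      new_hi = pick("categorynew", "ci_hi"),
      new_p = pick("categorynew", "p"))
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    est <- is.finite(out$growing_p)
    out$growing_p_corrected <- NA_real_
    out$growing_p_corrected[est] <- correct_pvalues(out$growing_p[est],
                                                    method)
    est <- is.finite(out$new_p)
    out$new_p_corrected <- NA_real_
    out$new_p_corrected[est] <- correct_pvalues(out$new_p[est], method)
  }
  out
}

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg by default; Holm and Bonferroni selectable. The
#' family is whatever vector is passed in (e.g. the 9 location-by-tissue
#' contrasts of one category).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"BH"`, `"holm"` or `"bonferroni"`.
#' @return corrected p-values, same length.
#' @export
correct_pvalues <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = method)
}

#' Mixed model of lesion rCBF on centroid ventricular distance
#'
#' Fits `log_rcbf ~ centroid_distance_mm + (1 | subject)` over lesion-level
#' rows, the continuous-covariate counterpart of the banded location
#' analysis: a positive slope means lesions farther from the ventricles are
#' better perfused.
#'
#' @param tbl lesion-level table with `centroid_distance_mm` and `log_rcbf`
#'   (or `mean_rcbf`).
#' @return coefficient tibble.
#' @export
centroid_distance_model <- function(tbl) {
  if (!"log_rcbf" %in% names(tbl))
    tbl$log_rcbf <- ifelse(is.finite(tbl$mean_rcbf) & tbl$mean_rcbf > 0,
                           log(tbl$mean_rcbf), NA_real_)
  d <- tbl[is.finite(tbl$log_rcbf) & is.finite(tbl$centroid_distance_mm), ]
  fit <- lmerTest::lmer(log_rcbf ~ centroid_distance_mm + (1 | subject),
                        data = d, REML = TRUE)
  tidy_lmm(fit, "centroid_distance")
}

#' One-way ANOVA of (log) WMH volume across brain locations
#'
#' @param tbl table with per-subject per-location WMH volumes; columns
#'   `location` and `log_volume` (or `volume_mm3`, logged here).
#' @return list with `F`, `p`, `df`, and the `aov` fit.
#' @export
anova_volume_by_location <- function(tbl) {
  if (!"log_volume" %in% names(tbl))
    tbl$log_volume <- log(tbl$volume_mm3)
  d <- tbl[is.finite(tbl$log_volume), ]
  d$location <- factor(d$location)
  if (nlevels(d$location) < 2L)
    stop("need at least 2 locations for ANOVA", call. = FALSE)
  fit <- aov(log_volume ~ location, data = d)
  sm <- summary(fit)[[1]]
  list(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       df = unname(sm[["Df"]]), fit = fit)
}
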