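# Table-level simulators: draw ROI / lesion measurement tables directly in
# log-rCBF space with known fixed effects, for parameter-recovery and
# coverage testing of the model layer without building image volumes.

#' Simulate a subject-by-tissue-by-location log-rCBF table
#'
#' Additive model in log space: subject random intercept + tissue effect +
#' location effect + residual. Defaults plant a deep-vs-JV location offset
#' with JV as the zero level.
#'
#' @param n_subjects subjects.
#' @param tissue_effects named additive effects (first entry is reference).
#' @param location_effects named additive effects.
#' @param intercept grand intercept (log rCBF of the reference cell).
#' @param subject_sd random-intercept SD.
#' @param resid_sd residual SD.
#' @param seed RNG seed.
#' @return tibble with `subject`, `tissue`, `location`, `log_rcbf`.
#' @export
simulate_tissue_location_table <- function(
    n_subjects = 300,
    tissue_effects = c(NAWM = 0, WMH = -0.4, P4 = -0.25, P8 = -0.18),
    location_effects = c(JV = 0, PV = 0.012, D = 0.123),
    intercept = -0.1,
    subject_sd = 0.1, resid_sd = 0.08, seed = 1L) {
  with_local_seed(seed, {
    g <- expand.grid(subject = seq_len(n_subjects),
                     tissue = names(tissue_effects),
                     location = names(location_effects),
                     stringsAsFactors = FALSE)
    u <- rnorm(n_subjects, 0, subject_sd)
    g$log_rcbf <- intercept + tissue_effects[g$tissue] +
      location_effects[g$location] + u[g$subject] +
      rnorm(nrow(g), 0, resid_sd)
    tibble::as_tibble(g)
  })
}

#' Simulate a volume-by-location log-rCBF table
#'
#' Each subject contributes one row per location with a centered log rVol
#' covariate drawn N(0, 1) and location-specific slope; defaults plant the
#' JV-deep and PV-deep slope differences used in the recovery experiments.
#'
#' @param n_subjects subjects.
#' @param slopes named per-location slopes of log rCBF on centered log rVol.
#' @param intercepts named per-location intercepts.
#' @param subject_sd,resid_sd random-intercept and residual SDs.
#' @param seed RNG seed.
#' @return tibble with `subject`, `location`, `log_rvol_centered`,
#'   `log_rcbf`.
#' @export
simulate_volume_location_table <- function(
    n_subjects = 300,
    slopes = c(D = -0.05, JV = -0.05 - 0.2369, PV = -0.05 - 0.1897),
    intercepts = c(D = -0.11, JV = -0.23, PV = -0.22),
    subject_sd = 0.1, resid_sd = 0.1, seed = 1L) {
  with_local_seed(seed, {
    g <- expand.grid(subject = seq_len(n_subjects),
                     location = names(slopes),
                     stringsAsFactors = FALSE)
    u <- rnorm(n_subjects, 0, subject_sd)
    g$log_rvol_centered <- rnorm(nrow(g))
    g$log_rcbf <- intercepts[g$location] +
      slopes[g$location] * g$log_rvol_centered + u[g$subject] +
      rnorm(nrow(g), 0, resid_sd)
    tibble::as_tibble(g)
  })
}

#' Simulate a lesion-level longitudinal log-rCBF table
#'
#' Each subject contributes `lesions_per_subject` lesions of one band and
#' tissue, observed at baseline and follow-up. Baseline log rCBF is the
#' stagnant intercept plus a category contrast (growing or new deficit);
#' session and category-by-session effects act at follow-up. New lesions'
#' baseline rows represent back-projected pre-lesional tissue.
#'
#' @param n_subjects subjects.
#' @param lesions_per_subject lesions per subject.
#' @param category_fractions sampling fractions over stagnant/growing/new.
#' @param intercept stagnant baseline mean (log rCBF).
#' @param growing_diff,new_diff baseline contrasts vs stagnant.
#' @param session_effect follow-up minus baseline for stagnant lesions.
#' @param interaction_growing,interaction_new category-by-session effects.
#' @param band,tissue labels copied into the table.
#' @param subject_sd,resid_sd random-intercept and residual SDs.
#' @param seed RNG seed.
#' @return tibble shaped like [track_lesions()] output plus `log_rcbf`.
#' @export
simulate_lesion_longitudinal_table <- function(
    n_subjects = 60, lesions_per_subject = 5,
    category_fractions = c(stagnant = 0.5, growing = 0.3, new = 0.2),
    intercept = -0.295, growing_diff = -0.127, new_diff = -0.105,
    session_effect = -0.02, interaction_growing = -0.05,
    interaction_new = 0.05,
    band = "JV", tissue = "WMH",
    subject_sd = 0.08, resid_sd = 0.12, seed = 1L) {
  with_local_seed(seed, {
    rows <- list()
    uid <- 0L
    u <- rnorm(n_subjects, 0, subject_sd)
    for (s in seq_len(n_subjects)) {
      n_les <- lesions_per_subject
      cats <- sample(names(category_fractions), n_les, replace = TRUE,
                     prob = category_fractions)
      for (k in seq_len(n_les)) {
        uid <- uid + 1L
        cat_diff <- switch(cats[k], stagnant = 0, growing = growing_diff,
                           new = new_diff)
        inter <- switch(cats[k], stagnant = 0,
                        growing = interaction_growing,
                        new = interaction_new)
        mu_bl <- intercept + cat_diff + u[s]
        mu_fu <- mu_bl + session_effect + inter
        for (ses in c("baseline", "followup")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject = s,
            lesion_uid = sprintf("sim%05d", uid),
            session = ses, tissue = tissue, category = cats[k],
            band = band,
            centroid_distance_mm = NA_real_, volume_mm3 = NA_real_,
            log_rcbf = (if (ses == "baseline") mu_bl else mu_fu) +
              rnorm(1, 0, resid_sd))
        }
      }
    }
    do.call(rbind, rows)
  })
}
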