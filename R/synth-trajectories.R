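# Longitudinal outcome generation: regional composite volumes (ICV-
# normalized), cognitive scores, and the brain-age gap itself, following
# linear or quadratic group trajectories with per-subject random intercepts
# and slopes.

#' Define a longitudinal outcome for the synthetic generator
#'
#' An outcome follows, for a subject in group g at time t years after
#' baseline:
#' `value = baseline + baseline_beta[g] + (slope + slope_beta[g]) * t +
#'  quad_beta[g] * t^2 + b0_subject + b1_subject * t + residual`,
#' with `b0 ~ N(0, ri_sd^2)`, `b1 ~ N(0, rs_sd^2)`, residual
#' `~ N(0, resid_sd^2)`.
#'
#' @param name Outcome name.
#' @param baseline Reference baseline level (the `AD-LB-` level; CU shares it
#'   unless a CU beta is given).
#' @param baseline_beta Named per-group additive baseline offsets.
#' @param slope Reference yearly slope.
#' @param slope_beta Named per-group additive slope offsets.
#' @param quad_beta Named per-group quadratic (per year squared) terms.
#' @param ri_sd,rs_sd Random-intercept and random-slope SDs.
#' @param resid_sd Residual SD.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(name, baseline, baseline_beta = NULL, slope = 0,
                         slope_beta = NULL, quad_beta = NULL,
                         ri_sd = 0, rs_sd = 0, resid_sd = 0) {
  zero <- stats::setNames(rep(0, 5), pathology_groups())
  fill <- function(x) { z <- zero; if (!is.null(x)) z[names(x)] <- x; z }
  structure(list(name = name, baseline = baseline,
                 baseline_beta = fill(baseline_beta), slope = slope,
                 slope_beta = fill(slope_beta), quad_beta = fill(quad_beta),
                 ri_sd = ri_sd, rs_sd = rs_sd, resid_sd = resid_sd),
            class = "outcome_spec")
}

#' Default longitudinal outcome specifications
#'
#' Generator defaults echoing the reported fitted effects: brain-age gap
#' (baseline offsets at the subgroup means, slopes 0.03/0.14/0.29/0.54
#' yr/yr), ICV-normalized composite volumes for the medial temporal lobe,
#' basal ganglia, occipital lobe, and middle temporal cortex (baseline and
#' slope contrasts at the reported betas where reported, small or zero where
#' not significant), and two global cognitive scores (CDRSB and ADAS-Cog-11)
#' with quadratic group terms. Volume baselines correspond to the published
#' subgroup volumetrics divided by a nominal 1,500 cm3 intracranial volume.
#'
#' @param params A [generator_params()] (supplies the brain-age offsets and
#'   slopes).
#' @return Named list of [outcome_spec()] objects.
#' @export
default_outcome_specs <- function(params = generator_params()) {
  g <- pathology_groups()
  bag <- outcome_spec(
    "bag", baseline = 0,
    baseline_beta = params$group_offset,
    slope = 0, slope_beta = params$group_slope,
    ri_sd = 2.0, rs_sd = 0.15, resid_sd = 1.5)
  mtl <- outcome_spec(
    "mtl", baseline = 11.681 / 1500,
    baseline_beta = c("AD-LB+" = -1e-4, "AD+LB-" = -5.01e-4,
                      "AD+LB+" = -8.52e-4),
    slope = -3e-5,
    slope_beta = c("AD-LB+" = -4e-5, "AD+LB-" = -1.45e-4,
                   "AD+LB+" = -2.14e-4),
    ri_sd = 6e-4, rs_sd = 3e-5, resid_sd = 1.5e-4)
  bg <- outcome_spec(
    "basal_ganglia", baseline = 12.647 / 1500,
    baseline_beta = NULL,
    slope = -2e-5,
    slope_beta = c("AD-LB+" = -2e-5, "AD+LB-" = -7.3e-5,
                   "AD+LB+" = -1.21e-4),
    ri_sd = 7e-4, rs_sd = 2e-5, resid_sd = 1.5e-4)
  occ <- outcome_spec(
    "occipital", baseline = 28.397 / 1500,
    baseline_beta = NULL,
    slope = -3e-5,
    slope_beta = c("AD-LB+" = -5e-5, "AD+LB-" = -2.09e-4,
                   "AD+LB+" = -3.27e-4),
    ri_sd = 1.5e-3, rs_sd = 4e-5, resid_sd = 3e-4)
  mt <- outcome_spec(
    "middle_temporal", baseline = 13.421 / 1500,
    baseline_beta = c("AD-LB+" = -1e-4, "AD+LB-" = -5.00e-4,
                      "AD+LB+" = -6.60e-4),
    slope = -3e-5,
    slope_beta = c("AD-LB+" = -5e-5, "AD+LB-" = -2.04e-4,
                   "AD+LB+" = -3.67e-4),
    ri_sd = 8e-4, rs_sd = 3e-5, resid_sd = 2e-4)
  cdrsb <- outcome_spec(
    "cdrsb", baseline = 1.44,
    baseline_beta = c("AD-LB+" = -0.15, "AD+LB-" = 0.84, "AD+LB+" = 1.23),
    slope = 0.2,
    slope_beta = c("AD-LB+" = 0.05, "AD+LB-" = 0.25, "AD+LB+" = 0.35),
    quad_beta = c("AD-LB+" = 0.01, "AD+LB-" = 0.05, "AD+LB+" = 0.14),
    ri_sd = 1.0, rs_sd = 0.2, resid_sd = 0.6)
  adas <- outcome_spec(
    "adas11", baseline = 8.49,
    baseline_beta = c("AD-LB+" = 0.59, "AD+LB-" = 1.42, "AD+LB+" = 2.73),
    slope = 0.5,
    slope_beta = c("AD-LB+" = 0.2, "AD+LB-" = 0.8, "AD+LB+" = 1.1),
    quad_beta = c("AD-LB+" = 0.03, "AD+LB-" = 0.12, "AD+LB+" = 0.44),
    ri_sd = 3.5, rs_sd = 0.6, resid_sd = 2.0)
  specs <- list(bag, mtl, bg, occ, mt, cdrsb, adas)
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Generate longitudinal outcome trajectories
#'
#' Produces a long-format table (one row per subject, visit, outcome) of the
#' configured outcomes. With all betas and noise at zero the trajectories are
#' flat at the baseline value; with random-effect and residual SDs at zero a
#' per-subject ordinary regression recovers the planted slope exactly.
#'
#' @param cohort A [generate_cohort()] result.
#' @param specs List of [outcome_spec()] objects (default
#'   [default_outcome_specs()]).
#' @param params A [generator_params()] (supplies the seed).
#' @param noise Draw random effects and residuals; `FALSE` gives the
#'   deterministic mean trajectories.
#' @return Long-format data frame: subject_id, group, time, outcome, value,
#'   baseline_age, sex, cognitive_state, education.
#' @export
generate_trajectories <- function(cohort, specs = NULL,
                                  params = generator_params(), noise = TRUE) {
  if (is.null(specs)) specs <- default_outcome_specs(params)
  if (inherits(specs, "outcome_spec")) specs <- list(specs)
  subjects <- cohort$subjects
  if (length(subjects) == 0L) return(data.frame())
  stopifnot(all(vapply(subjects, function(s) length(s$visit_times) >= 1L,
                       logical(1))))
  with_seed(params$seed + 1L, {
    out <- list()
    for (sp in specs) {
      for (s in subjects) {
        g <- s$true_group
        b0 <- if (noise && sp$ri_sd > 0) stats::rnorm(1, 0, sp$ri_sd) else 0
        b1 <- if (noise && sp$rs_sd > 0) stats::rnorm(1, 0, sp$rs_sd) else 0
        t <- s$visit_times
        mu <- sp$baseline + sp$baseline_beta[[g]] +
          (sp$slope + sp$slope_beta[[g]]) * t + sp$quad_beta[[g]] * t^2
        e <- if (noise && sp$resid_sd > 0) {
          stats::rnorm(length(t), 0, sp$resid_sd)
        } else 0
        out[[length(out) + 1L]] <- data.frame(
          subject_id = s$subject_id, group = g, time = t,
          outcome = sp$name, value = mu + b0 + b1 * t + e,
          baseline_age = s$CA0, sex = s$sex,
          cognitive_state = s$cognitive_state, education = s$education,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Generate raw regional volumetrics with intracranial volume
#'
#' Emits per-scan raw region volumes (cm3) for the constituent regions of
#' the standard composites, plus a per-subject intracranial volume (ICV), so
#' the normalization and aggregation path can be exercised end to end.
#' Region-level group effects are the composite-level defaults distributed
#' proportionally to each constituent's share of the composite baseline.
#'
#' @param cohort A [generate_cohort()] result.
#' @param params A [generator_params()].
#' @param icv_mean,icv_sd Intracranial volume distribution (cm3).
#' @param noise Add per-scan measurement noise.
#' @return Long-format data frame: subject_id, time, region, volume_cm3, icv_cm3.
#' @export
generate_volumetrics <- function(cohort, params = generator_params(),
                                 icv_mean = 1500, icv_sd = 120, noise = TRUE) {
  region_base <- c(hippocampus = 4.847, entorhinal = 2.334, amygdala = 1.997,
                   parahippocampal = 2.503, caudate = 3.6, putamen = 4.5,
                   accumbens = 0.9, pallidum = 3.647, lateral_occipital = 12.0,
                   cuneus = 6.0, pericalcarine = 4.0, lingual = 6.397,
                   middle_temporal = 13.421)
  comp <- composite_definitions()
  specs <- default_outcome_specs(params)
  region_of_comp <- list(mtl = comp$mtl, basal_ganglia = comp$basal_ganglia,
                         occipital = comp$occipital,
                         middle_temporal = comp$middle_temporal)
  with_seed(params$seed + 2L, {
    rows <- list()
    for (s in cohort$subjects) {
      icv <- max(stats::rnorm(1, icv_mean, if (noise) icv_sd else 0), 900)
      g <- s$true_group
      for (t in s$visit_times) {
        for (cn in names(region_of_comp)) {
          sp <- specs[[cn]]
          regions <- region_of_comp[[cn]]
          base_sum <- sum(region_base[regions])
          # composite-level normalized trajectory, de-normalized by ICV and
          # split proportionally across constituents
          comp_norm <- sp$baseline + sp$baseline_beta[[g]] +
            (sp$slope + sp$slope_beta[[g]]) * t
          scale <- comp_norm / sp$baseline
          for (r in regions) {
            v <- region_base[[r]] * scale * icv / 1500
            if (noise) v <- v + stats::rnorm(1, 0, 0.02 * region_base[[r]])
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = s$subject_id, time = t, region = r,
              volume_cm3 = v, icv_cm3 = icv, stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
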