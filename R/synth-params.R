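#' Pathology subgroup labels
#'
#' The five analysis groups: the cognitively unimpaired reference (CU) and the
#' four biomarker-defined cognitively impaired subgroups, where AD status is
#' set by the CSF p-tau181/Abeta42 ratio and LB status by the alpha-synuclein
#' seed amplification assay (SAA).
#'
#' @return Character vector of group labels in canonical order.
#' @export
pathology_groups <- function() {
  c("CU", "AD-LB-", "AD-LB+", "AD+LB-", "AD+LB+")
}

ci_groups <- function() pathology_groups()[-1]

#' Synthetic-cohort generator parameters
#'
#' Defines the study conditions emulated by the synthetic generator. Defaults
#' are anchored to the reported cohort: cognitively unimpaired (CU) ages
#' uniform over 23-100; cognitively impaired (CI) subgroup ages and female
#' fractions matching the published subgroup demographics; group brain-age
#' offsets at the reported subgroup means of the corrected brain-age gap
#' (0, 2.08, 2.40, 4.64, 6.93 years vs CU) and yearly slopes at the reported
#' fitted rates (0, 0.03, 0.14, 0.29, 0.54 yr/yr); scan-level noise SD 3.7 yr
#' (the subgroup standard deviations implied by the reported standard
#' errors); AD positivity threshold 0.021 on the p-tau181/Abeta42 ratio.
#'
#' @param n_cu Default CU count for convenience wrappers.
#' @param group_offset Named numeric: years added to the effective (brain)
#'   age of each group at baseline, relative to chronological age.
#' @param group_slope Named numeric: extra years of brain aging per follow-up
#'   year for each group.
#' @param noise_sd SD (years) of the per-scan effective-age noise.
#' @param age_range CU baseline age range (years).
#' @param ci_age_mean,ci_age_sd Per-CI-group baseline age distributions.
#' @param female_frac Named per-group female fractions.
#' @param ad_threshold p-tau181/Abeta42 ratio at or above which a record is
#'   AD-positive.
#' @param intermediate_frac Fraction of extra CI subjects generated with an
#'   intermediate SAA readout (these are excluded by subgroup
#'   classification).
#' @param visits_range Range of per-subject visit counts (annual visits).
#' @param volume_shape Voxel grid dimensions for rendered volumes.
#' @param voxel_noise_sd SD of additive voxel intensity noise.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_cu = 200L,
                             group_offset = c("CU" = 0, "AD-LB-" = 2.08,
                                              "AD-LB+" = 2.40, "AD+LB-" = 4.64,
                                              "AD+LB+" = 6.93),
                             group_slope = c("CU" = 0, "AD-LB-" = 0.03,
                                             "AD-LB+" = 0.14, "AD+LB-" = 0.29,
                                             "AD+LB+" = 0.54),
                             noise_sd = 3.7,
                             age_range = c(23, 100),
                             ci_age_mean = c("AD-LB-" = 72.0, "AD-LB+" = 73.8,
                                             "AD+LB-" = 73.5, "AD+LB+" = 74.3),
                             ci_age_sd = c("AD-LB-" = 8.2, "AD-LB+" = 7.2,
                                           "AD+LB-" = 7.0, "AD+LB+" = 7.2),
                             female_frac = c("CU" = 0.632, "AD-LB-" = 0.405,
                                             "AD-LB+" = 0.283, "AD+LB-" = 0.424,
                                             "AD+LB+" = 0.392),
                             ad_threshold = 0.021,
                             intermediate_frac = 0,
                             visits_range = c(1L, 6L),
                             volume_shape = c(32L, 32L, 32L),
                             voxel_noise_sd = 0.05,
                             seed = 1L) {
  grp <- pathology_groups()
  stopifnot(age_range[1] >= 0, age_range[2] > age_range[1],
            all(grp %in% names(group_offset)),
            all(grp %in% names(group_slope)),
            noise_sd >= 0, ad_threshold > 0,
            intermediate_frac >= 0, intermediate_frac < 1,
            visits_range[1] >= 1L, visits_range[2] >= visits_range[1],
            length(volume_shape) == 3L)
  if (any(volume_shape < 16L)) {
    stop("volume_shape must be at least 16 voxels per axis to host the ",
         "age-encoding structures")
  }
  if (group_offset["CU"] != 0 || group_slope["CU"] != 0) {
    stop("the CU group has offset 0 and slope 0 by construction")
  }
  structure(list(n_cu = as.integer(n_cu),
                 group_offset = group_offset[grp],
                 group_slope = group_slope[grp],
                 noise_sd = noise_sd, age_range = age_range,
                 ci_age_mean = ci_age_mean, ci_age_sd = ci_age_sd,
                 female_frac = female_frac[grp],
                 ad_threshold = ad_threshold,
                 intermediate_frac = intermediate_frac,
                 visits_range = as.integer(visits_range),
                 volume_shape = as.integer(volume_shape),
                 voxel_noise_sd = voxel_noise_sd,
                 seed = as.integer(seed)),
            class = "generator_params")
}
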