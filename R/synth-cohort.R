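# Synthetic cohort generation: subject records whose CSF biomarkers, SAA
# status, demographics, and visit schedules carry the statistical structure
# the downstream stages assume.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# Biomarker values consistent with a group label under the ratio threshold.
# AD+ ratios are drawn above the threshold, AD- ratios below, with a small
# guard band so boundary ties cannot flip labels.
draw_biomarkers <- function(n, ad_positive, threshold) {
  abeta42 <- rnorm_trunc(n, 800, 150, 300, 1700)
  ratio <- ifelse(ad_positive,
                  stats::runif(n, threshold * 1.2, threshold * 5),
                  stats::runif(n, threshold * 0.1, threshold * 0.8))
  list(ptau181 = ratio * abeta42, abeta42 = abeta42)
}

make_subject <- function(id, group, ca0, sex, education, cognitive_state,
                         ptau181, abeta42, saa, visit_times) {
  structure(list(subject_id = id, CA0 = ca0, sex = sex,
                 education = education, cognitive_state = cognitive_state,
                 ptau181 = ptau181, abeta42 = abeta42, saa = saa,
                 true_group = group, visit_times = visit_times),
            class = "subject_spec")
}

#' Generate a synthetic cohort
#'
#' Draws `n_cu` cognitively unimpaired subjects (ages uniform over the
#' configured range) and the four cognitively impaired biomarker subgroups
#' with the given sizes. Biomarkers are generated consistently with each
#' subject's group under the p-tau181/Abeta42 ratio threshold, so group
#' labels are recoverable from the generated fields via
#' [classify_subgroup()]. A configurable fraction of additional CI subjects
#' receives an intermediate SAA readout to exercise the exclusion rule.
#'
#' @param n_cu Number of cognitively unimpaired subjects.
#' @param n_per_group Named or positional counts for the four CI subgroups in
#'   the order `AD-LB-`, `AD-LB+`, `AD+LB-`, `AD+LB+`.
#' @param params A [generator_params()].
#' @return A list with `table` (one row per subject) and `subjects` (list of
#'   subject specifications carrying visit schedules).
#' @export
generate_cohort <- function(n_cu, n_per_group = c(0L, 0L, 0L, 0L),
                            params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n_cu <- as.integer(n_cu)
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 4L) {
    stop("n_per_group must give counts for the four CI subgroups")
  }
  if (n_cu < 0L || any(n_per_group < 0L)) stop("counts must be non-negative")
  groups <- ci_groups()
  n_int <- as.integer(round(params$intermediate_frac * sum(n_per_group)))
  with_seed(params$seed, {
    specs <- list()
    add <- function(group, n, saa_override = NULL) {
      if (n == 0L) return(invisible(NULL))
      if (group == "CU") {
        ca0 <- runif_range(n, params$age_range)
        state <- rep("CU", n)
        ad_pos <- rep(FALSE, n)
        saa <- rep("negative", n)
      } else {
        ca0 <- rnorm_trunc(n, params$ci_age_mean[group],
                           params$ci_age_sd[group],
                           params$age_range[1], params$age_range[2])
        state <- sample(c("MCI", "dementia"), n, replace = TRUE,
                        prob = c(0.7, 0.3))
        ad_pos <- rep(grepl("AD\\+", group), n)
        saa <- rep(if (grepl("LB\\+", group)) "positive" else "negative", n)
      }
      if (!is.null(saa_override)) saa <- rep(saa_override, n)
      sex <- ifelse(stats::runif(n) < params$female_frac[group], "F", "M")
      edu <- round(rnorm_trunc(n, 16, 2.7, 6, 24))
      bio <- draw_biomarkers(n, ad_pos, params$ad_threshold)
      vv <- seq(params$visits_range[1], params$visits_range[2])
      nv <- vv[sample.int(length(vv), n, replace = TRUE)]
      for (i in seq_len(n)) {
        id <- sprintf("S%05d", length(specs) + 1L)
        specs[[length(specs) + 1L]] <<- make_subject(
          id, group, ca0[i], sex[i], edu[i], state[i],
          bio$ptau181[i], bio$abeta42[i], saa[i],
          visit_times = as.numeric(0:(nv[i] - 1L)))
      }
    }
    add("CU", n_cu)
    for (g in seq_along(groups)) add(groups[g], n_per_group[g])
    if (n_int > 0L) {
      int_groups <- sample(groups, n_int, replace = TRUE)
      for (g in int_groups) add(g, 1L, saa_override = "intermediate")
    }
    table <- do.call(rbind, lapply(specs, function(s) {
      data.frame(subject_id = s$subject_id, CA0 = s$CA0, sex = s$sex,
                 education = s$education, cognitive_state = s$cognitive_state,
                 ptau181 = s$ptau181, abeta42 = s$abeta42, saa = s$saa,
                 true_group = s$true_group, n_visits = length(s$visit_times),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(table)) {
      table <- data.frame(subject_id = character(), CA0 = numeric(),
                          sex = character(), education = numeric(),
                          cognitive_state = character(), ptau181 = numeric(),
                          abeta42 = numeric(), saa = character(),
                          true_group = character(), n_visits = integer(),
                          stringsAsFactors = FALSE)
    }
    list(table = table, subjects = specs)
  })
}

#' Effective (generative) brain age of a synthetic subject
#'
#' The planted ground truth recovered by the brain-age pipeline: at follow-up
#' time `t` years, the effective age is `CA0 + t + group_offset +
#' group_slope * t`, optionally perturbed by Gaussian noise. CU subjects have
#' offset and slope zero by construction, so their effective age equals their
#' chronological age when noise is off.
#'
#' @param subject A subject specification from [generate_cohort()].
#' @param t Years since baseline (must be one of the subject's visit times).
#' @param params A [generator_params()].
#' @param noise_sd SD of additive noise in years; 0 (default) is
#'   deterministic.
#' @return Effective age in years.
#' @export
effective_age <- function(subject, t, params = generator_params(),
                          noise_sd = 0) {
  stopifnot(inherits(subject, "subject_spec"))
  if (!t %in% subject$visit_times) {
    stop("t = ", t, " is not a visit time of subject ", subject$subject_id)
  }
  g <- subject$true_group
  ea <- subject$CA0 + t + params$group_offset[[g]] + params$group_slope[[g]] * t
  if (noise_sd > 0) ea <- ea + stats::rnorm(1, 0, noise_sd)
  ea
}
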