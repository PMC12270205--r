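# Baseline general-linear-model contrasts and longitudinal linear mixed
# models for corrected brain-age gap, ICV-normalized regional volumes, and
# cognitive scores: linear or quadratic time trends, BIC order selection,
# and FDR-corrected pairwise group contrasts.

#' Standard regional composite definitions
#'
#' Bilateral composites: medial temporal lobe (hippocampus, entorhinal
#' cortex, amygdala, parahippocampal gyrus), basal ganglia (caudate, putamen,
#' accumbens, pallidum), occipital lobe (lateral occipital, cuneus,
#' pericalcarine, lingual), and middle temporal cortex.
#'
#' @return Named list of constituent region vectors.
#' @export
composite_definitions <- function() {
  list(mtl = c("hippocampus", "entorhinal", "amygdala", "parahippocampal"),
       basal_ganglia = c("caudate", "putamen", "accumbens", "pallidum"),
       occipital = c("lateral_occipital", "cuneus", "pericalcarine",
                     "lingual"),
       middle_temporal = "middle_temporal")
}

#' ICV-normalize regional volumes and aggregate composites
#'
#' Divides each region volume by the subject's intracranial volume (ICV) and
#' aggregates composites as the sum (default) or mean of their constituent
#' normalized volumes. A scan missing any constituent gets `NA` for that
#' composite.
#'
#' @param volumetrics Long-format data frame: `subject_id`, `time`, `region`,
#'   `volume_cm3`, `icv_cm3`.
#' @param composites Named list of constituent vectors (default
#'   [composite_definitions()]).
#' @param aggregate "sum" or "mean".
#' @return Long-format data frame: `subject_id`, `time`, `outcome`, `value`
#'   (ICV-normalized composite).
#' @export
normalize_and_aggregate <- function(volumetrics,
                                    composites = composite_definitions(),
                                    aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  need <- c("subject_id", "time", "region", "volume_cm3", "icv_cm3")
  stopifnot(all(need %in% names(volumetrics)))
  if (any(volumetrics$icv_cm3 <= 0)) stop("ICV must be positive")
  volumetrics$norm <- volumetrics$volume_cm3 / volumetrics$icv_cm3
  out <- list()
  for (cn in names(composites)) {
    members <- composites[[cn]]
    sub <- volumetrics[volumetrics$region %in% members, , drop = FALSE]
    if (nrow(sub) == 0L) next
    skey <- paste(sub$subject_id, sub$time, sep = "\r")
    agg <- tapply(sub$norm, skey, function(v) {
      if (length(v) < length(members)) return(NA_real_)
      if (aggregate == "sum") sum(v) else mean(v)
    })
    ids <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    out[[cn]] <- data.frame(subject_id = ids[, 1],
                            time = as.numeric(ids[, 2]), outcome = cn,
                            value = as.numeric(agg), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Locale-independent factor construction: canonical pathology-group order
# first (reference leading), then any other labels in first-appearance order.
canonical_group_factor <- function(x, reference) {
  canon <- c(reference, setdiff(pathology_groups(), reference))
  lev <- c(intersect(canon, unique(x)), setdiff(unique(x), canon))
  factor(x, levels = lev)
}

drop_constant_covariates <- function(data, covariates) {
  keep <- covariates[vapply(covariates, function(cv) {
    cv %in% names(data) && length(unique(stats::na.omit(data[[cv]]))) > 1L
  }, logical(1))]
  keep
}

#' Baseline group contrasts under a general linear model
#'
#' Fits `value ~ group + covariates` on baseline records (time 0) with
#' `AD-LB-` as the reference level, and returns adjusted group coefficients
#' plus all pairwise contrasts with Benjamini-Hochberg FDR adjustment.
#'
#' @param data Long-format baseline table with `group`, `value`, and the
#'   covariate columns.
#' @param covariates Covariate names (constant columns are dropped).
#' @param reference Reference group level.
#' @return List: `fit`, `coefficients` (group betas vs reference with SE and
#'   p), `contrasts` (all pairwise, raw and FDR-adjusted p).
#' @export
fit_baseline_glm <- function(data,
                             covariates = c("baseline_age", "sex",
                                            "cognitive_state", "education"),
                             reference = "AD-LB-") {
  stopifnot(all(c("group", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  if (!reference %in% data$group) reference <- data$group[1]
  data$group <- canonical_group_factor(data$group, reference)
  covariates <- drop_constant_covariates(data, covariates)
  rhs <- paste(c("group", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  grows <- grepl("^group", rownames(sm))
  coefs <- data.frame(group = sub("^group", "", rownames(sm)[grows]),
                      beta = sm[grows, 1], se = sm[grows, 2],
                      p = sm[grows, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  em <- suppressMessages(emmeans::emmeans(fit, "group"))
  ct <- summary(emmeans::contrast(em, method = "pairwise"), adjust = "none")
  contrasts <- data.frame(contrast = as.character(ct$contrast),
                          estimate = ct$estimate, se = ct$SE,
                          p_raw = ct$p.value,
                          p_adj = stats::p.adjust(ct$p.value, "BH"),
                          stringsAsFactors = FALSE)
  list(fit = fit, coefficients = coefs, contrasts = contrasts)
}

#' Longitudinal linear mixed model with linear or quadratic time
#'
#' Fits `value ~ group * time (+ group * time^2) + covariates` with random
#' intercepts and slopes per subject, by maximum likelihood (not REML) so
#' BIC values are comparable across fixed-effect structures. On convergence
#' failure the unstructured random-effect covariance is replaced by a
#' diagonal one and the fit is flagged.
#'
#' @param data Long-format table: `subject_id`, `group`, `time`, `value`,
#'   plus covariate columns.
#' @param order "linear" or "quadratic".
#' @param covariates Covariate names (constant columns dropped).
#' @param reference Reference group level.
#' @return A `longitudinal_fit` list: `fit`, `order`, `bic`, `fixed`
#'   (coefficient table), `contrasts` (baseline/slope/acceleration group
#'   contrasts with raw p), `fallback` flag.
#' @export
fit_lmm <- function(data, order = c("linear", "quadratic"),
                    covariates = c("baseline_age", "sex", "cognitive_state",
                                   "education"),
                    reference = "AD-LB-") {
  order <- match.arg(order)
  stopifnot(all(c("subject_id", "group", "time", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  if (any(data$time < 0)) stop("time since baseline must be >= 0")
  if (!reference %in% data$group) reference <- data$group[1]
  data$group <- canonical_group_factor(data$group, reference)
  data$tsq <- data$time^2
  covariates <- drop_constant_covariates(data, covariates)
  multi_group <- nlevels(data$group) > 1L
  fixed <- if (multi_group) "group * time" else "time"
  if (order == "quadratic") {
    fixed <- paste(fixed, "+", if (multi_group) "group * tsq" else "tsq")
  }
  rhs <- paste(c(fixed, covariates), collapse = " + ")
  f_full <- stats::as.formula(paste("value ~", rhs,
                                    "+ (1 + time | subject_id)"))
  f_diag <- stats::as.formula(paste("value ~", rhs,
                                    "+ (1 + time || subject_id)"))
  fallback <- FALSE
  quiet_lmer <- function(f) {
    tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(f, data = data, REML = FALSE))),
      error = function(e) NULL)
  }
  fit <- quiet_lmer(f_full)
  if (is.null(fit) || length(fit@optinfo$conv$lme4$messages) > 0) {
    fit2 <- quiet_lmer(f_diag)
    if (!is.null(fit2)) { fit <- fit2; fallback <- TRUE }
    if (is.null(fit)) stop("mixed model failed to converge under both ",
                           "unstructured and diagonal random effects")
  }
  sm <- stats::coef(summary(fit))
  fixed_tab <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                          se = sm[, "Std. Error"],
                          p = sm[, "Pr(>|t|)"], row.names = NULL,
                          stringsAsFactors = FALSE)
  contrasts <- NULL
  if (multi_group) {
    base_em <- suppressMessages(
      emmeans::emmeans(fit, "group", at = list(time = 0, tsq = 0),
                       lmer.df = "satterthwaite"))
    base_ct <- summary(emmeans::contrast(base_em, "pairwise"), adjust = "none")
    slope_em <- suppressMessages(
      emmeans::emtrends(fit, "group", var = "time", at = list(tsq = 0),
                        lmer.df = "satterthwaite"))
    slope_ct <- summary(emmeans::contrast(slope_em, "pairwise"),
                        adjust = "none")
    fam <- function(ct, family) {
      data.frame(family = family, contrast = as.character(ct$contrast),
                 estimate = ct$estimate, se = ct$SE, p_raw = ct$p.value,
                 stringsAsFactors = FALSE)
    }
    contrasts <- rbind(fam(base_ct, "baseline"), fam(slope_ct, "slope"))
    if (order == "quadratic") {
      acc_em <- suppressMessages(
        emmeans::emtrends(fit, "group", var = "tsq",
                          lmer.df = "satterthwaite"))
      acc_ct <- summary(emmeans::contrast(acc_em, "pairwise"), adjust = "none")
      contrasts <- rbind(contrasts, fam(acc_ct, "acceleration"))
    }
  }
  structure(list(fit = fit, order = order, bic = stats::BIC(fit),
                 fixed = fixed_tab, contrasts = contrasts,
                 fallback = fallback, n_obs = nrow(data)),
            class = "longitudinal_fit")
}

#' Choose between linear and quadratic trajectories by BIC
#'
#' Returns the fit with the lower BIC; ties favor the linear (parsimonious)
#' model. If one fit failed (is `NULL`), the surviving fit is returned with a
#' warning.
#'
#' @param fit_linear,fit_quadratic [fit_lmm()] results (either may be NULL).
#' @return The selected `longitudinal_fit`.
#' @export
select_model_bic <- function(fit_linear, fit_quadratic) {
  if (is.null(fit_linear) && is.null(fit_quadratic)) {
    stop("both fits failed")
  }
  if (is.null(fit_linear)) {
    warning("linear fit failed; returning quadratic")
    return(fit_quadratic)
  }
  if (is.null(fit_quadratic)) {
    warning("quadratic fit failed; returning linear")
    return(fit_linear)
  }
  if (fit_quadratic$bic < fit_linear$bic) fit_quadratic else fit_linear
}

#' FDR-adjusted pairwise group contrasts
#'
#' Applies Benjamini-Hochberg adjustment to the stored pairwise contrasts,
#' within each term family (baseline, slope, acceleration) separately.
#'
#' @param fit A [fit_lmm()] result, or a data frame with `family` and
#'   `p_raw` columns.
#' @param alpha Significance level used for the `significant` column.
#' @return The contrast table with `p_adj` and `significant` columns.
#' @export
pairwise_contrasts <- function(fit, alpha = 0.05) {
  ct <- if (inherits(fit, "longitudinal_fit")) fit$contrasts else fit
  if (is.null(ct)) stop("fit has no estimable group contrasts")
  stopifnot(all(c("family", "p_raw") %in% names(ct)))
  ct$p_adj <- NA_real_
  for (f in unique(ct$family)) {
    i <- ct$family == f
    ct$p_adj[i] <- stats::p.adjust(ct$p_raw[i], method = "BH")
  }
  ct$significant <- ct$p_adj < alpha
  ct
}
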