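# Bias correction of predicted brain age and cross-group / sex-stratified
# statistics of the corrected brain-age gap.

#' Fit the linear brain-age bias model
#'
#' Ordinary least squares of predicted brain age (BA) on chronological age
#' (CA), `BA = a * CA + b`, fitted on the cognitively unimpaired validation
#' set. The coefficients are frozen and reused for every other dataset.
#'
#' @param ca Chronological ages (years).
#' @param ba Predicted brain ages (years).
#' @param source Tag recording which dataset the model was fitted on.
#' @return An object of class `bias_model` with slope `a`, intercept `b`,
#'   `fit_n`, `fit_source`.
#' @export
fit_bias <- function(ca, ba, source = "CU-validation") {
  stopifnot(length(ca) == length(ba))
  if (length(ca) < 3L) stop("need at least 3 records to fit the bias model")
  if (stats::sd(ca) == 0) stop("chronological ages are degenerate (all equal)")
  fit <- stats::lm(ba ~ ca)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (abs(a) < 1e-8) {
    stop("fitted slope a is (numerically) zero; predicted ages carry no age ",
         "signal, bias correction is undefined")
  }
  structure(list(a = a, b = b, fit_n = length(ca), fit_source = source),
            class = "bias_model")
}

#' Apply the bias correction to prediction records
#'
#' Computes the raw gap `BA - CA` and the corrected brain-age gap
#' `(BA - b)/a - CA` using coefficients from [fit_bias()]. On the fitting set
#' itself, the corrected gap has mean zero and zero OLS slope against CA
#' (properties of least-squares residuals).
#'
#' @param model A [fit_bias()] result.
#' @param records Data frame with columns `CA` and `BA` (and any others,
#'   preserved).
#' @return The records with `raw_bag` and `corrected_bag` columns added.
#' @export
correct_bag <- function(model, records) {
  stopifnot(inherits(model, "bias_model"),
            all(c("CA", "BA") %in% names(records)))
  records$raw_bag <- records$BA - records$CA
  records$corrected_bag <- (records$BA - model$b) / model$a - records$CA
  records
}

#' Prediction accuracy metrics
#'
#' Mean absolute error between bias-corrected brain age `(BA - b)/a` and CA,
#' Spearman's rank correlation between BA and CA, the coefficient of
#' determination R2 of BA explained by CA in a linear model, and the mean
#' with standard error of the corrected gap.
#'
#' @param records Output of [correct_bag()].
#' @param model The [fit_bias()] model used (for the corrected MAE); when
#'   omitted, MAE is computed from `corrected_bag` directly.
#' @return List: `mae`, `spearman_r`, `r_squared`, `mean_bag`, `se_bag`, `n`.
#' @export
compute_metrics <- function(records, model = NULL) {
  stopifnot(nrow(records) >= 3L)
  mae <- mean(abs(records$corrected_bag))
  r <- stats::cor(records$BA, records$CA, method = "spearman")
  r2 <- summary(stats::lm(BA ~ CA, data = records))$r.squared
  list(mae = mae, spearman_r = r, r_squared = r2,
       mean_bag = mean(records$corrected_bag),
       se_bag = stats::sd(records$corrected_bag) / sqrt(nrow(records)),
       n = nrow(records))
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak adjustment: sort raw p ascending, adjust
#' `p_(i) -> 1 - (1 - p_(i))^(m - i + 1)`, and enforce monotonicity by
#' running maximum; adjusted values are returned in the input order.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values (same order as input).
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Residualize a response on chronological age (the default covariate
# adjustment before group comparisons).
residualize_on <- function(y, covariate) {
  stats::resid(stats::lm(y ~ covariate))
}

#' Group comparison of corrected brain-age gaps
#'
#' Adjusts the corrected gap for chronological age (residualization by
#' default, or an ANCOVA term), then runs a one-way ANOVA across groups
#' followed by Holm-Sidak-adjusted pairwise Welch t-tests.
#'
#' @param records Output of [correct_bag()] with `group` and `CA` columns.
#' @param adjust Covariate mechanism: "residualize" (default) regresses the
#'   gap on CA first; "ancova" models CA as a nuisance term (the ANOVA F for
#'   group is then the partial F).
#' @return List: `anova` (F, df, p), `pairwise` (data frame with raw and
#'   Holm-Sidak-adjusted p per group pair), `group_means`.
#' @export
group_stats <- function(records, adjust = c("residualize", "ancova")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("corrected_bag", "group", "CA") %in% names(records)))
  tab <- table(records$group)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("dropping groups with n < 2: ", paste(small, collapse = ", "))
    records <- records[!records$group %in% small, , drop = FALSE]
  }
  g <- factor(records$group)
  if (nlevels(g) < 2L) stop("need at least 2 groups with n >= 2")
  if (adjust == "residualize") {
    y <- residualize_on(records$corrected_bag, records$CA)
    fit <- stats::aov(y ~ g)
    a <- summary(fit)[[1]]
    anova_res <- list(F = a[["F value"]][1],
                      df = c(a[["Df"]][1], a[["Df"]][2]),
                      p = a[["Pr(>F)"]][1])
  } else {
    y <- records$corrected_bag
    fit <- stats::lm(y ~ records$CA + g)
    a <- stats::anova(fit)
    anova_res <- list(F = a[["F value"]][2],
                      df = c(a[["Df"]][2], a[["Df"]][3]),
                      p = a[["Pr(>F)"]][2])
    y <- residualize_on(records$corrected_bag, records$CA)
  }
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   diff = NA_real_, t = NA_real_, p_raw = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    y1 <- y[g == pairs[1, i]]; y2 <- y[g == pairs[2, i]]
    tt <- stats::t.test(y1, y2)
    pw$diff[i] <- mean(y1) - mean(y2)
    pw$t[i] <- unname(tt$statistic)
    pw$p_raw[i] <- tt$p.value
  }
  pw$p_adj <- holm_sidak(pw$p_raw)
  means <- tapply(records$corrected_bag, g, mean)
  ses <- tapply(records$corrected_bag, g,
                function(v) stats::sd(v) / sqrt(length(v)))
  list(anova = anova_res, pairwise = pw,
       group_means = data.frame(group = names(means), mean = as.numeric(means),
                                se = as.numeric(ses), n = as.integer(tab[names(means)]),
                                stringsAsFactors = FALSE))
}

#' Sex-stratified comparisons of corrected brain-age gaps
#'
#' Within each group, a two-sample Welch t-test of male versus female
#' corrected gaps after CA residualization, Holm-Sidak corrected across
#' groups; separately, per-sex one-way ANOVAs across groups.
#'
#' @param records Output of [correct_bag()] with `group`, `sex`, `CA`.
#' @return List: `within_group` (t-test per group, adjusted), `per_sex`
#'   (ANOVA per sex), `skipped` (groups lacking both sexes).
#' @export
sexwise_stats <- function(records) {
  stopifnot(all(c("corrected_bag", "group", "sex", "CA") %in% names(records)))
  records$adj <- residualize_on(records$corrected_bag, records$CA)
  groups <- sort(unique(records$group))
  rows <- list(); skipped <- character(0)
  for (g in groups) {
    r <- records[records$group == g, ]
    nf <- sum(r$sex == "F"); nm <- sum(r$sex == "M")
    if (nf < 2L || nm < 2L) {
      skipped <- c(skipped, g)
      next
    }
    tt <- stats::t.test(r$adj[r$sex == "M"], r$adj[r$sex == "F"])
    rows[[g]] <- data.frame(group = g, diff_m_minus_f = unname(diff(rev(tt$estimate))),
                            t = unname(tt$statistic), p_raw = tt$p.value,
                            stringsAsFactors = FALSE)
  }
  within <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(within)) within$p_adj <- holm_sidak(within$p_raw)
  per_sex <- list()
  for (sx in c("F", "M")) {
    r <- records[records$sex == sx, ]
    gs <- factor(r$group)
    if (nlevels(droplevels(gs)) >= 2L && min(table(droplevels(gs))) >= 2L) {
      a <- summary(stats::aov(r$adj ~ droplevels(gs)))[[1]]
      per_sex[[sx]] <- list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
    }
  }
  if (length(skipped)) {
    message("sexwise comparison skipped for: ", paste(skipped, collapse = ", "))
  }
  list(within_group = within, per_sex = per_sex, skipped = skipped)
}
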