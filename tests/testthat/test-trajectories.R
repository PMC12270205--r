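test_that("ICV normalization and composite aggregation follow the division rule", {
  v <- data.frame(subject_id = "s1", time = 0,
                  region = c("hippocampus", "entorhinal", "amygdala",
                             "parahippocampal"),
                  volume_cm3 = c(4.847, 2.334, 1.997, 2.503),
                  icv_cm3 = 1500)
  agg <- normalize_and_aggregate(v)
  mtl <- agg$value[agg$outcome == "mtl"]
  expect_equal(mtl, (4.847 + 2.334 + 1.997 + 2.503) / 1500)
  # single-region check of the division itself
  single <- normalize_and_aggregate(v, composites = list(h = "hippocampus"))
  expect_equal(single$value, 4.847 / 1500)
  expect_equal(single$value, 3.231e-3, tolerance = 1e-3)

  # doubling ICV halves every normalized value
  v2 <- v; v2$icv_cm3 <- 3000
  expect_equal(normalize_and_aggregate(v2, list(h = "hippocampus"))$value,
               single$value / 2)

  # zero constituents give a zero composite; a missing constituent gives NA
  v3 <- v; v3$volume_cm3 <- 0
  expect_equal(normalize_and_aggregate(v3)$value[1], 0)
  v4 <- v[-2, ]
  expect_true(is.na(normalize_and_aggregate(v4)$value[
    normalize_and_aggregate(v4)$outcome == "mtl"]))

  expect_error(normalize_and_aggregate(transform(v, icv_cm3 = -1)), "ICV")

  # mean aggregation is sum / #constituents
  expect_equal(normalize_and_aggregate(v, aggregate = "mean")$value[1],
               mtl / 4)
})

test_that("baseline GLM recovers noise-free and planted group effects", {
  params <- generator_params(seed = 31L)
  coh <- generate_cohort(0, c(60, 60, 60, 60), params)
  base <- coh$table
  dat <- data.frame(subject_id = base$subject_id, group = base$true_group,
                    baseline_age = base$CA0, sex = base$sex,
                    cognitive_state = base$cognitive_state,
                    education = base$education)
  # noise-free indicator outcome: exact recovery
  dat$value <- as.numeric(dat$group == "AD+LB+")
  res <- fit_baseline_glm(dat)
  b <- res$coefficients
  expect_equal(b$beta[b$group == "AD+LB+"], 1, tolerance = 1e-10)
  expect_equal(b$beta[b$group != "AD+LB+"], c(0, 0), tolerance = 1e-10)

  # planted offsets at reported effect sizes, paper-scale n
  params2 <- generator_params(seed = 32L)
  coh2 <- generate_cohort(0, c(195, 46, 396, 166), params2)
  base2 <- coh2$table
  offs <- c("AD-LB-" = 0, "AD-LB+" = 0, "AD+LB-" = 2.25, "AD+LB+" = 3.53)
  set.seed(32)
  dat2 <- data.frame(group = base2$true_group, baseline_age = base2$CA0,
                     sex = base2$sex, cognitive_state = base2$cognitive_state,
                     education = base2$education,
                     value = offs[base2$true_group] +
                       stats::rnorm(nrow(base2), 0, 3.7))
  res2 <- fit_baseline_glm(dat2)
  b2 <- res2$coefficients
  est <- b2$beta[b2$group == "AD+LB-"]; se <- b2$se[b2$group == "AD+LB-"]
  expect_lt(abs(est - 2.25), 2 * se)
  est4 <- b2$beta[b2$group == "AD+LB+"]; se4 <- b2$se[b2$group == "AD+LB+"]
  expect_lt(abs(est4 - 3.53), 2 * se4)

  # rank-deficient designs are rejected with the aliased column named
  dat3 <- dat
  dat3$education <- as.numeric(dat3$group == "AD+LB+")  # aliased with group
  dat3$value <- stats::rnorm(nrow(dat3))
  expect_error(fit_baseline_glm(dat3), "aliased|rank")
})

test_that("the mixed model recovers planted slopes and nests correctly", {
  # noise-free single-group data: exact slope recovery
  params <- generator_params(seed = 33L, visits_range = c(3L, 5L))
  coh <- generate_cohort(0, c(25, 0, 0, 0), params)
  sp <- outcome_spec("y", baseline = 2, slope = 0.5)
  tr <- generate_trajectories(coh, sp, params, noise = FALSE)
  fit <- fit_lmm(tr, "linear")
  expect_equal(fit$fixed$beta[fit$fixed$term == "time"], 0.5,
               tolerance = 1e-6)

  # noisy four-group data: slope contrasts carry the planted signs, and the
  # quadratic model's likelihood dominates the linear one (nesting)
  params2 <- generator_params(seed = 34L, visits_range = c(3L, 6L))
  coh2 <- generate_cohort(0, c(50, 50, 50, 50), params2)
  tr2 <- generate_trajectories(coh2, default_outcome_specs(params2)["bag"],
                               params2)
  lin <- fit_lmm(tr2, "linear")
  quad <- fit_lmm(tr2, "quadratic")
  expect_gte(as.numeric(stats::logLik(quad$fit)),
             as.numeric(stats::logLik(lin$fit)) - 1e-6)
  sel <- select_model_bic(lin, quad)
  expect_s3_class(sel, "longitudinal_fit")
  slope_ct <- lin$contrasts[lin$contrasts$family == "slope", ]
  ref_vs_copath <- slope_ct$estimate[
    slope_ct$contrast == "(AD-LB-) - (AD+LB+)"]
  expect_lt(ref_vs_copath, 0)
})

test_that("BIC selection favours the generating order and breaks ties to linear", {
  fl <- structure(list(bic = 100, order = "linear"),
                  class = "longitudinal_fit")
  fq <- structure(list(bic = 100, order = "quadratic"),
                  class = "longitudinal_fit")
  expect_equal(select_model_bic(fl, fq)$order, "linear")
  fq2 <- structure(list(bic = 90, order = "quadratic"),
                   class = "longitudinal_fit")
  expect_equal(select_model_bic(fl, fq2)$order, "quadratic")
  expect_warning(out <- select_model_bic(fl, NULL), "quadratic fit failed")
  expect_equal(out$order, "linear")
  expect_error(select_model_bic(NULL, NULL), "both")
})

test_that("MTL slope contrast sign is recovered across replicates", {
  signs <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    params <- generator_params(seed = 4000L + r, visits_range = c(2L, 5L))
    coh <- generate_cohort(0, c(40, 10, 60, 40), params)
    tr <- generate_trajectories(coh, default_outcome_specs(params)["mtl"],
                                params)
    fit <- fit_lmm(tr, "linear")
    ct <- fit$contrasts
    est <- ct$estimate[ct$family == "slope" &
                         ct$contrast == "(AD+LB-) - (AD+LB+)"]
    signs <- signs + isTRUE(est > 0)  # AD+LB+ declines faster than AD+LB-
  }
  expect_gte(signs, ceiling(0.95 * n_rep))
})

test_that("FDR adjustment of contrasts matches the Benjamini-Hochberg rule", {
  ct <- data.frame(family = "slope", contrast = letters[1:4],
                   p_raw = c(0.01, 0.02, 0.03, 0.04))
  adj <- pairwise_contrasts(ct, alpha = 0.05)
  expect_equal(adj$p_adj, rep(0.04, 4))
  ct2 <- data.frame(family = rep(c("baseline", "slope"), each = 3),
                    p_raw = rep(1, 6))
  expect_true(all(pairwise_contrasts(ct2)$p_adj == 1))
  set.seed(9)
  ct3 <- data.frame(family = "slope", p_raw = stats::runif(7))
  adj3 <- pairwise_contrasts(ct3)
  o <- order(ct3$p_raw)
  expect_true(all(diff(adj3$p_adj[o]) >= -1e-12))
})
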