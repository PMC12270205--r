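test_that("bias model recovers identity and planted coefficients", {
  ca <- seq(40, 90, length.out = 60)
  m <- fit_bias(ca, ca)
  expect_equal(m$a, 1, tolerance = 1e-12)
  expect_equal(m$b, 0, tolerance = 1e-10)

  set.seed(6)
  ca <- stats::runif(500, 23, 100)
  ba <- 0.8 * ca + 15 + stats::rnorm(500, 0, 1)
  m2 <- fit_bias(ca, ba)
  expect_gt(m2$a, 0.78); expect_lt(m2$a, 0.82)
  expect_gt(m2$b, 13); expect_lt(m2$b, 17)

  expect_error(fit_bias(rep(70, 10), stats::rnorm(10)), "degenerate")
  expect_error(fit_bias(ca, rep(75, 500)), "zero")
  expect_error(fit_bias(1:2, 1:2), "at least 3")
})

test_that("bias correction algebra holds on and off the fitting set", {
  id <- structure(list(a = 1, b = 0, fit_n = 10, fit_source = "test"),
                  class = "bias_model")
  rec <- data.frame(CA = c(60, 70), BA = c(65, 68))
  out <- correct_bag(id, rec)
  expect_equal(out$corrected_bag, out$raw_bag)

  m <- structure(list(a = 2, b = -10, fit_n = 10, fit_source = "test"),
                 class = "bias_model")
  one <- correct_bag(m, data.frame(CA = 70, BA = 150))
  expect_equal(one$corrected_bag, 10)

  # on the fitting set: zero mean and zero OLS slope against CA
  set.seed(2)
  ca <- stats::runif(300, 23, 100)
  ba <- 0.7 * ca + 20 + stats::rnorm(300, 0, 3)
  fitted_model <- fit_bias(ca, ba)
  rec2 <- correct_bag(fitted_model, data.frame(CA = ca, BA = ba))
  expect_lt(abs(mean(rec2$corrected_bag)), 1e-8)
  sl <- stats::coef(stats::lm(corrected_bag ~ CA, rec2))[2]
  expect_lt(abs(sl), 1e-8)

  # refitting after an affine rescaling of BA leaves the corrected gap
  # unchanged
  ba3 <- 1.9 * ba - 12
  rec3 <- correct_bag(fit_bias(ca, ba3), data.frame(CA = ca, BA = ba3))
  expect_equal(rec3$corrected_bag, rec2$corrected_bag, tolerance = 1e-8)
})

test_that("accuracy metrics match closed-form cases", {
  id <- structure(list(a = 1, b = 0, fit_n = 3, fit_source = "t"),
                  class = "bias_model")
  ca <- seq(30, 90, by = 2)
  perfect <- correct_bag(id, data.frame(CA = ca, BA = ca))
  m <- compute_metrics(perfect)
  expect_equal(m$mae, 0)
  expect_equal(m$spearman_r, 1)
  expect_equal(m$r_squared, 1)

  rev_rec <- correct_bag(id, data.frame(CA = ca, BA = rev(ca)))
  expect_equal(compute_metrics(rev_rec)$spearman_r, -1)

  alt <- correct_bag(id, data.frame(CA = ca,
                                    BA = ca + c(2, -2)[seq_along(ca) %% 2 + 1]))
  expect_equal(compute_metrics(alt)$mae, 2)
})

test_that("Holm-Sidak adjustment matches the step-down formula", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(c(0.04, 0.01)), c(0.04, 1 - 0.99^2))
  expect_equal(holm_sidak(numeric(0)), numeric(0))
  set.seed(3)
  for (i in 1:20) {
    p <- stats::runif(sample(2:8, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("group statistics recover the planted subgroup pattern", {
  set.seed(42)
  offs <- c("CU" = 0, "AD-LB-" = 2.08, "AD-LB+" = 2.40, "AD+LB-" = 4.64,
            "AD+LB+" = 6.93)
  ns <- c("CU" = 436, "AD-LB-" = 195, "AD-LB+" = 46, "AD+LB-" = 396,
          "AD+LB+" = 166)
  rec <- do.call(rbind, lapply(names(ns), function(g) {
    data.frame(group = g, CA = stats::runif(ns[g], 55, 90),
               corrected_bag = offs[g] + stats::rnorm(ns[g], 0, 3.7))
  }))
  res <- group_stats(rec)
  expect_lt(res$anova$p, 1e-10)
  pw <- res$pairwise
  pick <- function(a, b) {
    pw$p_adj[(pw$group1 == a & pw$group2 == b) |
               (pw$group1 == b & pw$group2 == a)]
  }
  for (g in c("AD-LB-", "AD-LB+", "AD+LB-", "AD+LB+")) {
    expect_lt(pick("CU", g), 0.05)
  }
  expect_lt(pick("AD+LB+", "AD+LB-"), 0.05)
  expect_lt(pick("AD+LB+", "AD-LB+"), 0.05)
  expect_gt(pick("AD-LB-", "AD-LB+"), 0.05)  # the one under-powered pair

  # residualization and ANCOVA agree on the group F up to the standard
  # df bookkeeping difference
  res2 <- group_stats(rec, adjust = "ancova")
  expect_equal(res$anova$F, res2$anova$F, tolerance = 0.05)
})

test_that("sex-stratified tests recover a planted sex-by-pathology reversal", {
  set.seed(7)
  groups <- c("AD-LB-", "AD-LB+", "AD+LB-", "AD+LB+")
  rec <- do.call(rbind, lapply(groups, function(g) {
    male_shift <- if (grepl("AD\\-", g)) 1 else -1
    data.frame(group = g, sex = rep(c("F", "M"), each = 200),
               CA = stats::runif(400, 60, 85),
               corrected_bag = stats::rnorm(400, 0, 2) +
                 rep(c(0, male_shift), each = 200))
  }))
  res <- sexwise_stats(rec)
  w <- res$within_group
  expect_gt(w$diff_m_minus_f[w$group == "AD-LB-"], 0)
  expect_gt(w$diff_m_minus_f[w$group == "AD-LB+"], 0)
  expect_lt(w$diff_m_minus_f[w$group == "AD+LB-"], 0)
  expect_lt(w$diff_m_minus_f[w$group == "AD+LB+"], 0)
  expect_true(all(w$p_adj < 0.05))

  # an all-female subgroup is skipped; the others are unaffected
  rec2 <- rec
  rec2 <- rec2[!(rec2$group == "AD-LB+" & rec2$sex == "M"), ]
  res2 <- suppressMessages(sexwise_stats(rec2))
  expect_true("AD-LB+" %in% res2$skipped)
  expect_setequal(res2$within_group$group, c("AD-LB-", "AD+LB-", "AD+LB+"))
})
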