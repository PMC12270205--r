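test_that("cohort generation honours counts, is seeded, and is empty-safe", {
  params <- generator_params(seed = 3L)
  empty <- generate_cohort(0, c(0, 0, 0, 0), params)
  expect_equal(nrow(empty$table), 0L)
  expect_length(empty$subjects, 0L)

  coh <- generate_cohort(10, c(195, 46, 396, 166), params)
  counts <- table(coh$table$true_group)
  expect_equal(as.integer(counts[c("AD-LB-", "AD-LB+", "AD+LB-", "AD+LB+")]),
               c(195L, 46L, 396L, 166L))
  expect_equal(unname(counts[["CU"]]), 10L)

  again <- generate_cohort(10, c(195, 46, 396, 166), params)
  expect_identical(coh$table, again$table)

  expect_error(generate_cohort(-1, c(0, 0, 0, 0), params), "non-negative")
})

test_that("generated biomarkers reclassify to the planted group", {
  params <- generator_params(seed = 8L, intermediate_frac = 0.1)
  coh <- generate_cohort(20, c(30, 30, 30, 30), params)
  tab <- coh$table
  cl <- classify_subgroup(tab$ptau181, tab$abeta42, tab$saa,
                          params$ad_threshold)
  ci <- tab$true_group != "CU" & tab$saa != "intermediate"
  expect_true(all(cl[ci] == tab$true_group[ci]))
  expect_true(all(cl[tab$saa == "intermediate"] == "excluded"))
  expect_gt(sum(tab$saa == "intermediate"), 0L)
  # CU subjects are AD- and SAA-negative by construction
  expect_true(all(cl[tab$true_group == "CU"] == "AD-LB-"))
})

test_that("effective age follows the planted offset and slope model", {
  params <- generator_params(seed = 1L)
  cu <- one_subject("CU", ca0 = 64.5, visits = c(0, 1, 2, 5))
  for (t in c(0, 1, 5)) {
    expect_identical(effective_age(cu, t, params), 64.5 + t)
  }

  p2 <- generator_params(
    seed = 1L,
    group_offset = c("CU" = 0, "AD-LB-" = 0, "AD-LB+" = 0, "AD+LB-" = 0,
                     "AD+LB+" = 3.53),
    group_slope = c("CU" = 0, "AD-LB-" = 0, "AD-LB+" = 0, "AD+LB-" = 0,
                    "AD+LB+" = 0.54))
  s <- one_subject("AD+LB+", ca0 = 70, visits = c(0, 2))
  expect_equal(effective_age(s, 2, p2), 76.61)
  expect_equal(effective_age(s, 0, p2), 70 + 3.53)
  expect_error(effective_age(s, 3, p2), "not a visit time")
})

test_that("rendered volumes encode age monotonically and deterministically", {
  params <- generator_params(seed = 2L)
  young <- one_subject("CU", ca0 = 30, visits = 0)
  old <- one_subject("CU", ca0 = 90, visits = 0)
  cavity_voxels <- function(vol) sum(vol < 0.3 & brainage:::radius_grid(dim(vol)) < 0.7)
  vy <- render_volume(young, 0, params, noise = FALSE)
  vo <- render_volume(old, 0, params, noise = FALSE)
  expect_gt(cavity_voxels(vo), cavity_voxels(vy))

  expect_identical(as.vector(render_volume(young, 0, params, noise = FALSE)),
                   as.vector(render_volume(young, 0, params, noise = FALSE)))
  expect_identical(as.vector(render_volume(young, 0, params, seed = 7L)),
                   as.vector(render_volume(young, 0, params, seed = 7L)))

  # brute-force feature extraction over 100 noise-off CU volumes: the
  # cavity radius (cube root of the voxel count) grows linearly with age
  coh <- generate_cohort(100, c(0, 0, 0, 0), params)
  cav <- vapply(coh$subjects, function(s) {
    cavity_voxels(render_volume(s, 0, params, noise = FALSE))
  }, numeric(1))
  ca <- coh$table$CA0
  expect_gt(stats::cor(cav^(1 / 3), ca), 0.99)
})

test_that("volume rendering rejects grids too small for the structures", {
  expect_error(generator_params(volume_shape = c(8, 8, 8)), "at least 16")
})

test_that("trajectory generator is flat under the null and exact without noise", {
  params <- generator_params(seed = 4L)
  coh <- generate_cohort(0, c(3, 3, 3, 3), params)
  null_spec <- outcome_spec("y", baseline = 5)
  tr <- generate_trajectories(coh, null_spec, params, noise = FALSE)
  expect_true(all(tr$value == 5))

  # slope difference between AD+LB+ and AD+LB- over 10 years, default betas
  p10 <- generator_params(seed = 4L, visits_range = c(11L, 11L))
  coh10 <- generate_cohort(0, c(0, 0, 2, 2), p10)
  mtl <- default_outcome_specs(p10)$mtl
  tr10 <- generate_trajectories(coh10, mtl, p10, noise = FALSE)
  g <- function(grp, t) tr10$value[tr10$group == grp & tr10$time == t][1]
  d_slope10 <- (g("AD+LB+", 10) - g("AD+LB+", 0)) -
    (g("AD+LB-", 10) - g("AD+LB-", 0))
  expect_equal(d_slope10, -6.9e-4, tolerance = 1e-10)

  # with all randomness off, per-subject OLS recovers the planted slope
  sp <- outcome_spec("y", baseline = 1, slope = 0.25,
                     slope_beta = c("AD+LB+" = 0.1))
  tr2 <- generate_trajectories(coh, sp, params, noise = FALSE)
  one <- tr2[tr2$subject_id == tr2$subject_id[1] & tr2$outcome == "y", ]
  if (nrow(one) >= 2) {
    sl <- stats::coef(stats::lm(value ~ time, one))[2]
    truth <- 0.25 + 0.1 * (one$group[1] == "AD+LB+")
    expect_equal(unname(sl), truth, tolerance = 1e-12)
  }
})

test_that("planted slope ordering is preserved in generated outcomes", {
  params <- generator_params(seed = 6L, visits_range = c(5L, 6L))
  coh <- generate_cohort(0, c(120, 120, 120, 120), params)
  tr <- generate_trajectories(coh, default_outcome_specs(params)["bag"],
                              params)
  slopes <- vapply(ci_groups <- c("AD-LB-", "AD-LB+", "AD+LB-", "AD+LB+"),
                   function(g) {
    d <- tr[tr$group == g, ]
    unname(stats::coef(stats::lm(value ~ time, d))[2])
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("regional volumetrics reproduce composite trajectories after aggregation", {
  params <- generator_params(seed = 12L, visits_range = c(3L, 3L))
  coh <- generate_cohort(0, c(4, 4, 4, 4), params)
  vols <- generate_volumetrics(coh, params, noise = FALSE)
  agg <- normalize_and_aggregate(vols)
  mtl <- agg[agg$outcome == "mtl", ]
  expect_true(all(is.finite(mtl$value)))
  # noise-free: AD+LB+ subjects decline faster than AD-LB- subjects
  sl <- function(g) {
    ids <- coh$table$subject_id[coh$table$true_group == g]
    d <- mtl[mtl$subject_id %in% ids, ]
    unname(stats::coef(stats::lm(value ~ time, d))[2])
  }
  expect_lt(sl("AD+LB+"), sl("AD-LB-"))
})
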