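test_that("the packaged study table averages and extrapolates correctly", {
  records <- read_occupancy_table()
  expect_equal(average_hc_occupancy(records), 0.236)
  expect_equal(average_hc_occupancy(records[1, , drop = FALSE]), 0.12)
  expect_error(average_hc_occupancy(records[records$cohort == "SZ", ]),
               "healthy-control")

  m1 <- build_model(0.12, 0.21, 1.2, "Model 1")
  expect_equal(extrapolate_sz_occupancy(0.236, m1), 0.236 * 21 / 12,
               tolerance = 1e-10)
  expect_equal(extrapolate_sz_occupancy(0.12, m1), 0.21, tolerance = 1e-10)
  # unit ratio model leaves the occupancy unchanged
  expect_equal(extrapolate_sz_occupancy(0.3, build_model(0.2, 0.2)), 0.3)
})

test_that("malformed occupancy tables are rejected with the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_label,cohort,occupancy_percent",
               "a,HC,12", "b,XX,20"), path)
  expect_error(read_occupancy_table(path), "row 2.*HC.*SZ|row 2")
  writeLines(c("study_label,cohort,occupancy_percent",
               "a,HC,12", "b,SZ,120"), path)
  expect_error(read_occupancy_table(path), "row 2")
  writeLines("study_label,value", path)
  expect_error(read_occupancy_table(path), "columns")
})

test_that("both canonical calibrations reproduce the reference cells", {
  models <- canonical_models()
  m1 <- models$model1; m2 <- models$model2
  expect_equal(models$hc_average, 0.236)
  expect_equal(models$sz_extrapolated, 0.413, tolerance = 5e-4)
  expect_equal(m1$hc$b_max, 1)
  expect_equal(m1$sz$b_max, 1.2)
  # all eight cells: densities, occupancies, normalized DA levels
  expect_equal(occupancy_from_da(c(m1$hc$y, m1$sz$y, m2$hc$y, m2$sz$y)),
               c(0.12, 0.21, 0.24, 0.41))
  expect_equal(round(c(m1$hc$y, m1$sz$y, m2$hc$y, m2$sz$y), 3),
               c(0.136, 0.266, 0.316, 0.695))
  # degenerate calibration with no endogenous DA
  m0 <- build_model(0, 0, 1)
  expect_equal(c(m0$hc$y, m0$sz$y), c(0, 0))
})

test_that("equilibrium inversion recovers efficacy and PFC activity", {
  m1 <- build_model(0.12, 0.21, 1.2, "Model 1")
  # no D2 effects: v_ps = 1, x_p = J_d - Y
  e0 <- efficacy_and_pfc(m1, a = 0, b = 0)
  expect_equal(e0$v_ps, c(1, 1))
  expect_equal(e0$x_p[e0$cohort == "HC"], 1 - m1$hc$y, tolerance = 1e-12)
  expect_equal(e0$x_p[e0$cohort == "SZ"], 1 - m1$sz$y, tolerance = 1e-12)
  # hypofrontality: -0.1295 exactly, -0.130 at the precision of the
  # rounded calibration cells
  expect_equal(diff(e0$x_p), -0.130, tolerance = 0.005)

  # the inversion is the exact inverse of the forward equilibrium
  for (b in c(0, 0.5, 1)) {
    for (a in c(0, 0.2)) {
      params <- circuit_params(a = a, b = b)
      eq <- solve_equilibrium(params, 0.6)
      m <- build_model(occupancy_from_da(eq$y), occupancy_from_da(eq$y), 1)
      inv <- efficacy_and_pfc(m, a = a, b = b, scale_with_density = FALSE)
      expect_equal(inv$x_p, c(0.6, 0.6), tolerance = 1e-9)
      expect_equal(inv$v_ps, rep(1 - b * eq$p, 2), tolerance = 1e-12)
    }
  }
  # total heteroreceptor suppression is flagged infeasible
  strong <- build_model(0.9, 0.9, 1.2)
  expect_error(efficacy_and_pfc(strong, a = 0, b = 1.2), "infeasible")
})

test_that("patient-control differences behave as the calibration predicts", {
  m1 <- build_model(0.12, 0.21, 1.2, "Model 1")
  m2 <- build_model(0.24, 0.41, 1.2, "Model 2")
  a_vals <- c(0, 0.1, 0.2)
  d1 <- sz_hc_differences(m1, a = a_vals, b = seq(0, 1, by = 0.1))
  expect_true(all(d1$feasible))
  # efficacy difference vanishes without the heteroreceptor
  expect_equal(d1$d_v_ps[d1$b == 0], rep(0, length(a_vals)))
  # and is bitwise identical across autoreceptor strengths
  for (bb in unique(d1$b)) {
    dv <- d1$d_v_ps[d1$b == bb]
    expect_identical(dv, rep(dv[1], length(a_vals)))
  }
  # PFC-activity difference does depend on the autoreceptor
  dx_by_a <- d1$d_x_p[d1$b == 1]
  expect_gt(max(dx_by_a) - min(dx_by_a), 1e-6)
  # reference values at (a, b) = (0, 0), and Model 2's larger hypofrontality
  expect_equal(d1$d_x_p[d1$a == 0 & d1$b == 0], -0.130, tolerance = 0.005)
  d2 <- sz_hc_differences(m2, a = 0, b = 0)
  expect_equal(d2$d_x_p, -(0.695 - 0.316), tolerance = 0.005)
  expect_gt(abs(d2$d_x_p), abs(d1$d_x_p[d1$a == 0 & d1$b == 0]))
})

test_that("synthetic depletion studies are reproducible and recoverable", {
  # noise-free: every subject inverts exactly to the true DA level
  clean <- generate_depletion_study(0.266, b_max = 1.2, alpha = 0.3,
                                    n_subjects = 5, noise_cv = 0)
  est <- vapply(clean, estimate_da_from_depletion, numeric(1))
  expect_equal(est, rep(0.266, 5), tolerance = 1e-12)
  # determinism under a fixed seed
  s1 <- generate_depletion_study(0.266, n_subjects = 10, noise_cv = 0.05,
                                 seed = 11)
  s2 <- generate_depletion_study(0.266, n_subjects = 10, noise_cv = 0.05,
                                 seed = 11)
  expect_identical(s1, s2)
  # Monte-Carlo recovery: mean estimate within 3 SE of the truth
  study <- generate_depletion_study(0.266, n_subjects = 50, noise_cv = 0.05,
                                    seed = 5)
  est <- vapply(study, estimate_da_from_depletion, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.266), 3 * se)
  # error shrinks as the noise shrinks
  mae <- vapply(c(0.1, 0.05, 0.01), function(cv) {
    st <- generate_depletion_study(0.266, n_subjects = 200, noise_cv = cv,
                                   seed = 17)
    median(abs(vapply(st, estimate_da_from_depletion, numeric(1)) - 0.266))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})
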