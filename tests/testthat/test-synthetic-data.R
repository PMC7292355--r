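test_that("zero dialyzer clearance removes nothing and leaves the curve unchanged", {
  grid <- seq(0, 5, by = 0.05)
  base <- two_compartment_params(v_central = 0.2, v_peripheral = 0.4,
                                 q_intercompartmental = 0.06, fu = 0.7,
                                 cl_dialyzer = 0, infusion_rate = 6,
                                 infusion_duration = 1,
                                 dialysis_windows = rbind(c(1, 3)))
  no_windows <- base; no_windows$dialysis_windows <- matrix(numeric(0), ncol = 2)
  s1 <- simulate_hd_study(base, grid)
  s2 <- simulate_hd_study(no_windows, grid)
  expect_equal(s1$removal_percent_true, 0)
  expect_equal(s1$c_central[match(grid, s1$times)],
               s2$c_central[match(grid, s2$times)], tolerance = 1e-9)
})

test_that("one-compartment removal matches the analytic washout", {
  # bolus 30 mg into 0.1 L, dialyzer clearance 0.83 mL/min for 2 h
  cl <- 0.83 / 1000 * 60
  p <- two_compartment_params(v_central = 0.1, fu = 1, cl_dialyzer = cl,
                              dialysis_windows = rbind(c(0, 2)))
  s <- simulate_hd_bolus(p, dose = 30, grid = seq(0, 2, by = 0.05))
  truth <- 100 * (1 - exp(-cl * 2 / 0.1))
  expect_equal(truth, 63.06, tolerance = 1e-3)
  expect_equal(s$removal_percent_true, truth, tolerance = 1e-6)
})

test_that("mass balance closes to 1e-6 at every output time", {
  grid <- seq(0, 8, by = 0.1)
  cases <- list(
    default_rat_params(),
    two_compartment_params(v_central = 0.15, v_peripheral = 0.3,
                           q_intercompartmental = 0.04, fu = 0.4,
                           cl_dialyzer = 0.08, cl_nonrenal = 0.02,
                           infusion_rate = 20, infusion_start = 0.5,
                           infusion_duration = 0.25,
                           dialysis_windows = rbind(c(1, 3), c(5, 6)))
  )
  for (p in cases) {
    s <- simulate_hd_study(p, grid)
    expect_lt(max(mass_balance_error(s)), 1e-6)
  }
})

test_that("redistribution produces the post-dialysis rebound", {
  # dialysis drains the central compartment faster than the periphery
  # refills it: start from distribution equilibrium, dialyze hard for 2 h
  p <- two_compartment_params(v_central = 0.15, v_peripheral = 0.3,
                              q_intercompartmental = 0.15, fu = 0.8,
                              cl_dialyzer = 0.6,
                              dialysis_windows = rbind(c(6, 8)))
  s <- simulate_hd_bolus(p, 10, seq(0, 10, by = 1 / 60))
  c_end <- s$c_central[which.min(abs(s$times - 8))]
  c_10min <- s$c_central[which.min(abs(s$times - (8 + 10 / 60)))]
  expect_gt(c_10min, c_end)
  # the gradient driving it: peripheral above central at the window end
  expect_gt(s$c_peripheral[which.min(abs(s$times - 8))], c_end)
})

test_that("dialysate sampling reproduces the true removal rate exactly", {
  s <- simulate_hd_study(default_rat_params(), seq(0, 4, by = 0.05))
  m <- sample_dialysate(s, dialysate_flow = 5, duration = 2)
  expect_equal(m$dialysate_volume, 600)
  expect_equal(drug_removal_rate(m), s$removal_percent_true, tolerance = 1e-9)
  expect_error(sample_dialysate(s, 0, 2), "positive")
  expect_error(sample_dialysate(s, 5, 3), "exceeds the simulated dialysis time")
})

test_that("first-order extrapolation is exact without a peripheral compartment and overestimates with one", {
  cl <- 0.06
  one <- two_compartment_params(v_central = 0.2, fu = 1, cl_dialyzer = cl,
                                dialysis_windows = rbind(c(0, 4)))
  grid <- seq(0, 4, by = 0.02)
  s4 <- simulate_hd_bolus(one, 10, grid)
  # removal over the first 2 h from the same run
  i2 <- which.min(abs(s4$times - 2))
  r2 <- 100 * s4$cumulative_dialysate_mass[i2] / s4$dose
  expect_equal(extrapolate_removal(r2, 2, 4), s4$removal_percent_true,
               tolerance = 1e-6)

  # redistribution-limited case: the periphery cannot resupply the central
  # compartment fast enough, so the second 2 h removes less than first-order
  # kinetics predicts
  two <- two_compartment_params(v_central = 0.15, v_peripheral = 0.5,
                                q_intercompartmental = 0.02, fu = 1,
                                cl_dialyzer = 0.15,
                                dialysis_windows = rbind(c(0, 4)))
  t4 <- simulate_hd_bolus(two, 10, grid)
  j2 <- which.min(abs(t4$times - 2))
  q2 <- 100 * t4$cumulative_dialysate_mass[j2] / t4$dose
  expect_gt(extrapolate_removal(q2, 2, 4), t4$removal_percent_true)
})

test_that("NCA on a dense noise-free simulation recovers Vss and CL", {
  p <- two_compartment_params(v_central = 0.2, v_peripheral = 0.33,
                              q_intercompartmental = 0.05, fu = 1,
                              cl_nonrenal = 0.04)
  grid <- seq(0, 600, by = 0.25)
  s <- simulate_hd_bolus(p, 10, grid)
  ser <- conc_time_series(s$times, s$c_central, dose = 10, body_weight = 1)
  res <- nca(ser)
  expect_equal(res$cl_total, 0.04, tolerance = 0.01)
  expect_equal(res$vd_ss, 0.53, tolerance = 0.01)
})

test_that("cohorts are seed-reproducible and collapse to identical subjects without noise", {
  p <- default_rat_params()
  grid <- seq(0, 4, by = 0.25)
  a <- generate_cohort(p, grid, n_subjects = 3, noise_cv = 0.1,
                       param_cv = 0.15, seed = 11)
  b <- generate_cohort(p, grid, n_subjects = 3, noise_cv = 0.1,
                       param_cv = 0.15, seed = 11)
  expect_identical(a, b)
  c2 <- generate_cohort(p, grid, n_subjects = 3, noise_cv = 0.1,
                        param_cv = 0.15, seed = 12)
  expect_false(identical(a, c2))

  quiet <- generate_cohort(p, grid, n_subjects = 3, noise_cv = 0,
                           param_cv = 0, seed = 5)
  expect_equal(quiet$subjects[[1]]$series$concentrations,
               quiet$subjects[[2]]$series$concentrations)
  expect_equal(quiet$subjects[[2]]$series$concentrations,
               quiet$subjects[[3]]$series$concentrations)
})

test_that("extrapolating a mono-exponential cohort to 4 h is nearly unbiased", {
  cl <- 0.05
  p2 <- two_compartment_params(v_central = 0.2, fu = 1, cl_dialyzer = cl,
                               infusion_rate = 10, infusion_duration = 0.25,
                               infusion_start = 0,
                               dialysis_windows = rbind(c(0.25, 2.25)))
  p4 <- p2; p4$dialysis_windows <- rbind(c(0.25, 4.25))
  grid2 <- seq(0, 2.25, by = 0.05)
  grid4 <- seq(0, 4.25, by = 0.05)
  s2 <- simulate_hd_study(p2, grid2)
  s4 <- simulate_hd_study(p4, grid4)
  est4 <- extrapolate_removal(s2$removal_percent_true, 2, 4)
  expect_lt(abs(est4 - s4$removal_percent_true), 0.5)
})
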