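test_that("identical configurations produce bit-identical trajectories", {
  a <- run_simulation("bradycardia", years = 1)
  b <- run_simulation("bradycardia", years = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 366) # day 0 .. day 365
})

test_that("recording stride keeps day zero, the grid and the final day", {
  traj <- run_simulation("normal_aging", years = 2, record_stride = 365)
  expect_equal(traj$t_days, c(0, 365, 730))
  full <- run_simulation("normal_aging", years = 2)
  expect_equal(nrow(full), 731)
  expect_equal(full$t_days, 0:730)
})

test_that("the ledger detects tampering and is zero for an inert run", {
  traj <- run_simulation("normal_aging", years = 3, record_stride = 30)
  expect_lt(mass_balance_residual(traj), 1e-9)

  bad <- traj
  bad$C1[20] <- bad$C1[20] * 1.01
  expect_gt(mass_balance_residual(bad), 1e-9)

  inert <- update_params(default_params(), k3 = 0, k8 = 0, k5 = 0, k11 = 0,
                         C1_0 = 0, C4_0 = 0)
  quiet <- run_simulation("normal_aging", years = 1, params = inert)
  expect_identical(mass_balance_residual(quiet), 0)
})

test_that("the fine-step reference integrator reproduces the cell-pool closed forms", {
  ref <- reference_50y()
  last <- ref[nrow(ref), ]
  p <- default_params()
  expect_equal(last$N / p$N0, 0.99^50, tolerance = 1e-6)
  expect_equal(last$M / p$M0, (1 - 7.3e-5)^18250, tolerance = 1e-6)
  expect_equal(last$LRP / p$LRP0, 0.99^50, tolerance = 1e-6) # ~0.605, the ~60% endpoint
  expect_error(reference_integrate(years = 1, fine_dt = 0.5),
               class = "glymphsim_invalid_parameter")
})

test_that("velocity calibration recovers a known synthetic v0 and flags unreachable anchors", {
  p <- default_params()
  v_true <- 0.25
  dep <- endpoints(run_simulation("normal_aging", years = 5,
                                  record_stride = 5 * 365,
                                  params = update_params(p, v0 = v_true)))[["C9"]]
  cal <- calibrate_v0(p, anchor = dep, years = 5)
  expect_false(cal$at_bound)
  expect_equal(cal$fitted_value, v_true, tolerance = 5e-3)
  expect_lt(cal$residual, 1e-3)

  absurd <- calibrate_v0(p, anchor = 1e3, years = 5)
  expect_true(absurd$at_bound)
  expect_equal(absurd$fitted_value, 0.43) # fastest admissible flow
  expect_gt(absurd$residual, 1)

  td <- tidy(cal)
  expect_equal(td$parameter, "v0")
  expect_equal(td$fitted_value, cal$fitted_value)
})

test_that("exit-rate calibration recovers a known synthetic k_exit", {
  p <- default_params()
  k_true <- 0.2
  p_true <- update_params(p, k_exit = k_true)
  base <- run_simulation("normal_aging", years = 5, record_stride = 5 * 365,
                         params = p_true)
  apo <- run_simulation("apoe4", years = 5, record_stride = 5 * 365,
                        params = p_true)
  ratio <- endpoints(apo)[["C3"]] / endpoints(base)[["C3"]]
  cal <- calibrate_k_exit(p, anchor_ratio = ratio, years = 5)
  expect_false(cal$at_bound)
  expect_equal(cal$fitted_value, k_true, tolerance = 1e-2)
  expect_lt(cal$residual, 1e-3)
  expect_true(is.finite(cal$lrp_share) && cal$lrp_share > 0 && cal$lrp_share < 1)

  expect_error(calibrate_k_exit(p, anchor_ratio = 0.9),
               class = "glymphsim_invalid_parameter")
})

test_that("final parenchymal deposits fall strictly with heart rate", {
  deps <- vapply(c(40, 50, 60, 90, 120), function(hr) {
    traj <- run_simulation(scenario(paste0("hr", hr), heart_rate = hr),
                           years = 5, record_stride = 5 * 365)
    endpoints(traj)[["C9"]]
  }, numeric(1))
  expect_true(all(diff(deps) < 0))
})

test_that("trajectory CSV export round-trips at full precision with the fixed header", {
  traj <- run_simulation("normal_aging", years = 1, record_stride = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header, glymphsim:::TRAJ_COLS)
  back <- utils::read.csv(path)
  for (col in glymphsim:::TRAJ_COLS) {
    expect_equal(back[[col]], traj[[col]], tolerance = 1e-15)
  }
})

test_that("trajectory tidiers expose pools, endpoints and the ledger residual", {
  traj <- run_simulation("normal_aging", years = 1, record_stride = 73)
  long <- tidy(traj)
  expect_setequal(unique(long$pool), glymphsim:::pool_metadata()$pool)
  expect_equal(nrow(long), nrow(traj) * 12)

  g <- glance(traj)
  expect_equal(g$scenario, "normal_aging")
  expect_equal(g$parenchyma_Abeta40, endpoints(traj)[["C9"]])
  expect_lt(g$mass_balance_residual, 1e-9)

  expect_s3_class(autoplot(traj), "ggplot")
  expect_s3_class(plot_cell_pools(traj), "ggplot")
})
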