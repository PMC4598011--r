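test_that("pg/mL to molecule conversion matches hand arithmetic and is linear", {
  # 450 pg/mL in 1 mm^3 = 4.5e-13 g; / 4330 g/mol * 6.02214076e23 /mol
  expect_equal(pgml_to_molecules(450, 4330, 1), 6.258576e7,
               tolerance = 1e-6)
  expect_equal(pgml_to_molecules(70, 4514, 1), 9.338721e6,
               tolerance = 1e-6)
  expect_identical(pgml_to_molecules(0, 4330, 1), 0)

  withr::local_seed(101)
  for (i in 1:20) {
    conc <- runif(1, 0, 1000); mm <- runif(1, 1000, 9000)
    vol <- runif(1, 0.1, 10); a <- runif(1, 0.1, 5)
    expect_equal(pgml_to_molecules(a * conc, mm, vol),
                 a * pgml_to_molecules(conc, mm, vol))
    expect_equal(pgml_to_molecules(conc, mm, a * vol),
                 a * pgml_to_molecules(conc, mm, vol))
    expect_equal(pgml_to_molecules(conc, a * mm, vol),
                 pgml_to_molecules(conc, mm, vol) / a)
  }

  expect_error(pgml_to_molecules(10, -1, 1), class = "glymphsim_invalid_parameter")
  expect_error(pgml_to_molecules(10, 4330, 0), class = "glymphsim_invalid_parameter")
  expect_error(pgml_to_molecules(-1, 4330, 1), class = "glymphsim_invalid_parameter")
})

test_that("annual-to-daily compounding is exact and matches the closed form", {
  expect_identical(annual_to_daily(0), 0)
  expect_equal(annual_to_daily(0.01), 2.753478e-5, tolerance = 1e-6)
  expect_equal(annual_to_daily(0.034), 9.476659e-5, tolerance = 1e-6)

  # 365 daily steps recover the annual fraction
  for (r in seq(0, 0.5, by = 0.05)) {
    expect_equal((1 - annual_to_daily(r))^365, 1 - r, tolerance = 1e-12)
  }

  expect_error(annual_to_daily(1), class = "glymphsim_invalid_parameter")
  expect_error(annual_to_daily(-0.1), class = "glymphsim_invalid_parameter")
})

test_that("capillary lattice geometry reproduces the worked counts", {
  expect_identical(ec_per_capillary_length(8, 20, 100), 5L)
  expect_identical(ec_per_capillary_length(8, 100, 100), 1L)
  expect_identical(ec_per_capillary_length(8, 20, 1000), 50L)

  expect_identical(capillaries_per_edge(1000, 8, 40), 21L)
  expect_identical(capillaries_per_edge(48, 8, 40), 1L)
  expect_identical(capillaries_per_edge(1000, 10, 40), 20L)

  expect_error(ec_per_capillary_length(0, 20, 100),
               class = "glymphsim_invalid_parameter")
  expect_error(capillaries_per_edge(1000, 8, -1),
               class = "glymphsim_invalid_parameter")

  geom <- geometry_constants()
  expect_gt(geom$capillary_separation, geom$capillary_diameter)
  expect_error(geometry_constants(capillary_separation = 5),
               class = "glymphsim_invalid_parameter")
})

test_that("percent volume loss per year matches the MRI table", {
  tab <- percent_loss_per_year(hippocampal_volumes())
  expect_equal(round(tab$percent_per_year[tab$cohort == "healthy"], 1), -0.8)
  expect_equal(round(tab$percent_per_year[tab$cohort == "AD"], 1), -4.4)
  expect_equal(tab$percent_per_year[tab$cohort == "AD"], -4.414, tolerance = 1e-3)

  flat <- percent_loss_per_year(
    tibble::tibble(cohort = "x", baseline_volume = 1000, loss_rate = 0))
  expect_identical(flat$percent_per_year, 0)

  expect_error(percent_loss_per_year(
    tibble::tibble(baseline_volume = 0, loss_rate = -1)),
    class = "glymphsim_invalid_parameter")
})

test_that("default parameter presets carry the allele-specific transport rate", {
  e3 <- default_params("E3")
  e2 <- default_params("E2")
  e4 <- default_params("E4")
  expect_equal(e3$k6, 0.4)
  expect_equal(e2$k6, 0.4)
  expect_equal(e4$k6, 0.12)
  expect_equal(e3$k3, 16000)
  expect_equal(e3$k8, 3000)
  expect_equal(e3$k10, e3$k2)
  expect_equal(e3$EC0, 21^2 * 50) # lattice-derived endothelial pool
  expect_error(default_params("E5"), class = "glymphsim_invalid_parameter")

  # every preset passes its own invariants
  for (allele in c("E2", "E3", "E4")) {
    expect_silent(validate_params(default_params(allele)))
  }
})

test_that("parameter updates are fail-closed and keep k10 tied to k2", {
  p <- default_params()
  expect_error(update_params(p, k6_lrp = 0.2),
               class = "glymphsim_invalid_parameter")
  expect_error(update_params(p, 0.2), class = "glymphsim_invalid_parameter")

  p2 <- update_params(p, k2 = 0.017)
  expect_equal(p2$k10, 0.017)
  p3 <- update_params(p, k2 = 0.017, k10 = 0.001)
  expect_equal(p3$k10, 0.001)

  expect_error(update_params(p, v0 = 0.6), class = "glymphsim_invalid_parameter")
  expect_error(update_params(p, pvs_init_fraction = 0),
               class = "glymphsim_invalid_parameter")
  expect_error(update_params(p, k7 = -0.1), class = "glymphsim_invalid_parameter")

  td <- tidy(p)
  expect_true(all(c("parameter", "value") %in% names(td)))
  expect_equal(nrow(td), length(glymphsim:::PARAM_FIELDS))
})

test_that("endothelial senescence presets include the default and both literature rates", {
  tab <- ec_senescence_rates()
  expect_setequal(tab$preset, c("default", "no_stimulus", "stimulus"))
  expect_equal(tab$k2[tab$preset == "default"], 0.01)
  expect_equal(tab$k2[tab$preset == "no_stimulus"], 0.001)
  expect_equal(tab$k2[tab$preset == "stimulus"], 0.017)
})
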