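test_that("to_co2e converts gas fluxes linearly under the chosen metric", {
  g28 <- gwp_set(28, 265)
  expect_equal(to_co2e(gas_amount(co2 = 1), g28), 1)
  expect_equal(to_co2e(gas_amount(ch4 = 0.1), g28), 2.8)
  expect_equal(to_co2e(gas_amount(co2 = 2, ch4 = 0.1, n2o = 0.01), g28), 7.45)
  # doubling the CH4 factor doubles only the CH4 term
  expect_equal(to_co2e(gas_amount(ch4 = 0.1), gwp_set(56, 265)), 5.6)
})

test_that("to_co2e is additive over gas amounts", {
  set.seed(11)
  for (i in 1:25) {
    a <- gas_amount(rnorm(1), rnorm(1), rnorm(1))
    b <- gas_amount(rnorm(1), rnorm(1), rnorm(1))
    gwp <- gwp_set(runif(1, 1, 100), runif(1, 1, 400))
    expect_equal(to_co2e(a + b, gwp), to_co2e(a, gwp) + to_co2e(b, gwp))
  }
})

test_that("gas amounts and GWP sets reject invalid values", {
  expect_error(gas_amount(co2 = NaN), "co2")
  expect_error(gas_amount(ch4 = Inf), "ch4")
  expect_error(gwp_set(-1, 265), "ch4_factor")
  expect_error(gwp_set(28, 265, horizon_years = 0), "horizon")
})

test_that("area_times_rate carries Mha x Mg/ha to Tg with exact linearity", {
  expect_equal(area_times_rate(2.1, 1), 2.1)
  expect_equal(area_times_rate(88, 0.32 * 44 / 12), 103.2533, tolerance = 1e-6)
  expect_equal(round(area_times_rate(88, 0.32 * 44 / 12)), 103)
  expect_equal(area_times_rate(17.6 * 0.05, 5 / 0.88), 5)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0, 100); r <- runif(1, -5, 10); k <- runif(1, 0, 7)
    expect_equal(area_times_rate(k * a, r), k * area_times_rate(a, r),
                 tolerance = 1e-12)
  }
  expect_error(area_times_rate(-1, 2), "nonnegative")
  expect_equal(area_times_rate(2, -0.5), -1)  # negative rates are penalties
})

test_that("percent_of_reference reports unrounded and rounded forms", {
  expect_equal(percent_of_reference(5794.5, 5794.5)$percent, 100)
  p <- percent_of_reference(1203, 5794.5)
  expect_equal(p$percent, 20.76107, tolerance = 1e-6)
  expect_equal(p$percent_rounded, 21)
  p10 <- percent_of_reference(299, 1203)
  expect_equal(p10$percent, 24.854, tolerance = 1e-4)
  expect_equal(p10$percent_rounded, 25)
  expect_error(percent_of_reference(1, 0), "positive")
  expect_error(percent_of_reference(1, -5), "positive")
})

test_that("mitigation_estimate enforces CI bracketing and pool closure", {
  expect_error(mitigation_estimate("cover_crops", 10, ci = c(11, 12)),
               "bracket")
  expect_error(
    mitigation_estimate("cover_crops", 10,
                        by_pool = c(biomass = 4, soil = 4,
                                    avoided_ch4_n2o = 0)),
    "sums to")
  est <- mitigation_estimate("cover_crops", 10, ci = c(8, 14),
                             by_pool = c(biomass = 0, soil = 10,
                                         avoided_ch4_n2o = 0))
  expect_s3_class(est, "mitigation_estimate")
  expect_equal(sum(est$by_pool), est$mean)
})

test_that("a results table survives a CSV round trip bit-identically", {
  tab <- generate_parameter_table()
  rep <- report_table(tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(rep, path)
  back <- read_results_csv(path)
  expect_identical(back$maximum_tg, rep$maximum_tg)
  expect_identical(sum(back$maximum_tg), sum(rep$maximum_tg))
  expect_identical(back$cost10_tg, rep$cost10_tg)
  # and the pathway table itself round-trips through its own CSV format
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_pathway_table(tab, p2)
  tab2 <- read_pathway_table(p2)
  for (cl in c("mitigation_tg", "ci_low_tg", "ci_high_tg",
               "flux_mgco2e_ha_yr"))
    expect_identical(tab2[[cl]], tab[[cl]])
})
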