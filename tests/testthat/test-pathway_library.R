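test_that("reforestation eligibility matches exhaustive cell enumeration", {
  for (seed in c(2, 9, 31)) {
    g <- generate_landscape(synthetic_config(seed = seed, shape = c(25, 40)))
    expect_equal(reforestation_eligible_area(g), eligible_area_cell_oracle(g))
  }
})

test_that("reforestation eligibility honours masks and exclusions", {
  mk <- function(lc, tree, histosol = NULL) {
    landscape_grid(land_cover = lc, tree_cover = tree,
                   soil_c_1m = matrix(100, nrow(lc), ncol(lc)),
                   mat = matrix(10, nrow(lc), ncol(lc)),
                   map_mm = matrix(800, nrow(lc), ncol(lc)),
                   conifer_frac = matrix(0.5, nrow(lc), ncol(lc)),
                   masks = if (is.null(histosol)) list() else
                     list(histosol = histosol),
                   cell_area_ha = 100)
  }
  all_urban <- mk(matrix(match("urban", land_cover_classes()), 10, 10),
                  matrix(5, 10, 10))
  expect_equal(reforestation_eligible_area(all_urban), 0)

  # 37 low-cover forest cells among high-cover ones
  lc <- matrix(match("forest", land_cover_classes()), 10, 10)
  tree <- matrix(80, 10, 10)
  tree[seq_len(37)] <- 10
  g37 <- mk(lc, tree)
  expect_equal(reforestation_eligible_area(g37), 37 * 100 / 1e6)
  # masking 5 of the eligible cells as Histosol removes them
  hist <- matrix(FALSE, 10, 10)
  hist[seq_len(5)] <- TRUE
  expect_equal(reforestation_eligible_area(mk(lc, tree, hist)),
               32 * 100 / 1e6)
  # cropland is retained unless explicitly released
  lc_crop <- matrix(match("cropland", land_cover_classes()), 10, 10)
  g_crop <- mk(lc_crop, matrix(5, 10, 10))
  expect_equal(reforestation_eligible_area(g_crop), 0)
  expect_equal(reforestation_eligible_area(g_crop,
                                           released_cropland_mha = 0.002),
               0.002)
})

test_that("the conifer albedo discount scales reforestation benefit down", {
  plain <- reforestation_mitigation(10, 10)
  expect_equal(plain$mean, area_times_rate(10, 10))
  expect_equal(reforestation_mitigation(10, 10, conifer_frac = 0.5,
                                        albedo_discount = 0.2)$mean, 90)
  undiscounted <- reforestation_mitigation(51.2, 307 / 51.2)
  discounted <- reforestation_mitigation(51.2, 307 / 51.2,
                                         conifer_frac = 0.45,
                                         albedo_discount = 0.1)
  expect_equal(undiscounted$mean, 307)
  expect_lt(discounted$mean, 307)
  expect_error(reforestation_mitigation(1, 1, albedo_discount = 1.5),
               "albedo_discount")
})

test_that("fire benefit is negative without wildfire and maximal under full protection", {
  p0 <- fire_regime_params(10, 0.05, 20, 20, rx_emission = 8,
                           wildfire_annual_prob = 0, wildfire_emission = 100)
  # nothing to avoid: pay the mean annual prescribed-fire cost
  expect_equal(fire_management_benefit(p0), -mean(rep(0.05 * 10 * 8, 20)))
  pfull <- fire_regime_params(10, 1, 25, 20, rx_emission = 0,
                              wildfire_annual_prob = 1,
                              wildfire_emission = 50)
  expect_equal(fire_management_benefit(pfull), 10 * 50)
})

test_that("fire accrual equals the parcel-enumeration oracle", {
  set.seed(17)
  for (i in 1:12) {
    p <- fire_regime_params(
      treatable_area = runif(1, 1, 30),
      treat_frac_per_yr = sample(0:20, 1) / 20,
      protection_years = sample(1:25, 1),
      horizon = sample(1:30, 1),
      rx_emission = runif(1, 0, 20),
      wildfire_annual_prob = runif(1),
      wildfire_emission = runif(1, 0, 250))
    expect_equal(fire_management_benefit(p),
                 fire_benefit_parcel_oracle(p, n_parcels = 20L),
                 tolerance = 1e-10)
  }
})

test_that("fire stochastic mode is seed-deterministic and centred on the expectation", {
  p <- fire_regime_params(10.9, 0.05, 20, 20, rx_emission = 10,
                          wildfire_annual_prob = 0.02,
                          wildfire_emission = 200)
  s1 <- fire_management_benefit(p, stochastic = TRUE, seed = 5)
  expect_identical(s1, fire_management_benefit(p, stochastic = TRUE, seed = 5))
  reps <- vapply(1:200, function(s)
    fire_management_benefit(p, stochastic = TRUE, seed = s), numeric(1))
  expect_equal(mean(reps), fire_management_benefit(p), tolerance = 0.1)
})

test_that("avoided forest conversion excludes the soil pool", {
  expect_equal(avoided_forest_conversion(0.5, 0.4, 200)$mean, 40)
  expect_equal(avoided_forest_conversion(0.5, 0, 200)$mean, 0)
  est <- avoided_forest_conversion(0.7, 0.38, 150, conifer_frac = 0.5,
                                   albedo_discount = 0.1)
  expect_equal(unname(est$by_pool[["soil"]]), 0)
  expect_equal(est$mean, 0.7 * 0.38 * 150 * 0.95)
  expect_error(avoided_forest_conversion(1, 1.2, 100), "persistent_frac")
})

test_that("root biomass regression evaluates and clamps at zero", {
  expect_equal(root_biomass_from_climate(3, 100, c(5, 0, 0)), 5)
  expect_equal(root_biomass_from_climate(10, 500, c(1, 0.1, 0.001)), 2.5)
  expect_equal(root_biomass_from_climate(-40, 0, c(1, 0.5, 0)), 0)
  expect_error(root_biomass_from_climate(10, 500), "coefficients")
  # vectorised over a grid layer
  m <- root_biomass_from_climate(matrix(10, 2, 2), matrix(500, 2, 2),
                                 c(1, 0.1, 0.001))
  expect_equal(m, matrix(2.5, 2, 2))
})

test_that("grassland conversion reproduces the soil term and 81% soil share", {
  inp <- pathway_inputs()$avoided_grassland_conversion
  est <- avoided_grassland_conversion(inp$conv_area, inp$soil_stock,
                                      inp$soil_loss_frac, inp$root_c,
                                      inp$shrub_agb_c)
  per_ha <- attr(est, "per_ha")
  expect_equal(per_ha$soil, 125, tolerance = 1e-9)
  expect_equal(per_ha$soil_share, 0.81, tolerance = 0.005)
  expect_equal(est$mean, 107, tolerance = 1e-6)
  # spec example: a 121.9 Mg C/ha stock gives a ~125.1 soil term
  est2 <- avoided_grassland_conversion(1, 121.9, 0.28, 0, 0)
  expect_equal(attr(est2, "per_ha")$soil, 125.15, tolerance = 1e-4)
  expect_equal(avoided_grassland_conversion(0, 120, 0.28, 5)$mean, 0)
})

test_that("nutrient management reproduces the 22/33/29 cascade", {
  est <- nutrient_management(nutrient_params())
  red <- attr(est, "reductions")
  expect_equal(red$rate, 0.22)
  expect_equal(red$field, 0.33, tolerance = 1e-9)
  expect_equal(red$upstream, 0.22)
  expect_equal(red$combined, 0.29, tolerance = 1e-9)
  expect_equal(round(est$mean), 52)
  # a linear response gives only the 22% field cut -- the nonlinear
  # response is what produces the amplified 33%
  lin <- nutrient_management(nutrient_params(response = "linear"))
  expect_equal(attr(lin, "reductions")$field, 0.22)
  expect_lt(attr(lin, "reductions")$field, 0.33)
  zero <- nutrient_management(nutrient_params(rate_reduction = 0))
  expect_equal(zero$mean, 0)
  expect_error(nutrient_params(response = "exponential",
                               response_exponent = "x"), "exponent")
})

test_that("biochar mitigation is a permanence-weighted chain product", {
  expect_equal(biochar_mitigation(biochar_params(100, 0.3, 0.7, 0.796))$mean,
               100 * 0.3 * 0.7 * 0.796 * 44 / 12)
  expect_equal(biochar_mitigation(biochar_params(100, 0.3, 0.7, 0))$mean, 0)
  est <- biochar_mitigation(biochar_params(155, 0.3, 0.7, 0.796))
  expect_equal(est$by_gas$ch4, 0)
  expect_equal(est$by_gas$n2o, 0)
  expect_equal(unname(est$by_pool[["soil"]]), est$mean)
  expect_error(biochar_params(10, char_yield = 1.2), "fractions")
})

test_that("tidal wetland restoration converts avoided CH4 via the GWP set", {
  inp <- pathway_inputs()$tidal_wetland_restoration
  est <- tidal_wetland_restoration(inp$marsh_area, inp$freshened_frac,
                                   inp$ch4_avoided)
  expect_equal(est$mean, 12, tolerance = 1e-9)
  expect_equal(unname(est$by_pool[["avoided_ch4_n2o"]]), est$mean)
  expect_equal(tidal_wetland_restoration(1.7, 0, 0.5)$mean, 0)
  # linear in the CH4 factor
  doubled <- tidal_wetland_restoration(inp$marsh_area, inp$freshened_frac,
                                       inp$ch4_avoided,
                                       gwp = gwp_set(90, 270, 100, "SGWP"))
  expect_equal(doubled$mean, 2 * est$mean)
})

test_that("seagrass pathways follow their loss/restoration arithmetic", {
  expect_equal(seagrass_avoided_loss(1, 0.015, 100, 0.5)$mean, 2.75)
  expect_equal(seagrass_avoided_loss(1, 0.015, 100, 0)$mean, 0)
  expect_equal(seagrass_avoided_loss(1, 0.0075, 100, 0.5)$mean, 2.75 / 2)
  est <- seagrass_restoration(1, 1, restorable_frac = 0.29)
  expect_equal(est$mean, 0.29 * 44 / 12)
  mid <- seagrass_restoration(1, 1)
  expect_lt(mid$ci[["low"]], mid$mean)
  expect_gt(mid$ci[["high"]], mid$mean)
  expect_equal(unname(mid$ci[["low"]]), 0.29 * 44 / 12)
  expect_equal(unname(mid$ci[["high"]]), 0.52 * 44 / 12)
  expect_equal(seagrass_restoration(1, 1, restorable_frac = 0,
                                    frac_interval = c(0, 0))$mean, 0)
})

test_that("rotation extension finds the biological rotation and never loses", {
  inp <- pathway_inputs()$improved_plantations
  p <- rotation_params(inp$growth_curve, inp$econ_rotation, inp$area)
  est <- rotation_extension_gain(p)
  rot <- attr(est, "rotation")
  expect_equal(rot$t_bio, 35)
  expect_equal(est$mean,
               rotation_gain_scan_oracle(inp$growth_curve,
                                         inp$econ_rotation, inp$area))
  # harvesting at the biological optimum already -> no gain
  p_bio <- rotation_params(inp$growth_curve, rot$t_bio, inp$area)
  expect_equal(rotation_extension_gain(p_bio)$mean, 0)
  # earlier economic harvest never decreases the gain
  gains <- vapply(c(10, 15, 20, 25, 30), function(t_econ)
    rotation_extension_gain(
      rotation_params(inp$growth_curve, t_econ, inp$area))$mean, numeric(1))
  expect_true(all(diff(gains) <= 1e-9))
  expect_error(rotation_params(inp$growth_curve, 80, 1), "beyond")
})

test_that("scalar pathways delegate to area_times_rate with table metadata", {
  expect_equal(scalar_pathway("grassland_restoration", 2.1, 0)$mean, 0)
  expect_equal(scalar_pathway("peatland_restoration", 1, 8.2)$mean, 8.2)
  wb <- scalar_pathway("windbreaks", 17.6 * 0.05, 5 / 0.88)
  expect_equal(wb$mean, 5)
  expect_true(all(attr(wb, "cobenefits") %in%
                    c("air", "biodiversity", "soil", "water")))
  expect_equal(sum(wb$by_pool), wb$mean)
  expect_error(scalar_pathway("afforestation", 1, 1), "valid ids")
})

test_that("every pathway estimator is degree-1 homogeneous in extent", {
  inp <- pathway_inputs()
  k <- 3.7
  builders <- list(
    function(s) reforestation_mitigation(s * 10, 7, 0.3, 0.1)$mean,
    function(s) avoided_forest_conversion(s * 0.5, 0.4, 180, 0.2, 0.1)$mean,
    function(s) avoided_grassland_conversion(s * 0.7, 120, 0.28, 7)$mean,
    function(s) fire_management_benefit(
      fire_regime_params(s * 10, 0.05, 20, 20, 10, 0.02, 200)),
    function(s) biochar_mitigation(biochar_params(s * 100))$mean,
    function(s) tidal_wetland_restoration(s * 1.7, 0.27, 0.6)$mean,
    function(s) seagrass_avoided_loss(s * 1, 0.015, 80)$mean,
    function(s) seagrass_restoration(s * 1, 1.2)$mean,
    function(s) rotation_extension_gain(rotation_params(
      inp$improved_plantations$growth_curve, 25, s * 5))$mean,
    function(s) scalar_pathway("cover_crops", s * 88, 1.17)$mean
  )
  for (f in builders) expect_equal(f(k), k * f(1), tolerance = 1e-12)
})
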