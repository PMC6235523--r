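#' Reforestation: eligible area on a landscape
#'
#' Sums cell area over cells that could be returned to forest: tree cover
#' below the forest threshold, a land-cover class whose native cover is
#' forest, and no exclusion mask set (intensive development, major roads,
#' impervious surfaces, Histosols -- the last to avoid double counting with
#' peatland restoration). Cropland and pasture are retained for food
#' production by default; a caller-specified released area (e.g. expiring
#' conservation-program cropland) can be added back, taken in row-major
#' order from otherwise-qualifying cropland/pasture cells.
#'
#' @param grid a [landscape_grid()].
#' @param tree_cover_threshold percent; cells at or above it already count
#'   as forest (default 25).
#' @param native_classes land-cover classes treated as natively forested
#'   (default `c("forest", "shrubland")`).
#' @param released_cropland_mha cropland/pasture area (Mha) released for
#'   reforestation (default 0 = retain all).
#' @return Eligible area in Mha.
#' @export
reforestation_eligible_area <- function(grid, tree_cover_threshold = 25,
                                        native_classes = c("forest",
                                                           "shrubland"),
                                        released_cropland_mha = 0) {
  stopifnot(inherits(grid, "landscape_grid"))
  for (nm in c("tree_cover", "land_cover"))
    if (is.null(grid[[nm]])) stop(sprintf("grid lacks required layer '%s'", nm))
  cls <- match(native_classes, land_cover_classes())
  if (anyNA(cls)) stop("unknown land-cover class in 'native_classes'")
  excluded <- grid$masks$urban | grid$masks$impervious |
    grid$masks$major_road | grid$masks$histosol
  open <- grid$tree_cover < tree_cover_threshold & !excluded
  eligible <- open & matrix(grid$land_cover %in% cls, nrow(grid$land_cover))
  area_mha <- sum(eligible) * grid$cell_area_ha / 1e6
  if (released_cropland_mha > 0) {
    ag <- match(c("cropland", "pasture"), land_cover_classes())
    candidates <- which(t(open & matrix(grid$land_cover %in% ag,
                                        nrow(grid$land_cover)))) # row-major
    n_release <- min(length(candidates),
                     floor(released_cropland_mha * 1e6 / grid$cell_area_ha))
    area_mha <- area_mha + n_release * grid$cell_area_ha / 1e6
  }
  area_mha
}

#' Reforestation: mitigation with a conifer albedo discount
#'
#' `area * seq_rate * (1 - conifer_frac * albedo_discount)`. Planted conifer
#' canopies darken snow-covered land, offsetting part of the carbon benefit;
#' the discount scales with the conifer-dominated fraction of the area.
#' The default discount is 0 (off).
#'
#' @param area Mha.
#' @param seq_rate Mg CO2e ha^-1 yr^-1.
#' @param conifer_frac fraction of the area that is conifer-dominated.
#' @param albedo_discount fraction of the benefit foregone on
#'   conifer-dominated area; must be in \[0, 1\].
#' @param pool_split named fractions over biomass/soil/avoided_ch4_n2o
#'   (default all biomass).
#' @param ci_rel optional `(low, high)` relative CI bounds as fractions of
#'   the mean; default degenerate.
#' @return A [mitigation_estimate()].
#' @export
#' @examples
#' reforestation_mitigation(10, 10, conifer_frac = 0.5, albedo_discount = 0.2)
reforestation_mitigation <- function(area, seq_rate, conifer_frac = 0,
                                     albedo_discount = 0,
                                     pool_split = c(biomass = 1, soil = 0,
                                                    avoided_ch4_n2o = 0),
                                     ci_rel = c(1, 1)) {
  if (!is.finite(albedo_discount) || albedo_discount < 0 || albedo_discount > 1)
    stop("'albedo_discount' must be in [0, 1]")
  if (!is.finite(conifer_frac) || conifer_frac < 0 || conifer_frac > 1)
    stop("'conifer_frac' must be in [0, 1]")
  m <- area_times_rate(area, seq_rate) * (1 - conifer_frac * albedo_discount)
  mitigation_estimate("reforestation", m, ci = m * ci_rel,
                      by_pool = pool_split * m)
}

#' Fire management parameters
#'
#' @param treatable_area Mha of fire-prone forest eligible for prescribed
#'   fire treatment.
#' @param treat_frac_per_yr fraction of the treatable area newly treated
#'   each year (default 0.05).
#' @param protection_years years a treatment eliminates wildfire risk on
#'   the treated land (default 20).
#' @param horizon accounting horizon in years (default 20); the benefit is
#'   reported as the average annual value over this horizon.
#' @param rx_emission Mg CO2e ha^-1 emitted by one prescribed-fire
#'   treatment.
#' @param wildfire_annual_prob annual probability that untreated land
#'   burns.
#' @param wildfire_emission Mg CO2e ha^-1 from a wildfire (combustion plus
#'   foregone net ecosystem production).
#' @return An object of class `fire_regime_params`.
#' @export
fire_regime_params <- function(treatable_area, treat_frac_per_yr = 0.05,
                               protection_years = 20L, horizon = 20L,
                               rx_emission = 10, wildfire_annual_prob = 0.02,
                               wildfire_emission = 120) {
  stopifnot(treatable_area >= 0,
            treat_frac_per_yr >= 0, treat_frac_per_yr <= 1,
            protection_years >= 1, horizon >= 1,
            rx_emission >= 0,
            wildfire_annual_prob >= 0, wildfire_annual_prob <= 1,
            wildfire_emission >= 0)
  structure(list(treatable_area = treatable_area,
                 treat_frac_per_yr = treat_frac_per_yr,
                 protection_years = as.integer(protection_years),
                 horizon = as.integer(horizon),
                 rx_emission = rx_emission,
                 wildfire_annual_prob = wildfire_annual_prob,
                 wildfire_emission = wildfire_emission),
            class = "fire_regime_params")
}

#' Fire management: average annual benefit of prescribed fire
#'
#' Year-by-year expected-value simulation over the horizon. Each year a
#' fixed fraction of the treatable area is newly treated (prioritising
#' unprotected land, and never exceeding what is unprotected), emitting the
#' prescribed-fire cost on the newly treated hectares. Land treated within
#' the protection window cannot burn; all other land burns with the annual
#' wildfire probability. The annual benefit is avoided wildfire emissions
#' minus prescribed-fire emissions; the return value is the mean over the
#' horizon, in Tg CO2e yr^-1. Early years are net-negative (treatment costs
#' up front); under default parameters the avoided wildfire impacts more
#' than offset them over the horizon.
#'
#' A seedable stochastic mode (`stochastic = TRUE`) replaces the expected
#' burned fraction with per-parcel Bernoulli ignition on `n_parcels`
#' equal-area parcels, for simulation cross-checks.
#'
#' @param p a [fire_regime_params()].
#' @param stochastic sample ignition instead of using expected values.
#' @param seed,n_parcels RNG seed and discretisation for the stochastic
#'   mode.
#' @return Average annual benefit, Tg CO2e yr^-1 (negative if treatment
#'   emissions exceed avoided emissions).
#' @export
fire_management_benefit <- function(p, stochastic = FALSE, seed = 1L,
                                    n_parcels = 1000L) {
  stopifnot(inherits(p, "fire_regime_params"))
  if (p$horizon < 1L) stop("'horizon' must be at least 1 year")
  A <- p$treatable_area
  treated <- numeric(p$horizon)        # area newly treated in each year
  benefit <- numeric(p$horizon)
  if (stochastic) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  for (t in seq_len(p$horizon)) {
    # cohorts treated in year s protect years s .. s + protection_years - 1
    window <- seq_len(t - 1L)
    window <- window[window >= t - p$protection_years + 1L]
    active_prior <- sum(treated[window])
    treated[t] <- min(p$treat_frac_per_yr * A, A - active_prior)
    protected <- active_prior + treated[t]
    # benefit = what would have burned on protected land, minus rx cost
    avoided <- if (stochastic) {
      n_prot <- round(protected / A * n_parcels)
      stats::rbinom(1, n_prot, p$wildfire_annual_prob) *
        (A / n_parcels) * p$wildfire_emission
    } else {
      protected * p$wildfire_annual_prob * p$wildfire_emission
    }
    benefit[t] <- avoided - treated[t] * p$rx_emission
  }
  mean(benefit)
}

#' Avoided forest conversion
#'
#' Mitigation from preventing the persistently converted share of annual
#' forest clearing from releasing its committed biomass emissions:
#' `clearing_rate * persistent_frac * committed_emission`, with the same
#' conifer albedo discount as reforestation. The soil carbon pool is
#' excluded (evidence on soil carbon response to forest conversion is
#' conflicting), so the estimate is all biomass.
#'
#' @param clearing_rate Mha yr^-1 of gross forest clearing.
#' @param persistent_frac fraction of clearing converted to another land
#'   use (rather than regenerating), in \[0, 1\].
#' @param committed_emission Mg CO2e ha^-1 of committed above- and
#'   belowground biomass emissions.
#' @inheritParams reforestation_mitigation
#' @return A [mitigation_estimate()] with `by_pool["soil"] == 0`.
#' @export
avoided_forest_conversion <- function(clearing_rate, persistent_frac,
                                      committed_emission, conifer_frac = 0,
                                      albedo_discount = 0, ci_rel = c(1, 1)) {
  if (persistent_frac < 0 || persistent_frac > 1)
    stop("'persistent_frac' must be in [0, 1]")
  if (albedo_discount < 0 || albedo_discount > 1)
    stop("'albedo_discount' must be in [0, 1]")
  m <- area_times_rate(clearing_rate * persistent_frac, committed_emission) *
    (1 - conifer_frac * albedo_discount)
  mitigation_estimate("avoided_forest_conversion", m, ci = m * ci_rel,
                      by_pool = c(biomass = m, soil = 0, avoided_ch4_n2o = 0))
}

#' Grassland root biomass from climate normals
#'
#' Evaluates a configured two-predictor regression of root biomass carbon
#' on mean annual temperature and precipitation, clamped at 0. The
#' coefficient vector is supplied by the caller (the functional form is the
#' contract; coefficients are interchangeable).
#'
#' @param mat mean annual temperature, deg C (vector or matrix).
#' @param map_mm mean annual precipitation, mm yr^-1, >= 0.
#' @param coefficients numeric `(intercept, per-degree, per-mm)`.
#' @return Root biomass carbon, Mg C ha^-1 (same shape as the inputs).
#' @export
#' @examples
#' root_biomass_from_climate(10, 500, c(1, 0.1, 0.001))  # 2.5
root_biomass_from_climate <- function(mat, map_mm, coefficients) {
  if (missing(coefficients) || is.null(coefficients) ||
      length(coefficients) != 3L)
    stop("'coefficients' must supply (intercept, mat, map) values")
  if (any(map_mm < 0)) stop("'map_mm' must be >= 0")
  pred <- coefficients[1] + coefficients[2] * mat + coefficients[3] * map_mm
  pmax(pred, 0)
}

#' Avoided grassland conversion
#'
#' Emissions avoided by preventing grassland/shrubland conversion to
#' cropland. Conversion releases a fixed fraction of the soil carbon stock
#' to 1 m (default 28%) plus root and shrub aboveground biomass carbon;
#' the per-hectare emission is the carbon sum times 44/12.
#'
#' @param conv_area Mha yr^-1 of avoided conversion.
#' @param soil_stock Mg C ha^-1 to 1 m.
#' @param soil_loss_frac fraction of the soil stock lost on conversion
#'   (default 0.28).
#' @param root_c root biomass carbon, Mg C ha^-1.
#' @param shrub_agb_c shrub aboveground biomass carbon, Mg C ha^-1.
#' @param ci_rel optional relative CI bounds.
#' @return A [mitigation_estimate()]; its `per_ha` attribute holds the
#'   per-hectare decomposition (`soil`, `biomass`, `total` in Mg CO2e
#'   ha^-1 and the `soil_share`).
#' @export
avoided_grassland_conversion <- function(conv_area, soil_stock,
                                         soil_loss_frac = 0.28, root_c,
                                         shrub_agb_c = 0, ci_rel = c(1, 1)) {
  stopifnot(soil_stock >= 0, root_c >= 0, shrub_agb_c >= 0)
  if (soil_loss_frac < 0 || soil_loss_frac > 1)
    stop("'soil_loss_frac' must be in [0, 1]")
  soil_ha <- soil_stock * soil_loss_frac * C_TO_CO2
  biomass_ha <- (root_c + shrub_agb_c) * C_TO_CO2
  total_ha <- soil_ha + biomass_ha
  m <- area_times_rate(conv_area, total_ha)
  est <- mitigation_estimate(
    "avoided_grassland_conversion", m, ci = m * ci_rel,
    by_pool = c(biomass = conv_area * biomass_ha,
                soil = conv_area * soil_ha, avoided_ch4_n2o = 0))
  attr(est, "per_ha") <- list(
    soil = soil_ha, biomass = biomass_ha, total = total_ha,
    soil_share = if (total_ha > 0) soil_ha / total_ha else NA_real_)
  est
}

#' Cropland nutrient management parameters
#'
#' @param n_base Tg N yr^-1 currently applied.
#' @param bau_growth business-as-usual fractional growth in fertilizer use
#'   to the target year (default 0.046).
#' @param rate_reduction achievable fractional reduction in nitrogen use
#'   (default 0.22).
#' @param field_emission_base Tg CO2e yr^-1 of field N2O emissions at the
#'   current application rate.
#' @param upstream_emission_base Tg CO2e yr^-1 of fertilizer-manufacture
#'   emissions at the current rate.
#' @param response field-emission response to the application rate:
#'   `"exponential"` (emissions proportional to rate^k; the default) or
#'   `"linear"`.
#' @param response_exponent exponent k for the exponential response; if
#'   `NULL`, calibrated with [nutrient_response_exponent()] so the default
#'   22% rate reduction yields a 33% field-emission reduction.
#' @return An object of class `nutrient_params`.
#' @export
nutrient_params <- function(n_base = 12, bau_growth = 0.046,
                            rate_reduction = 0.22,
                            field_emission_base = 52 / (1.046 * 0.29) * 7 / 11,
                            upstream_emission_base = 52 / (1.046 * 0.29) * 4 / 11,
                            response = c("exponential", "linear"),
                            response_exponent = NULL) {
  response <- match.arg(response)
  if (rate_reduction < 0 || rate_reduction >= 1)
    stop("'rate_reduction' must be in [0, 1)")
  stopifnot(field_emission_base >= 0, upstream_emission_base >= 0,
            n_base >= 0)
  if (response == "exponential" && is.null(response_exponent))
    response_exponent <- nutrient_response_exponent()
  if (response == "exponential" && !is.numeric(response_exponent))
    stop("exponential response requires a numeric 'response_exponent'")
  structure(list(n_base = n_base, bau_growth = bau_growth,
                 rate_reduction = rate_reduction,
                 field_emission_base = field_emission_base,
                 upstream_emission_base = upstream_emission_base,
                 response = response,
                 response_exponent = response_exponent),
            class = "nutrient_params")
}

#' Calibrate the field-emission response exponent
#'
#' Field N2O emissions respond more than proportionally to the nitrogen
#' application rate. With an exponential response
#' `emissions ~ rate^k`, the exponent is the root of
#' `1 - (1 - rate_reduction)^k = field_reduction`, solved deterministically
#' to 1e-10 (defaults: a 22% rate cut producing a 33% field-emission cut,
#' giving k ~= 1.612).
#'
#' @param rate_reduction fractional nitrogen-rate reduction.
#' @param field_reduction fractional field-emission reduction it must
#'   produce.
#' @return The exponent k.
#' @export
nutrient_response_exponent <- function(rate_reduction = 0.22,
                                       field_reduction = 0.33) {
  stats::uniroot(function(k) (1 - (1 - rate_reduction)^k) - field_reduction,
                 interval = c(1e-6, 50), tol = 1e-10)$root
}

#' Cropland nutrient management
#'
#' Grows the baseline emissions by the BAU fertilizer-use growth, applies
#' the nitrogen rate reduction, and converts it to emission reductions:
#' field N2O falls by the response-function fraction (33% for the default
#' calibration), upstream manufacture emissions fall proportionally to
#' nitrogen (22%), and the combined reduction is the emission-weighted
#' mean of the two (29% with the default 7:4 field:upstream base ratio).
#'
#' @param p a [nutrient_params()].
#' @return A [mitigation_estimate()]; its `reductions` attribute holds the
#'   `rate`, `field`, `upstream` and `combined` fractional reductions.
#' @export
nutrient_management <- function(p) {
  stopifnot(inherits(p, "nutrient_params"))
  field_red <- switch(p$response,
    linear = p$rate_reduction,
    exponential = 1 - (1 - p$rate_reduction)^p$response_exponent)
  upstream_red <- p$rate_reduction
  growth <- 1 + p$bau_growth
  field_bau <- p$field_emission_base * growth
  upstream_bau <- p$upstream_emission_base * growth
  total_bau <- field_bau + upstream_bau
  combined <- if (total_bau > 0)
    (field_bau * field_red + upstream_bau * upstream_red) / total_bau else 0
  m <- field_bau * field_red + upstream_bau * upstream_red
  est <- mitigation_estimate(
    "cropland_nutrient_management", m,
    by_pool = c(biomass = 0, soil = 0, avoided_ch4_n2o = m))
  # field reductions are N2O, upstream are fossil CO2; the gas ledger is
  # kept in CO2e per gas
  est$by_gas <- structure(list(co2 = upstream_bau * upstream_red,
                               ch4 = 0, n2o = field_bau * field_red),
                          class = "gas_amount")
  attr(est, "reductions") <- list(rate = p$rate_reduction, field = field_red,
                                  upstream = upstream_red,
                                  combined = combined)
  est
}

#' Biochar parameters and mitigation
#'
#' Biochar converts sustainably harvestable crop residue to recalcitrant
#' carbon: `residue_mass * char_yield * char_c_frac * permanence * 44/12`
#' Tg CO2e yr^-1. Biochar is assumed to have no effect on N2O or CH4
#' emissions, so the gas ledger is CO2-only and the pool is all soil.
#'
#' @param residue_mass Tg dry residue yr^-1.
#' @param char_yield char mass per unit residue mass, in \[0, 1\].
#' @param char_c_frac carbon fraction of the char, in \[0, 1\].
#' @param permanence fraction of char carbon persisting > 100 years
#'   (default 0.796).
#' @return `biochar_params()` returns a parameter object;
#'   `biochar_mitigation()` a [mitigation_estimate()].
#' @export
biochar_params <- function(residue_mass, char_yield = 0.3,
                           char_c_frac = 0.7, permanence = 0.796) {
  stopifnot(residue_mass >= 0)
  for (f in c(char_yield, char_c_frac, permanence))
    if (f < 0 || f > 1) stop("biochar fractions must be in [0, 1]")
  structure(list(residue_mass = residue_mass, char_yield = char_yield,
                 char_c_frac = char_c_frac, permanence = permanence),
            class = "biochar_params")
}

#' @rdname biochar_params
#' @param p a `biochar_params` object.
#' @param ci_rel optional relative CI bounds.
#' @export
biochar_mitigation <- function(p, ci_rel = c(1, 1)) {
  stopifnot(inherits(p, "biochar_params"))
  m <- p$residue_mass * p$char_yield * p$char_c_frac * p$permanence * C_TO_CO2
  mitigation_estimate("biochar", m, ci = m * ci_rel,
                      by_pool = c(biomass = 0, soil = m, avoided_ch4_n2o = 0))
}

#' Tidal wetland restoration
#'
#' Salt marshes cut off from tidal exchange freshen and emit CH4;
#' reconnecting them avoids that flux. Mitigation is
#' `marsh_area * freshened_frac * ch4_avoided` (Tg CH4 yr^-1) converted to
#' CO2e -- by default under the sustained-flux metric ([gwp_sgwp()]), since
#' the avoided flux is ongoing. The pool is entirely avoided CH4/N2O.
#'
#' @param marsh_area total salt-marsh extent, Mha.
#' @param freshened_frac fraction disconnected from the ocean
#'   (default 0.27).
#' @param ch4_avoided Mg CH4 ha^-1 yr^-1 avoided on reconnected marsh.
#' @param gwp a [gwp_set()] (default [gwp_sgwp()]).
#' @param ci_rel optional relative CI bounds.
#' @return A [mitigation_estimate()].
#' @export
tidal_wetland_restoration <- function(marsh_area, freshened_frac = 0.27,
                                      ch4_avoided, gwp = gwp_sgwp(),
                                      ci_rel = c(1, 1)) {
  if (freshened_frac < 0 || freshened_frac > 1)
    stop("'freshened_frac' must be in [0, 1]")
  stopifnot(marsh_area >= 0, ch4_avoided >= 0)
  ch4_tg <- marsh_area * freshened_frac * ch4_avoided
  m <- to_co2e(gas_amount(ch4 = ch4_tg), gwp)
  est <- mitigation_estimate(
    "tidal_wetland_restoration", m, ci = m * ci_rel,
    by_pool = c(biomass = 0, soil = 0, avoided_ch4_n2o = m))
  est$by_gas <- structure(list(co2 = 0, ch4 = m, n2o = 0),
                          class = "gas_amount")
  attr(est, "gwp") <- gwp
  est
}

#' Avoided seagrass loss
#'
#' A fixed fraction of seagrass extent is lost annually; half of the carbon
#' in the biomass and sediment of disappearing beds reaches the atmosphere.
#' Mitigation from halting the loss:
#' `extent * loss_rate * stock_c * release_frac * 44/12`.
#'
#' @param extent current seagrass extent, Mha.
#' @param loss_rate fraction lost per year (default 0.015).
#' @param stock_c biomass + sediment carbon, Mg C ha^-1.
#' @param release_frac fraction of the stock released to the atmosphere on
#'   loss (default 0.5).
#' @param pool_split named fractions over the pools (default 30% biomass,
#'   70% soil/sediment).
#' @param ci_rel optional relative CI bounds.
#' @return A [mitigation_estimate()].
#' @export
seagrass_avoided_loss <- function(extent, loss_rate = 0.015, stock_c,
                                  release_frac = 0.5,
                                  pool_split = c(biomass = 0.3, soil = 0.7,
                                                 avoided_ch4_n2o = 0),
                                  ci_rel = c(1, 1)) {
  for (f in c(loss_rate, release_frac))
    if (f < 0 || f > 1) stop("rates/fractions must be in [0, 1]")
  stopifnot(extent >= 0, stock_c >= 0)
  m <- extent * loss_rate * stock_c * release_frac * C_TO_CO2
  mitigation_estimate("avoided_seagrass_loss", m, ci = m * ci_rel,
                      by_pool = pool_split * m)
}

#' Seagrass restoration
#'
#' Sequestration from restoring the share of historic seagrass extent that
#' has been lost and is restorable -- estimated as 29 to 52%, which supplies
#' the CI; the central estimate uses the interval midpoint unless a
#' fraction is given.
#'
#' @param historic_extent Mha of historic seagrass extent.
#' @param seq_rate sediment sequestration rate, Mg C ha^-1 yr^-1.
#' @param restorable_frac central restorable fraction (default: midpoint of
#'   `frac_interval`).
#' @param frac_interval `(low, high)` restorable-fraction interval
#'   (default `c(0.29, 0.52)`).
#' @return A [mitigation_estimate()] whose CI comes from the interval
#'   endpoints.
#' @export
seagrass_restoration <- function(historic_extent, seq_rate,
                                 restorable_frac = NULL,
                                 frac_interval = c(0.29, 0.52)) {
  stopifnot(historic_extent >= 0, seq_rate >= 0,
            length(frac_interval) == 2L, frac_interval[1] <= frac_interval[2],
            all(frac_interval >= 0), all(frac_interval <= 1))
  if (is.null(restorable_frac))
    restorable_frac <- mean(frac_interval)
  if (restorable_frac < 0 || restorable_frac > 1)
    stop("'restorable_frac' must be in [0, 1]")
  per_frac <- historic_extent * seq_rate * C_TO_CO2
  m <- per_frac * restorable_frac
  ci <- range(per_frac * frac_interval, m)
  mitigation_estimate("seagrass_restoration", m, ci = ci,
                      by_pool = c(biomass = 0, soil = m, avoided_ch4_n2o = 0))
}

#' Plantation rotation parameters
#'
#' @param growth_curve data.frame with strictly increasing `age` (years)
#'   and nonnegative `stand_c` (Mg C ha^-1).
#' @param econ_rotation current economically optimal rotation age, years.
#' @param area plantation area, Mha.
#' @return An object of class `rotation_params`.
#' @export
rotation_params <- function(growth_curve, econ_rotation, area) {
  stopifnot(is.data.frame(growth_curve),
            all(c("age", "stand_c") %in% names(growth_curve)),
            nrow(growth_curve) >= 2L, area >= 0)
  if (any(diff(growth_curve$age) <= 0))
    stop("growth-curve ages must be strictly increasing")
  if (any(growth_curve$stand_c < 0) || any(growth_curve$age <= 0))
    stop("growth curve must have positive ages and nonnegative carbon")
  if (econ_rotation > max(growth_curve$age) ||
      econ_rotation < min(growth_curve$age))
    stop("economic rotation lies beyond the tabulated growth curve")
  structure(list(growth_curve = growth_curve,
                 econ_rotation = econ_rotation, area = area),
            class = "rotation_params")
}

#' Improved plantations: gain from extending rotations
#'
#' The biological rotation age maximises mean annual increment
#' (stand carbon / age) over the tabulated curve; the annualised gain from
#' moving the harvest age there from the economic rotation is
#' `area * (C(t_bio)/t_bio - C(t_econ)/t_econ) * 44/12`, floored at 0
#' (extending rotations can only defer, never destroy, growth under this
#' accounting).
#'
#' @param p a [rotation_params()].
#' @return A [mitigation_estimate()]; attribute `rotation` holds
#'   `t_econ`, `t_bio` and the two mean annual increments.
#' @export
rotation_extension_gain <- function(p) {
  stopifnot(inherits(p, "rotation_params"))
  gc <- p$growth_curve
  mai <- gc$stand_c / gc$age
  t_bio <- gc$age[which.max(mai)]
  c_econ <- stats::approx(gc$age, gc$stand_c, xout = p$econ_rotation)$y
  mai_econ <- c_econ / p$econ_rotation
  gain_ha <- max(max(mai) - mai_econ, 0) * C_TO_CO2
  m <- area_times_rate(p$area, gain_ha)
  est <- mitigation_estimate(
    "improved_plantations", m,
    by_pool = c(biomass = m, soil = 0, avoided_ch4_n2o = 0))
  attr(est, "rotation") <- list(t_econ = p$econ_rotation, t_bio = t_bio,
                                mai_econ = mai_econ, mai_bio = max(mai))
  est
}

#' Scalar area-times-rate pathways
#'
#' The remaining pathways reduce to a single extent-times-rate product
#' (natural forest management under a harvest-hiatus scenario, urban
#' reforestation, cover crops, alley cropping, windbreaks, grazing
#' optimization, grassland restoration, legumes in pastures, improved rice
#' and manure management, peatland restoration). The pathway's pool split
#' and co-benefit tags are attached from the configuration table.
#'
#' @param id one of [pathway_ids()].
#' @param extent Mha.
#' @param rate Mg CO2e ha^-1 yr^-1.
#' @param config a pathway table supplying `frac_*` and `cobenefits` for
#'   `id` (default: the fixture table from [generate_parameter_table()]).
#' @param ci_rel optional relative CI bounds.
#' @return A [mitigation_estimate()] with a `cobenefits` attribute.
#' @export
#' @examples
#' scalar_pathway("peatland_restoration", 1, 8.2)
scalar_pathway <- function(id, extent, rate,
                           config = generate_parameter_table(),
                           ci_rel = c(1, 1)) {
  if (!id %in% pathway_ids())
    stop(sprintf("unknown pathway id '%s'; valid ids are: %s",
                 id, paste(pathway_ids(), collapse = ", ")))
  m <- area_times_rate(extent, rate)
  row <- config[config$id == id, ]
  split <- if (nrow(row) == 1L)
    c(biomass = row$frac_biomass, soil = row$frac_soil,
      avoided_ch4_n2o = row$frac_avoided)
  else c(biomass = 1, soil = 0, avoided_ch4_n2o = 0)
  est <- mitigation_estimate(id, m, ci = m * ci_rel, by_pool = split * m)
  attr(est, "cobenefits") <- if (nrow(row) == 1L)
    parse_cobenefits(row$cobenefits) else character()
  est
}
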