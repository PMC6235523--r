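#' Configuration for the synthetic-data generators
#'
#' Defines the toy study conditions: grid geometry, land-cover class
#' probabilities, the soil-carbon distribution, climate gradients, mask
#' probabilities, per-class annual conversion rates, and the noise level
#' used by the random parameter-table mode. One seed fixes every generated
#' object bit-for-bit.
#'
#' @param seed integer RNG seed.
#' @param shape `(rows, cols)` of the grid (default 100 x 100).
#' @param cell_area_ha hectares per cell (default 100, i.e. a 1 Mha toy
#'   domain at the default shape).
#' @param class_probs named probabilities over [land_cover_classes()];
#'   must sum to 1.
#' @param soil_c_meanlog,soil_c_sdlog lognormal parameters of the soil
#'   carbon stock to 1 m (defaults give mean 122 Mg C ha^-1, CV 0.3 --
#'   the stock at which the default grassland-conversion soil term is
#'   reproduced at the grid mean).
#' @param mat_range,map_range `(min, max)` of the north-south mean annual
#'   temperature gradient (deg C) and west-east precipitation gradient
#'   (mm yr^-1).
#' @param conversion_rates named per-class annual conversion fractions.
#' @param table_noise relative half-width of the perturbations used by the
#'   random parameter-table mode.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             shape = c(100L, 100L),
                             cell_area_ha = 100,
                             class_probs = c(forest = 0.30, grassland = 0.20,
                                             shrubland = 0.10, cropland = 0.20,
                                             pasture = 0.10, urban = 0.05,
                                             water = 0.025, wetland = 0.025),
                             soil_c_meanlog = log(122) - log(1 + 0.3^2) / 2,
                             soil_c_sdlog = sqrt(log(1 + 0.3^2)),
                             mat_range = c(4, 18),
                             map_range = c(300, 1400),
                             conversion_rates = c(grassland = 0.01,
                                                  shrubland = 0.005,
                                                  forest = 0.002),
                             table_noise = 0.1) {
  stopifnot(length(shape) == 2L, all(shape >= 1L), cell_area_ha > 0,
            soil_c_sdlog >= 0, length(mat_range) == 2L,
            length(map_range) == 2L, table_noise >= 0)
  if (!setequal(names(class_probs), land_cover_classes()))
    stop("'class_probs' must be named over all land-cover classes")
  if (any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-9)
    stop("'class_probs' must be nonnegative and sum to 1")
  if (any(conversion_rates < 0) || any(conversion_rates > 1))
    stop("'conversion_rates' must be fractions in [0, 1]")
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 cell_area_ha = cell_area_ha,
                 class_probs = class_probs[land_cover_classes()],
                 soil_c_meanlog = soil_c_meanlog,
                 soil_c_sdlog = soil_c_sdlog,
                 mat_range = mat_range, map_range = map_range,
                 conversion_rates = conversion_rates,
                 table_noise = table_noise),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a toy landscape
#'
#' Samples per-cell land cover from the class probabilities; tree cover from
#' class-conditional distributions (forest cells span intact and degraded
#' stands, so a share falls below the 25% forest threshold); soil carbon from
#' the configured lognormal; temperature and precipitation as smooth
#' north-south / west-east gradients plus noise; conifer fraction from a
#' Beta(2, 2); and exclusion masks from class-conditional probabilities
#' (urban cells always carry the urban mask; Histosols concentrate in
#' wetlands). Deterministic for a given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return A [landscape_grid()].
#' @export
generate_landscape <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nr <- cfg$shape[1]; nc <- cfg$shape[2]; n <- nr * nc
  with_seed(cfg$seed, {
    lc <- sample.int(length(land_cover_classes()), n, replace = TRUE,
                     prob = cfg$class_probs)
    lc <- matrix(lc, nr, nc)
    cls <- land_cover_classes()[lc]
    tree <- numeric(n)
    tree[cls == "forest"] <- 100 * stats::rbeta(sum(cls == "forest"), 5, 2)
    tree[cls == "shrubland"] <- 100 * stats::rbeta(sum(cls == "shrubland"),
                                                   1.5, 6)
    low <- cls %in% c("grassland", "cropland", "pasture")
    tree[low] <- 100 * stats::rbeta(sum(low), 1, 12)
    tree[cls == "urban"] <- 100 * stats::rbeta(sum(cls == "urban"), 2, 6)
    tree[cls == "wetland"] <- 100 * stats::rbeta(sum(cls == "wetland"), 2, 4)
    tree[cls == "water"] <- 0
    tree <- matrix(tree, nr, nc)
    soil <- matrix(stats::rlnorm(n, cfg$soil_c_meanlog, cfg$soil_c_sdlog),
                   nr, nc)
    row_frac <- (row(lc) - 1) / max(nr - 1, 1)
    col_frac <- (col(lc) - 1) / max(nc - 1, 1)
    mat <- cfg$mat_range[1] + diff(cfg$mat_range) * row_frac +
      matrix(stats::rnorm(n, 0, 0.5), nr, nc)
    map <- cfg$map_range[1] + diff(cfg$map_range) * col_frac +
      matrix(stats::rnorm(n, 0, 40), nr, nc)
    map <- pmax(map, 0)
    conifer <- matrix(stats::rbeta(n, 2, 2), nr, nc)
    bern <- function(p) matrix(stats::runif(n) < p, nr, nc)
    masks <- list(
      urban = matrix(cls == "urban", nr, nc),
      impervious = bern(ifelse(cls == "urban", 0.8, 0.02)),
      major_road = bern(0.03),
      histosol = bern(ifelse(cls == "wetland", 0.4, 0.01)),
      protected = bern(0.1)
    )
    landscape_grid(land_cover = lc, tree_cover = tree, soil_c_1m = soil,
                   mat = mat, map_mm = map, conifer_frac = conifer,
                   masks = masks, cell_area_ha = cfg$cell_area_ha)
  })
}

# The frozen pathway fixture: printed headline maxima for the ten largest
# opportunities plus an eleven-pathway remainder summing to 122 Tg; CIs,
# cost tranches for the unreported pathways, pool splits, saturation times
# and co-benefit tags are synthetic fixture values constructed to respect
# every table invariant and the portfolio-level totals.
ncs_fixture <- function() {
  ids <- pathway_ids()
  mitigation <- c(307, 267, 107, 103, 95, 82, 52, 38, 18, 12,
                  11.9, 11.9, 5, 11.9, 11.7, 11.6, 11.8, 11.8, 11.7,
                  11.5, 11.2)
  lo_hw <- c(180, 160, 100, 65, 75, 65, 33, 26, 15, 8,
             5, 5, 2.5, 5, 5, 5, 5, 5, 6, 5, 5)
  hi_hw <- c(250, 220, 130, 85, 110, 95, 45, 38, 30, 12,
             8, 8, 3.5, 8, 8, 8, 8, 8, 9, 8, 8)
  cost10 <- c(2, 64, 24, 100, 0, 0, 28, 37, 0, 2,
              0, 4, 5, 6, 4, 3, 6.2, 11.8, 2, 0, 0)
  cost50 <- c(260, 230, 95, 103, 20, 25, 45, 38, 8, 8,
              8, 10, 5, 10, 8, 6, 9, 11.8, 9.2, 2, 2)
  cost100 <- c(290, 267, 107, 103, 50, 57, 52, 38, 15, 11,
               11.9, 11.9, 5, 11.9, 10, 10, 11.8, 11.8, 10, 5.5, 5.2)
  frac_biomass <- c(1, 1, 0.19, 0, 0, 0.9, 0, 1, 1, 0,
                    1, 1, 0.7, 0, 0.2, 0, 0, 0, 0.3, 0.3, 0)
  frac_soil <- c(0, 0, 0.81, 1, 1, 0.1, 0, 0, 0, 0,
                 0, 0, 0.3, 1, 0.8, 1, 0, 0, 0.7, 0.7, 1)
  frac_avoided <- c(0, 0, 0, 0, 0, 0, 1, 0, 0, 1,
                    0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0)
  extent <- c(51.2, 100, 0.6934, 88, 155, 15.4, 126, 0.25, 10.9, 0.459,
              3.5, 6.68, 0.88, 107, 2.1, 10, 1.1, NA, 11.7 / 8.2, 1.0,
              0.405)
  saturation <- c(90, 90, 67, 28, 100, 45, NA, 67, 20, NA,
                  90, 45, 60, 28, 35, 28, NA, NA, 100, 67, 100)
  cobenefits <- c(
    "air;biodiversity;soil;water", "air;biodiversity;water",
    "biodiversity;soil;water", "soil;water", "soil",
    "air;biodiversity;soil;water", "air;soil;water",
    "air;biodiversity;soil;water", "air;biodiversity;water",
    "biodiversity;water", "air;water", "biodiversity;water",
    "air;biodiversity;soil;water", "biodiversity;soil;water",
    "biodiversity;soil;water", "biodiversity;soil;water", "air;water",
    "air;water", "air;biodiversity;soil;water", "biodiversity;water",
    "biodiversity;water")
  data.frame(
    id = ids,
    category = unname(pathway_categories()[ids]),
    extent_mha = extent,
    flux_mgco2e_ha_yr = ifelse(is.na(extent) | extent == 0, NA,
                               mitigation / extent),
    mitigation_tg = mitigation,
    ci_low_tg = mitigation - lo_hw,
    ci_high_tg = mitigation + hi_hw,
    frac_biomass = frac_biomass,
    frac_soil = frac_soil,
    frac_avoided = frac_avoided,
    saturation_yr = saturation,
    cost10_tg = cost10,
    cost50_tg = cost50,
    cost100_tg = cost100,
    cobenefits = cobenefits,
    stringsAsFactors = FALSE
  )
}

#' Generate a pathway parameter table
#'
#' `mode = "fixture"` (the default) returns the deterministic 21-row
#' reference table: the ten largest pathway maxima as reported (307, 267,
#' 107, 103, 95, 82, 52, 38, 18 and 12 Tg CO2e yr^-1) plus eleven further
#' pathways summing to 122 Tg, with fixture CIs, cost tranches, pool
#' splits and co-benefit tags. `mode = "random"` perturbs the fixture's
#' means, CI half-widths and tranches by the configured relative noise for
#' property testing; noise 0 reproduces the fixture. Every emitted table
#' satisfies [validate_pathway_params()].
#'
#' @param cfg a [synthetic_config()] (used for `seed` and `table_noise`
#'   in random mode).
#' @param mode `"fixture"` or `"random"`.
#' @return A validated pathway table (data.frame).
#' @export
#' @examples
#' tab <- generate_parameter_table()
#' sum(tab$mitigation_tg)  # 1203
generate_parameter_table <- function(cfg = synthetic_config(),
                                     mode = c("fixture", "random")) {
  mode <- match.arg(mode)
  tab <- ncs_fixture()
  if (mode == "random" && cfg$table_noise > 0) {
    rel_lo <- (tab$mitigation_tg - tab$ci_low_tg) / tab$mitigation_tg
    rel_hi <- (tab$ci_high_tg - tab$mitigation_tg) / tab$mitigation_tg
    tab <- with_seed(cfg$seed + 1L, {
      n <- nrow(tab)
      jitter <- function() pmax(1 + stats::rnorm(n, 0, cfg$table_noise), 0.05)
      tab$mitigation_tg <- tab$mitigation_tg * jitter()
      tab$ci_low_tg <- tab$mitigation_tg * (1 - rel_lo * jitter())
      tab$ci_high_tg <- tab$mitigation_tg * (1 + rel_hi * jitter())
      f <- jitter()
      for (cl in c("cost10_tg", "cost50_tg", "cost100_tg"))
        tab[[cl]] <- pmin(tab[[cl]] * f, tab$mitigation_tg)
      # keep tranches nondecreasing in price after capping
      tab$cost50_tg <- pmax(tab$cost50_tg, tab$cost10_tg)
      tab$cost100_tg <- pmax(tab$cost100_tg, tab$cost50_tg)
      tab$flux_mgco2e_ha_yr <- ifelse(
        is.na(tab$extent_mha) | tab$extent_mha == 0, NA,
        tab$mitigation_tg / tab$extent_mha)
      tab
    })
  }
  validate_pathway_params(tab)
  tab
}

#' Sample land-conversion events on a landscape
#'
#' Each cell of a converting class converts within the year with its class
#' rate; the expected converted area per class is the class area times the
#' rate. Deterministic for a given seed.
#'
#' @param grid a [landscape_grid()].
#' @param rates named per-class annual conversion fractions in \[0, 1\].
#' @param seed integer RNG seed.
#' @return Named numeric vector: converted area per class, Mha yr^-1.
#' @export
generate_conversion_events <- function(grid, rates, seed = 1L) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (any(rates < 0) || any(rates > 1))
    stop("'rates' must be fractions in [0, 1]")
  bad <- setdiff(names(rates), land_cover_classes())
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  cls <- land_cover_classes()[grid$land_cover]
  with_seed(seed, {
    out <- vapply(names(rates), function(cl) {
      idx <- which(cls == cl)
      sum(stats::runif(length(idx)) < rates[[cl]]) * grid$cell_area_ha / 1e6
    }, numeric(1))
    out
  })
}
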