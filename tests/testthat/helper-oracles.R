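# Independent brute-force oracles used by the property tests. These are
# deliberately written with different data structures and loops than the
# package implementations they check.

# Fire management: explicit parcel-by-parcel enumeration. The treatable
# area is cut into n_parcels equal parcels, each tracking its own last
# treatment year; expected-value wildfire accounting per parcel. Exact
# match with the continuum model requires treat_frac * n_parcels to be an
# integer.
fire_benefit_parcel_oracle <- function(p, n_parcels = 20L) {
  parcel_area <- p$treatable_area / n_parcels
  per_year_treat <- p$treat_frac_per_yr * n_parcels
  stopifnot(abs(per_year_treat - round(per_year_treat)) < 1e-9)
  per_year_treat <- as.integer(round(per_year_treat))
  last_treated <- rep(-Inf, n_parcels)
  benefits <- numeric(p$horizon)
  for (yr in seq_len(p$horizon)) {
    protected_before <- which(yr - last_treated < p$protection_years)
    candidates <- setdiff(seq_len(n_parcels), protected_before)
    to_treat <- head(candidates, per_year_treat)
    last_treated[to_treat] <- yr
    protected_now <- which(yr - last_treated < p$protection_years)
    avoided <- length(protected_now) * parcel_area *
      p$wildfire_annual_prob * p$wildfire_emission
    rx_cost <- length(to_treat) * parcel_area * p$rx_emission
    benefits[yr] <- avoided - rx_cost
  }
  mean(benefits)
}

# Reforestation eligibility: exhaustive double loop over cells.
eligible_area_cell_oracle <- function(grid, threshold = 25,
                                      native_classes = c("forest",
                                                         "shrubland")) {
  classes <- land_cover_classes()
  n_eligible <- 0L
  for (i in seq_len(nrow(grid$land_cover))) {
    for (j in seq_len(ncol(grid$land_cover))) {
      cls <- classes[grid$land_cover[i, j]]
      if (!(cls %in% native_classes)) next
      if (grid$tree_cover[i, j] >= threshold) next
      if (grid$masks$urban[i, j] || grid$masks$impervious[i, j] ||
          grid$masks$major_road[i, j] || grid$masks$histosol[i, j]) next
      n_eligible <- n_eligible + 1L
    }
  }
  n_eligible * grid$cell_area_ha / 1e6
}

# Quadrature: spreadsheet-style direct formula on vectors.
quadrature_vector_oracle <- function(means, lows, highs) {
  list(mean = sum(means),
       low = sum(means) - sqrt(sum((means - lows)^2)),
       high = sum(means) + sqrt(sum((highs - means)^2)))
}

# MAC: direct per-price summation over the table.
mac_sum_oracle <- function(params, price) {
  col <- if (price < 10) NULL
  else if (price < 50) "cost10_tg"
  else if (price < 100) "cost50_tg"
  else "cost100_tg"
  if (is.null(col)) 0 else sum(params[[col]])
}

# Rotation: exhaustive argmax of mean annual increment over the table.
rotation_gain_scan_oracle <- function(growth_curve, econ_rotation, area) {
  best <- -Inf
  for (k in seq_len(nrow(growth_curve))) {
    mai <- growth_curve$stand_c[k] / growth_curve$age[k]
    if (mai > best) best <- mai
  }
  c_econ <- approx(growth_curve$age, growth_curve$stand_c,
                   xout = econ_rotation)$y
  max(best - c_econ / econ_rotation, 0) * area * 44 / 12
}

# A small symmetric-CI pathway table for tests that do not need the fixture.
toy_pathway_table <- function(n = 3) {
  fx <- generate_parameter_table()
  fx[seq_len(n), , drop = FALSE]
}
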