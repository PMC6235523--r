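#' The 21 natural-climate-solution pathway identifiers
#'
#' Ordered as conventionally reported: the ten largest opportunities first,
#' then the remaining eleven.
#'
#' @return Character vector of length 21.
#' @export
pathway_ids <- function() {
  c("reforestation",
    "natural_forest_management",
    "avoided_grassland_conversion",
    "cover_crops",
    "biochar",
    "alley_cropping",
    "cropland_nutrient_management",
    "avoided_forest_conversion",
    "fire_management",
    "tidal_wetland_restoration",
    "urban_reforestation",
    "improved_plantations",
    "windbreaks",
    "grazing_optimization",
    "grassland_restoration",
    "legumes_in_pastures",
    "improved_rice_management",
    "improved_manure_management",
    "peatland_restoration",
    "avoided_seagrass_loss",
    "seagrass_restoration")
}

pathway_categories <- function() {
  c(reforestation = "forest",
    natural_forest_management = "forest",
    avoided_grassland_conversion = "agriculture_grassland",
    cover_crops = "agriculture_grassland",
    biochar = "agriculture_grassland",
    alley_cropping = "agriculture_grassland",
    cropland_nutrient_management = "agriculture_grassland",
    avoided_forest_conversion = "forest",
    fire_management = "forest",
    tidal_wetland_restoration = "wetland",
    urban_reforestation = "forest",
    improved_plantations = "forest",
    windbreaks = "agriculture_grassland",
    grazing_optimization = "agriculture_grassland",
    grassland_restoration = "agriculture_grassland",
    legumes_in_pastures = "agriculture_grassland",
    improved_rice_management = "agriculture_grassland",
    improved_manure_management = "agriculture_grassland",
    peatland_restoration = "wetland",
    avoided_seagrass_loss = "wetland",
    seagrass_restoration = "wetland")
}

cobenefit_names <- function() c("air", "biodiversity", "soil", "water")

pathway_table_columns <- function() {
  c("id", "category", "extent_mha", "flux_mgco2e_ha_yr", "mitigation_tg",
    "ci_low_tg", "ci_high_tg", "frac_biomass", "frac_soil", "frac_avoided",
    "saturation_yr", "cost10_tg", "cost50_tg", "cost100_tg", "cobenefits")
}

#' Validate a pathway parameter table
#'
#' Checks the structural invariants every downstream stage relies on:
#' unique known ids, CI bounds bracketing the mean, nonnegative extents,
#' pool fractions summing to 1, cost tranches nondecreasing in price with
#' the last tranche not exceeding the pathway maximum, and co-benefit tags
#' drawn from the known set.
#'
#' @param params a data.frame with the columns of [pathway_table_columns()].
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   first offending pathway and rule.
#' @export
validate_pathway_params <- function(params) {
  stopifnot(is.data.frame(params))
  missing_cols <- setdiff(pathway_table_columns(), names(params))
  if (length(missing_cols))
    stop("pathway table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad_id <- setdiff(params$id, pathway_ids())
  if (length(bad_id))
    stop("unknown pathway id(s): ", paste(bad_id, collapse = ", "),
         "; valid ids are: ", paste(pathway_ids(), collapse = ", "))
  if (anyDuplicated(params$id))
    stop("duplicate pathway id(s): ",
         paste(unique(params$id[duplicated(params$id)]), collapse = ", "))
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    ctx <- function(msg) stop(sprintf("pathway '%s': %s", p$id, msg))
    if (!is.na(p$extent_mha) && p$extent_mha < 0) ctx("extent_mha < 0")
    if (p$ci_low_tg > p$mitigation_tg || p$ci_high_tg < p$mitigation_tg)
      ctx(sprintf("CI [%g, %g] does not bracket mean %g",
                  p$ci_low_tg, p$ci_high_tg, p$mitigation_tg))
    fr <- c(p$frac_biomass, p$frac_soil, p$frac_avoided)
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
      ctx(sprintf("pool fractions (%g, %g, %g) must be nonnegative and sum to 1",
                  fr[1], fr[2], fr[3]))
    tr <- c(p$cost10_tg, p$cost50_tg, p$cost100_tg)
    if (any(tr < 0) || is.unsorted(tr))
      ctx("cost tranches must be nonnegative and nondecreasing in price")
    if (tr[3] > p$mitigation_tg + 1e-9)
      ctx(sprintf("cost tranche at USD 100 (%g Tg) exceeds pathway maximum %g Tg",
                  tr[3], p$mitigation_tg))
    tags <- parse_cobenefits(p$cobenefits)
    bad <- setdiff(tags, cobenefit_names())
    if (length(bad)) ctx(paste("unknown co-benefit tag(s):",
                               paste(bad, collapse = ", ")))
  }
  invisible(params)
}

parse_cobenefits <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Read / write a pathway parameter table
#'
#' The on-disk format is a plain CSV with one row per pathway and the exact
#' columns of [pathway_table_columns()]; co-benefit tags are
#' semicolon-joined. Numeric fields are written with full (17 significant
#' digit) precision so that a written table re-reads bit-identically.
#'
#' @param path file path of the CSV.
#' @return `read_pathway_table()` returns the validated data.frame.
#' @export
read_pathway_table <- function(path) {
  params <- utils::read.csv(path, stringsAsFactors = FALSE)
  # numeric columns are doubles in memory; never let read.csv narrow them
  params[] <- lapply(params, function(v) if (is.integer(v)) as.double(v) else v)
  params$cobenefits[is.na(params$cobenefits)] <- ""
  validate_pathway_params(params)
  params
}

#' @rdname read_pathway_table
#' @param params a validated pathway table.
#' @export
write_pathway_table <- function(params, path) {
  validate_pathway_params(params)
  out <- params
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  out[num] <- lapply(out[num], function(v) ifelse(v == "NA", NA, v))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
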