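#' Per-pathway estimates from a parameter table
#'
#' Turns each row of a validated pathway table into a
#' [mitigation_estimate()], carrying over the mean, CI and pool split. The
#' avoided-emission share is booked to N2O for cropland nutrient
#' management (a field N2O pathway) and to CH4 otherwise (rice, manure,
#' tidal wetlands); the remainder is CO2 uptake.
#'
#' @param params a validated pathway table.
#' @return Named list of [mitigation_estimate()] objects.
#' @export
pathway_estimates <- function(params) {
  validate_pathway_params(params)
  out <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    avoided <- p$mitigation_tg * p$frac_avoided
    gas <- if (p$id == "cropland_nutrient_management")
      list(co2 = p$mitigation_tg - avoided, ch4 = 0, n2o = avoided)
    else list(co2 = p$mitigation_tg - avoided, ch4 = avoided, n2o = 0)
    est <- mitigation_estimate(
      p$id, p$mitigation_tg, ci = c(p$ci_low_tg, p$ci_high_tg),
      by_pool = c(biomass = p$frac_biomass, soil = p$frac_soil,
                  avoided_ch4_n2o = p$frac_avoided) * p$mitigation_tg)
    est$by_gas <- structure(gas, class = "gas_amount")
    attr(est, "cobenefits") <- parse_cobenefits(p$cobenefits)
    est
  })
  stats::setNames(out, params$id)
}

#' Aggregate pathway estimates into a portfolio
#'
#' Sums the per-pathway means (guarding against duplicated pathway ids,
#' i.e. double counting) and propagates the per-pathway 95% CIs to a
#' portfolio CI -- by error quadrature (the default: deterministic,
#' asymmetry-preserving) or by Monte Carlo.
#'
#' @param estimates list of [mitigation_estimate()] objects (at most one
#'   per pathway), or a pathway table to be run through
#'   [pathway_estimates()].
#' @param ci_method `"quadrature"` or `"mc"`.
#' @param n_draws,seed Monte Carlo settings (see [combine_monte_carlo()]).
#' @param reference_net_emissions Tg CO2e yr^-1 of reference national net
#'   emissions used for percent-of-reference reporting (default 5794.5,
#'   the 2016 U.S. net total).
#' @return An object of class `ncs_portfolio`.
#' @export
aggregate_portfolio <- function(estimates, ci_method = c("quadrature", "mc"),
                                n_draws = 10000L, seed = 1L,
                                reference_net_emissions = 5794.5) {
  ci_method <- match.arg(ci_method)
  if (is.data.frame(estimates)) estimates <- pathway_estimates(estimates)
  if (!is.list(estimates) || length(estimates) == 0L)
    stop("an empty portfolio cannot be aggregated")
  ok <- vapply(estimates, inherits, logical(1), "mitigation_estimate")
  if (!all(ok)) stop("all portfolio entries must be mitigation estimates")
  ids <- vapply(estimates, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s) in portfolio (double counting): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) > 21L) stop("a portfolio holds at most 21 pathways")
  total_mean <- sum(vapply(estimates, `[[`, numeric(1), "mean"))
  combined <- if (ci_method == "quadrature")
    combine_quadrature(estimates)
  else combine_monte_carlo(estimates, n_draws = n_draws, seed = seed)
  structure(
    list(estimates = stats::setNames(estimates, ids),
         total_mean = total_mean,
         total_ci = c(low = combined$low, high = combined$high),
         ci_method = ci_method,
         ci_detail = combined,
         reference_net_emissions = reference_net_emissions),
    class = "ncs_portfolio"
  )
}

#' @export
print.ncs_portfolio <- function(x, ...) {
  pct <- percent_of_reference(x$total_mean, x$reference_net_emissions)
  cat(sprintf(
    "<ncs_portfolio> %d pathways: %.4g Tg CO2e/yr (%.2g Pg), 95%% CI %.3g-%.3g Tg [%s]\n",
    length(x$estimates), x$total_mean, tg_to_pg(x$total_mean),
    x$total_ci[["low"]], x$total_ci[["high"]], x$ci_method))
  cat(sprintf("  %.0f%% of reference net emissions (%.1f Tg)\n",
              pct$percent_rounded, x$reference_net_emissions))
  invisible(x)
}

#' Share of the portfolio held by the k largest pathways
#'
#' @param portfolio an `ncs_portfolio`.
#' @param k number of top pathways, `1 <= k <= n`.
#' @return A list with `percent` (unrounded), `percent_rounded`, the `ids`
#'   of the k largest pathways, and their summed mean `total_tg`.
#' @export
top_k_share <- function(portfolio, k) {
  stopifnot(inherits(portfolio, "ncs_portfolio"))
  n <- length(portfolio$estimates)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop(sprintf("'k' must be between 1 and %d", n))
  means <- vapply(portfolio$estimates, `[[`, numeric(1), "mean")
  ord <- order(means, decreasing = TRUE)
  top <- ord[seq_len(k)]
  p <- percent_of_reference(sum(means[top]), portfolio$total_mean)
  list(percent = p$percent, percent_rounded = p$percent_rounded,
       ids = names(means)[top], total_tg = sum(means[top]))
}

#' Mitigation-weighted carbon-pool decomposition
#'
#' @param portfolio an `ncs_portfolio` whose estimates carry pool splits.
#' @return A list with `fractions` (summing to 1), `percent` and
#'   `percent_rounded` over biomass, soil and avoided CH4/N2O. The rounded
#'   percentages need not sum to 100.
#' @export
pool_decomposition <- function(portfolio) {
  stopifnot(inherits(portfolio, "ncs_portfolio"))
  pools <- Reduce(`+`, lapply(portfolio$estimates, `[[`, "by_pool"))
  if (portfolio$total_mean <= 0) stop("portfolio total must be positive")
  fr <- pools / portfolio$total_mean
  list(fractions = fr, percent = 100 * fr, percent_rounded = round(100 * fr))
}

#' Fig.-1-style results table
#'
#' One row per pathway: maximum mitigation, CI text, the three
#' cost-constrained values, co-benefit flags and saturation time, ordered
#' by decreasing maximum.
#'
#' @param params a validated pathway table.
#' @return A data.frame with logical columns `air`, `biodiversity`,
#'   `soil`, `water`.
#' @export
report_table <- function(params) {
  validate_pathway_params(params)
  tags <- lapply(params$cobenefits, parse_cobenefits)
  out <- data.frame(
    pathway = params$id,
    maximum_tg = params$mitigation_tg,
    ci_text = sprintf("%.3g to %.3g", params$ci_low_tg, params$ci_high_tg),
    cost10_tg = params$cost10_tg,
    cost50_tg = params$cost50_tg,
    cost100_tg = params$cost100_tg,
    saturation_yr = params$saturation_yr,
    stringsAsFactors = FALSE
  )
  for (cb in cobenefit_names())
    out[[cb]] <- vapply(tags, function(t) cb %in% t, logical(1))
  out[order(-out$maximum_tg, out$pathway), , drop = FALSE]
}

#' Write / read the results CSV
#'
#' Numeric columns are serialized at full precision (17 significant
#' digits), so a written table re-reads bit-identically and totals
#' recomputed from the file match in-memory totals exactly.
#'
#' @param results a data.frame (e.g. from [report_table()]).
#' @param path CSV path.
#' @export
write_results_csv <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- sprintf("%.17g", v)
    ifelse(s == "NA", NA, s)
  })
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out[] <- lapply(out, function(v) if (is.integer(v)) as.double(v) else v)
  out
}

#' Plain-text portfolio summary
#'
#' The headline block: total (Tg and Pg at 2 s.f.), 95% CI, percent of
#' reference net emissions, price-point mitigation and fractions, pool
#' decomposition, and the CI method (with draws and seed when Monte
#' Carlo). All quantities are recomputed from the portfolio and curve
#' passed in.
#'
#' @param portfolio an `ncs_portfolio`.
#' @param mac a [mac_curve()] for the same pathways.
#' @param gwp the [gwp_set()] the estimates used (recorded in the header).
#' @return Character vector of report lines, invisibly printed.
#' @export
portfolio_summary <- function(portfolio, mac = NULL, gwp = gwp_ar5()) {
  stopifnot(inherits(portfolio, "ncs_portfolio"))
  pct <- percent_of_reference(portfolio$total_mean,
                              portfolio$reference_net_emissions)
  pools <- pool_decomposition(portfolio)
  lines <- c(
    sprintf("NCS portfolio: %d pathways", length(portfolio$estimates)),
    sprintf("GWP basis: %s-%d (CH4 x%g, N2O x%g)", gwp$scheme,
            gwp$horizon_years, gwp$ch4_factor, gwp$n2o_factor),
    sprintf("Maximum mitigation: %.1f Tg CO2e/yr (%.2g Pg CO2e/yr)",
            portfolio$total_mean, tg_to_pg(portfolio$total_mean)),
    sprintf("95%% CI: %.1f to %.1f Tg (%.2g to %.2g Pg) [%s]",
            portfolio$total_ci[["low"]], portfolio$total_ci[["high"]],
            tg_to_pg(portfolio$total_ci[["low"]]),
            tg_to_pg(portfolio$total_ci[["high"]]), portfolio$ci_method),
    sprintf("Share of reference net emissions (%.1f Tg): %.1f%% (~%d%%)",
            portfolio$reference_net_emissions, pct$percent,
            pct$percent_rounded),
    sprintf("Pools: biomass %.1f%%, soil %.1f%%, avoided CH4/N2O %.1f%% (rounded %d/%d/%d)",
            pools$percent[["biomass"]], pools$percent[["soil"]],
            pools$percent[["avoided_ch4_n2o"]],
            pools$percent_rounded[["biomass"]],
            pools$percent_rounded[["soil"]],
            pools$percent_rounded[["avoided_ch4_n2o"]])
  )
  if (portfolio$ci_method == "mc")
    lines <- c(lines, sprintf("Monte Carlo: %d draws, seed %d",
                              attr(portfolio$ci_detail, "n_draws"),
                              attr(portfolio$ci_detail, "seed")))
  if (!is.null(mac)) {
    for (p in mac$points$price) {
      fr <- mac_fraction(mac, p, portfolio$total_mean)
      lines <- c(lines, sprintf(
        "At USD %g/Mg: %.0f Tg CO2e/yr (%.1f%%, ~%d%%)", p,
        mitigation_at_price(mac, p), fr$percent, fr$percent_rounded))
    }
  }
  lines
}
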