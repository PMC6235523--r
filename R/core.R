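#' Extent-times-rate mitigation arithmetic
#'
#' The generic estimator that most land-management pathways reduce to:
#' an eligible extent multiplied by a per-area annual flux. With extent in
#' Mha and rate in Mg CO2e ha^-1 yr^-1 the product is in Tg CO2e yr^-1
#' (1 Mha x 1 Mg ha^-1 = 1 Tg), so no unit factor appears.
#'
#' @param extent Mha; must be nonnegative.
#' @param rate Mg CO2e ha^-1 yr^-1; may be negative (a penalty term).
#' @return Tg CO2e yr^-1.
#' @export
#' @examples
#' area_times_rate(2.1, 1)          # 2.1 Tg
#' area_times_rate(88, 0.32 * 44/12)  # cover-crop arithmetic, ~103 Tg
area_times_rate <- function(extent, rate) {
  stopifnot(is.numeric(extent), is.numeric(rate))
  if (any(!is.finite(extent)) || any(extent < 0))
    stop("'extent' must be finite and nonnegative (Mha)")
  if (any(!is.finite(rate)))
    stop("'rate' must be finite (Mg CO2e/ha/yr)")
  extent * rate
}

#' Express a mitigation total as a percentage of reference emissions
#'
#' @param total Tg CO2e yr^-1.
#' @param reference Tg CO2e yr^-1; must be > 0 (e.g. national net emissions).
#' @return A list with `percent` (unrounded) and `percent_rounded`
#'   (nearest integer), the form used in report text.
#' @export
#' @examples
#' percent_of_reference(1203, 5794.5)
percent_of_reference <- function(total, reference) {
  stopifnot(is.numeric(total), length(total) == 1L, is.finite(total),
            is.numeric(reference), length(reference) == 1L)
  if (!is.finite(reference) || reference <= 0)
    stop("'reference' must be a positive number of Tg CO2e/yr")
  p <- 100 * total / reference
  list(percent = p, percent_rounded = round(p))
}

#' Format Tg CO2e as Pg at report precision
#'
#' Totals are carried in Tg throughout; Pg appears only in formatted output,
#' at 2 significant figures.
#'
#' @param tg Tg CO2e yr^-1.
#' @return Numeric Pg value(s), 2 significant figures.
#' @export
#' @examples
#' tg_to_pg(1203)  # 1.2
tg_to_pg <- function(tg) signif(tg / 1000, 2)

pool_names <- function() c("biomass", "soil", "avoided_ch4_n2o")

#' Per-pathway mitigation estimate
#'
#' The common return value of all pathway estimators: a mean annual
#' mitigation with a 95% confidence interval, decomposed by gas (in CO2e)
#' and by carbon pool.
#'
#' @param pathway_id character id of the pathway (see [pathway_ids()]), or
#'   any label for ad-hoc estimates.
#' @param mean Tg CO2e yr^-1.
#' @param ci length-2 numeric `(low, high)`, Tg CO2e yr^-1; must bracket
#'   `mean`. Defaults to a degenerate interval at the mean.
#' @param by_gas a [gas_amount()] whose entries are already expressed in
#'   Tg CO2e yr^-1 per gas (not native gas mass). Defaults to all-CO2.
#' @param by_pool named numeric over `biomass`, `soil`, `avoided_ch4_n2o`
#'   (Tg CO2e yr^-1) summing to `mean` within 1e-6. Defaults to all-biomass.
#' @return An object of class `mitigation_estimate`.
#' @export
mitigation_estimate <- function(pathway_id, mean, ci = c(mean, mean),
                                by_gas = NULL, by_pool = NULL) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(ci), length(ci) == 2L, all(is.finite(ci)))
  if (ci[1] > mean + 1e-9 || ci[2] < mean - 1e-9)
    stop(sprintf("CI [%g, %g] must bracket the mean %g", ci[1], ci[2], mean))
  if (is.null(by_gas)) by_gas <- gas_amount(co2 = mean)
  stopifnot(inherits(by_gas, "gas_amount"))
  if (is.null(by_pool)) {
    by_pool <- setNames(c(mean, 0, 0), pool_names())
  } else {
    if (!all(pool_names() %in% names(by_pool)))
      stop("'by_pool' must be named over biomass/soil/avoided_ch4_n2o")
    by_pool <- vapply(pool_names(), function(p) as.numeric(by_pool[[p]]),
                      numeric(1))
  }
  if (abs(sum(by_pool) - mean) > 1e-6)
    stop(sprintf("pool decomposition sums to %g, not the mean %g",
                 sum(by_pool), mean))
  structure(
    list(pathway_id = pathway_id, mean = mean,
         ci = c(low = ci[1], high = ci[2]),
         by_gas = by_gas, by_pool = by_pool),
    class = "mitigation_estimate"
  )
}

#' @export
print.mitigation_estimate <- function(x, ...) {
  cat(sprintf("<mitigation_estimate> %s: %.3g Tg CO2e/yr (95%% CI %.3g-%.3g)\n",
              x$pathway_id, x$mean, x$ci[["low"]], x$ci[["high"]]))
  pools <- x$by_pool[x$by_pool != 0]
  if (length(pools))
    cat("  pools:", paste(sprintf("%s %.3g", names(pools), pools),
                          collapse = ", "), "\n")
  invisible(x)
}

# Internal helper: scale a (mean, ci, pools, gas) estimate by a scalar k >= 0.
scale_estimate <- function(est, k) {
  stopifnot(inherits(est, "mitigation_estimate"), k >= 0)
  mitigation_estimate(
    est$pathway_id, est$mean * k, est$ci * k,
    by_gas = gas_amount(est$by_gas$co2 * k, est$by_gas$ch4 * k,
                        est$by_gas$n2o * k),
    by_pool = est$by_pool * k
  )
}
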