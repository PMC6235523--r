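#' Warming-potential metric for CO2-equivalent conversion
#'
#' A `gwp_set` bundles the factors that convert unit masses of CH4 and N2O to
#' CO2-equivalent mass under a chosen metric: the conventional global warming
#' potential (GWP) or the sustained-flux GWP (SGWP) appropriate for ongoing
#' wetland fluxes.
#'
#' @param ch4_factor CO2e per Mg CH4 (dimensionless mass ratio). Must be > 0.
#' @param n2o_factor CO2e per Mg N2O. Must be > 0.
#' @param horizon_years integer time horizon of the metric, > 0.
#' @param scheme `"GWP"` or `"SGWP"`.
#'
#' @return An object of class `gwp_set`.
#' @seealso [gwp_ar5()], [gwp_sgwp()], [to_co2e()]
#' @export
#' @examples
#' gwp_set(28, 265, 100, "GWP")
gwp_set <- function(ch4_factor, n2o_factor, horizon_years = 100L,
                    scheme = c("GWP", "SGWP")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(ch4_factor), length(ch4_factor) == 1L,
            is.numeric(n2o_factor), length(n2o_factor) == 1L)
  if (!is.finite(ch4_factor) || ch4_factor <= 0)
    stop("'ch4_factor' must be a finite positive number")
  if (!is.finite(n2o_factor) || n2o_factor <= 0)
    stop("'n2o_factor' must be a finite positive number")
  horizon_years <- as.integer(horizon_years)
  if (is.na(horizon_years) || horizon_years <= 0L)
    stop("'horizon_years' must be a positive integer")
  structure(
    list(ch4_factor = as.numeric(ch4_factor),
         n2o_factor = as.numeric(n2o_factor),
         horizon_years = horizon_years,
         scheme = scheme),
    class = "gwp_set"
  )
}

#' @rdname gwp_set
#' @details `gwp_ar5()` is the package default: AR5 100-year GWP (CH4 28,
#'   N2O 265). `gwp_sgwp()` is the 100-year sustained-flux metric (CH4 45)
#'   used by default for the tidal-wetland pathway, where the avoided flux is
#'   sustained rather than pulsed.
#' @export
gwp_ar5 <- function() gwp_set(28, 265, 100L, "GWP")

#' @rdname gwp_set
#' @export
gwp_sgwp <- function() gwp_set(45, 270, 100L, "SGWP")

#' @export
print.gwp_set <- function(x, ...) {
  cat(sprintf("<gwp_set> %s-%d: CH4 x%g, N2O x%g\n",
              x$scheme, x$horizon_years, x$ch4_factor, x$n2o_factor))
  invisible(x)
}

#' Annual flux of the three accounted greenhouse gases
#'
#' Fluxes are in native gas mass (Tg of the gas per year), not CO2e.
#' Negative values are allowed and denote net uptake.
#'
#' @param co2 Tg CO2 yr^-1.
#' @param ch4 Tg CH4 yr^-1.
#' @param n2o Tg N2O yr^-1.
#' @return An object of class `gas_amount`.
#' @export
#' @examples
#' gas_amount(co2 = 2, ch4 = 0.1, n2o = 0.01)
gas_amount <- function(co2 = 0, ch4 = 0, n2o = 0) {
  for (nm in c("co2", "ch4", "n2o")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("gas amount '%s' must be a single finite number", nm))
  }
  structure(list(co2 = as.numeric(co2), ch4 = as.numeric(ch4),
                 n2o = as.numeric(n2o)),
            class = "gas_amount")
}

#' @export
print.gas_amount <- function(x, ...) {
  cat(sprintf("<gas_amount> CO2 %g, CH4 %g, N2O %g (Tg gas/yr)\n",
              x$co2, x$ch4, x$n2o))
  invisible(x)
}

#' @export
`+.gas_amount` <- function(e1, e2) {
  stopifnot(inherits(e1, "gas_amount"), inherits(e2, "gas_amount"))
  gas_amount(e1$co2 + e2$co2, e1$ch4 + e2$ch4, e1$n2o + e2$n2o)
}

#' Convert a gas flux to CO2-equivalent
#'
#' Linear conversion `co2 + ch4 * ch4_factor + n2o * n2o_factor`; with fluxes
#' in Tg gas yr^-1 the result is in Tg CO2e yr^-1.
#'
#' @param gas a [gas_amount()].
#' @param gwp a [gwp_set()]; defaults to AR5 100-year GWP.
#' @return Tg CO2e yr^-1 (numeric scalar).
#' @export
#' @examples
#' to_co2e(gas_amount(co2 = 2, ch4 = 0.1, n2o = 0.01), gwp_ar5())  # 7.45
to_co2e <- function(gas, gwp = gwp_ar5()) {
  if (!inherits(gas, "gas_amount")) gas <- do.call(gas_amount, as.list(gas))
  stopifnot(inherits(gwp, "gwp_set"))
  gas$co2 + gas$ch4 * gwp$ch4_factor + gas$n2o * gwp$n2o_factor
}
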