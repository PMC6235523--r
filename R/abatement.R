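#' Marginal-abatement-cost step function
#'
#' A `mac_curve` is the portfolio's cumulative mitigation available at or
#' below each carbon price: an ordered set of `(price, cumulative)` points
#' interpreted as a right-continuous step function that is 0 below the first
#' price.
#'
#' @param points data.frame with numeric columns `price` (USD per Mg CO2e,
#'   strictly increasing) and `cumulative` (Tg CO2e yr^-1, nondecreasing).
#' @return An object of class `mac_curve`.
#' @export
mac_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("price", "cumulative") %in% names(points)))
  if (nrow(points) == 0L) stop("a MAC curve needs at least one point")
  if (any(diff(points$price) <= 0))
    stop("MAC prices must be strictly increasing")
  if (any(diff(points$cumulative) < 0))
    stop("MAC cumulative mitigation must be nondecreasing")
  if (any(points$cumulative < 0)) stop("cumulative mitigation must be >= 0")
  structure(list(points = points[c("price", "cumulative")]),
            class = "mac_curve")
}

#' @export
print.mac_curve <- function(x, ...) {
  cat("<mac_curve>\n")
  with(x$points, cat(sprintf("  <= USD %g: %g Tg CO2e/yr\n", price,
                             cumulative), sep = ""))
  invisible(x)
}

#' Build the portfolio MAC curve from per-pathway cost tranches
#'
#' Each pathway contributes a three-step function (cumulative mitigation
#' achievable below USD 10, 50 and 100 per Mg CO2e); the portfolio curve is
#' their pointwise sum over the union of price ceilings.
#'
#' @param params a validated pathway parameter table
#'   (see [validate_pathway_params()]).
#' @return A [mac_curve()] with points at USD 10, 50 and 100.
#' @export
#' @examples
#' build_mac(generate_parameter_table())
build_mac <- function(params) {
  validate_pathway_params(params)
  prices <- c(10, 50, 100)
  cols <- c("cost10_tg", "cost50_tg", "cost100_tg")
  cumulative <- vapply(cols, function(cl) sum(params[[cl]]), numeric(1))
  mac_curve(data.frame(price = prices, cumulative = unname(cumulative)))
}

#' Cumulative mitigation available at or below a price
#'
#' Step-function evaluation: the cumulative value at the largest curve price
#' `<= price`, and 0 below the first step.
#'
#' @param curve a [mac_curve()].
#' @param price USD per Mg CO2e, >= 0. `Inf` returns the curve maximum.
#' @return Tg CO2e yr^-1.
#' @export
mitigation_at_price <- function(curve, price) {
  stopifnot(inherits(curve, "mac_curve"), is.numeric(price),
            length(price) == 1L, !is.na(price), price >= 0)
  at <- which(curve$points$price <= price)
  if (length(at) == 0L) return(0)
  curve$points$cumulative[max(at)]
}

#' Fraction of the portfolio maximum achievable at a price
#'
#' @inheritParams mitigation_at_price
#' @param maximum portfolio maximum mitigation, Tg CO2e yr^-1 (> 0).
#' @return A list with `fraction` (in \[0, 1\]), `percent` and
#'   `percent_rounded`.
#' @export
mac_fraction <- function(curve, price, maximum) {
  stopifnot(is.numeric(maximum), maximum > 0)
  v <- mitigation_at_price(curve, price)
  p <- percent_of_reference(v, maximum)
  list(fraction = v / maximum, percent = p$percent,
       percent_rounded = p$percent_rounded)
}
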