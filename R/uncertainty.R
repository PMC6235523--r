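#' An uncertain annual quantity with 95% bounds
#'
#' @param mean central estimate, Tg CO2e yr^-1.
#' @param low,high 95% bounds; must satisfy `low <= mean <= high`.
#' @param family distribution family used when sampling: `"normal"`,
#'   `"two_piece_normal"`, `"lognormal"`, `"uniform"`, or `"point"` for a
#'   degenerate (zero-width) quantity.
#' @param sigma_low,sigma_high optional standard deviations of the lower and
#'   upper halves (filled in by [fit_from_ci()]).
#' @return An object of class `uncertain_quantity`.
#' @export
uncertain_quantity <- function(mean, low, high,
                               family = c("normal", "two_piece_normal",
                                          "lognormal", "uniform", "point"),
                               sigma_low = NULL, sigma_high = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(mean), is.numeric(low), is.numeric(high),
            length(mean) == 1L, length(low) == 1L, length(high) == 1L,
            all(is.finite(c(mean, low, high))))
  if (low > mean || mean > high)
    stop(sprintf("need low <= mean <= high, got (%g, %g, %g)",
                 low, mean, high))
  if (family == "lognormal" && low <= 0)
    stop("lognormal family requires low > 0")
  structure(list(mean = mean, low = low, high = high, family = family,
                 sigma_low = sigma_low, sigma_high = sigma_high),
            class = "uncertain_quantity")
}

#' @export
print.uncertain_quantity <- function(x, ...) {
  cat(sprintf("<uncertain_quantity> %.4g [%.4g, %.4g] (%s)\n",
              x$mean, x$low, x$high, x$family))
  invisible(x)
}

#' Fit a sampling family to a reported mean and 95% CI
#'
#' A symmetric interval maps to a normal with `sigma = (high - low)/(2 * 1.96)`;
#' an asymmetric one to a two-piece normal with per-side sigmas equal to each
#' half-width divided by 1.96; a degenerate interval (`low == mean == high`)
#' to a point mass.
#'
#' @inheritParams uncertain_quantity
#' @return An [uncertain_quantity()].
#' @export
#' @examples
#' fit_from_ci(10, 6.08, 13.92)  # normal, sigma = 2
#' fit_from_ci(10, 8, 16)        # two-piece, sigma_low ~1.02, sigma_high ~3.06
fit_from_ci <- function(mean, low, high) {
  if (low > mean || mean > high)
    stop(sprintf("need low <= mean <= high, got (%g, %g, %g)",
                 low, mean, high))
  hw_low <- mean - low
  hw_high <- high - mean
  if (hw_low == 0 && hw_high == 0)
    return(uncertain_quantity(mean, low, high, "point",
                              sigma_low = 0, sigma_high = 0))
  # tolerate floating-point asymmetry when classifying as symmetric
  if (abs(hw_low - hw_high) <= 1e-9 * max(hw_low, hw_high)) {
    s <- (high - low) / (2 * Z95)
    return(uncertain_quantity(mean, low, high, "normal",
                              sigma_low = s, sigma_high = s))
  }
  uncertain_quantity(mean, low, high, "two_piece_normal",
                     sigma_low = hw_low / Z95, sigma_high = hw_high / Z95)
}

#' Combine independent uncertain quantities by error quadrature
#'
#' The summation rule for independent terms used in inventory (IPCC
#' Approach 1 style) uncertainty reporting: means add, and each side's CI
#' half-widths add in quadrature, preserving asymmetry.
#'
#' @param quantities list of [uncertain_quantity()] (or objects coercible
#'   via [fit_from_ci()]); must be nonempty.
#' @return An [uncertain_quantity()] for the sum.
#' @export
#' @examples
#' q1 <- fit_from_ci(10, 7, 13)   # +/- 3
#' q2 <- fit_from_ci(20, 16, 24)  # +/- 4
#' combine_quadrature(list(q1, q2))  # +/- 5
combine_quadrature <- function(quantities) {
  quantities <- as_quantity_list(quantities)
  m <- sum(vapply(quantities, `[[`, numeric(1), "mean"))
  lo2 <- sum(vapply(quantities,
                    function(q) (q$mean - q$low)^2, numeric(1)))
  hi2 <- sum(vapply(quantities,
                    function(q) (q$high - q$mean)^2, numeric(1)))
  fit_from_ci(m, m - sqrt(lo2), m + sqrt(hi2))
}

#' Combine independent uncertain quantities by Monte Carlo
#'
#' Sampling-based (IPCC Approach 2 style) combination: each quantity is
#' drawn from its fitted family, draws are summed, and the empirical mean
#' and 2.5/97.5 percentiles of the sum are reported. Deterministic for a
#' given `seed`; the caller's RNG state is left untouched.
#'
#' Negative draws are truncated at 0 for quantities whose reported interval
#' is entirely nonnegative (mitigation potentials are nonnegative by
#' construction); the number of truncated draws is recorded in the
#' `truncated_draws` attribute of the result.
#'
#' @inheritParams combine_quadrature
#' @param n_draws number of draws, >= 1000.
#' @param seed integer RNG seed.
#' @param truncate_nonnegative truncate negative draws at zero for
#'   nonnegative quantities (default `TRUE`).
#' @return An [uncertain_quantity()] for the sum, with attributes
#'   `n_draws`, `seed` and `truncated_draws`.
#' @export
combine_monte_carlo <- function(quantities, n_draws = 10000L, seed = 1L,
                                truncate_nonnegative = TRUE) {
  quantities <- as_quantity_list(quantities)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1000L)
    stop("'n_draws' must be at least 1000")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  truncated <- 0L
  total <- numeric(n_draws)
  for (q in quantities) {
    d <- draw_quantity(q, n_draws)
    if (truncate_nonnegative && q$low >= 0) {
      n_neg <- sum(d < 0)
      if (n_neg > 0L) {
        truncated <- truncated + n_neg
        d[d < 0] <- 0
      }
    }
    total <- total + d
  }
  ci <- unname(stats::quantile(total, c(0.025, 0.975)))
  m <- mean(total)
  # guard the low <= mean <= high invariant against degenerate inputs
  out <- uncertain_quantity(m, min(ci[1], m), max(ci[2], m),
                            if (ci[1] == ci[2]) "point" else "two_piece_normal",
                            sigma_low = (m - ci[1]) / Z95,
                            sigma_high = (ci[2] - m) / Z95)
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  attr(out, "truncated_draws") <- truncated
  out
}

as_quantity_list <- function(quantities) {
  if (inherits(quantities, "uncertain_quantity"))
    quantities <- list(quantities)
  if (!is.list(quantities) || length(quantities) == 0L)
    stop("'quantities' must be a nonempty list of uncertain quantities")
  lapply(quantities, function(q) {
    if (inherits(q, "uncertain_quantity")) return(q)
    if (inherits(q, "mitigation_estimate"))
      return(fit_from_ci(q$mean, q$ci[["low"]], q$ci[["high"]]))
    if (is.numeric(q) && length(q) == 3L)
      return(fit_from_ci(q[2], q[1], q[3]))
    stop("cannot interpret element as an uncertain quantity")
  })
}

# One vector of draws from a fitted family.
draw_quantity <- function(q, n) {
  s_lo <- if (is.null(q$sigma_low)) (q$mean - q$low) / Z95 else q$sigma_low
  s_hi <- if (is.null(q$sigma_high)) (q$high - q$mean) / Z95 else q$sigma_high
  switch(q$family,
    point = rep(q$mean, n),
    normal = stats::rnorm(n, q$mean, (s_lo + s_hi) / 2),
    two_piece_normal = {
      # two-piece (split) normal: lower half-density with probability
      # proportional to sigma_low, upper with sigma_high
      lower <- stats::runif(n) < s_lo / (s_lo + s_hi)
      z <- abs(stats::rnorm(n))
      q$mean + ifelse(lower, -z * s_lo, z * s_hi)
    },
    lognormal = {
      if (q$low <= 0) stop("lognormal family requires positive bounds")
      sdlog <- (log(q$high) - log(q$low)) / (2 * Z95)
      stats::rlnorm(n, meanlog = log(q$mean), sdlog = sdlog)
    },
    uniform = stats::runif(n, q$low, q$high),
    stop(sprintf("cannot draw from family '%s'", q$family))
  )
}
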