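test_that("fit_from_ci classifies symmetric, asymmetric and degenerate CIs", {
  q <- fit_from_ci(10, 6.08, 13.92)
  expect_equal(q$family, "normal")
  expect_equal(q$sigma_low, 2)
  expect_equal(q$sigma_high, 2)
  qp <- fit_from_ci(10, 10, 10)
  expect_equal(qp$family, "point")
  qa <- fit_from_ci(10, 8, 16)
  expect_equal(qa$family, "two_piece_normal")
  expect_equal(qa$sigma_low, 2 / 1.96, tolerance = 1e-9)
  expect_equal(qa$sigma_high, 6 / 1.96, tolerance = 1e-9)
  expect_error(fit_from_ci(10, 12, 14), "low <= mean <= high")
})

test_that("quadrature combines independent half-widths in quadrature", {
  single <- fit_from_ci(10, 8, 16)
  c1 <- combine_quadrature(list(single))
  expect_equal(c1$mean, single$mean)
  expect_equal(c1$low, single$low)
  expect_equal(c1$high, single$high)
  c2 <- combine_quadrature(list(fit_from_ci(10, 7, 13),
                                fit_from_ci(20, 16, 24)))
  expect_equal(c2$mean, 30)
  expect_equal(c2$low, 25)   # 3-4-5
  expect_equal(c2$high, 35)
  expect_error(combine_quadrature(list()), "nonempty")
})

test_that("quadrature on the 21-pathway table matches the vector oracle", {
  tab <- generate_parameter_table()
  got <- combine_quadrature(pathway_estimates(tab))
  want <- quadrature_vector_oracle(tab$mitigation_tg, tab$ci_low_tg,
                                   tab$ci_high_tg)
  expect_equal(got$mean, want$mean)
  expect_equal(got$low, want$low)
  expect_equal(got$high, want$high)
})

test_that("Monte Carlo combination is seed-deterministic and leaves the RNG alone", {
  qs <- list(fit_from_ci(10, 6, 18), fit_from_ci(5, 4, 6))
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  a <- combine_monte_carlo(qs, n_draws = 2000, seed = 3)
  after <- rnorm(1)
  expect_identical(before, after)
  b <- combine_monte_carlo(qs, n_draws = 2000, seed = 3)
  expect_identical(a$low, b$low)
  expect_identical(a$high, b$high)
  expect_error(combine_monte_carlo(qs, n_draws = 10), "at least 1000")
})

test_that("point masses combine to an exact zero-width sum", {
  qs <- list(fit_from_ci(3, 3, 3), fit_from_ci(4, 4, 4))
  mc <- combine_monte_carlo(qs, n_draws = 1000, seed = 1)
  expect_equal(mc$mean, 7)
  expect_equal(mc$low, 7)
  expect_equal(mc$high, 7)
})

test_that("Monte Carlo agrees with quadrature for independent normals", {
  qs <- list(fit_from_ci(100, 80.4, 119.6), fit_from_ci(50, 35.3, 64.7))
  quad <- combine_quadrature(qs)
  mc <- combine_monte_carlo(qs, n_draws = 1e5, seed = 12,
                            truncate_nonnegative = FALSE)
  hw_q <- c(quad$mean - quad$low, quad$high - quad$mean)
  hw_m <- c(mc$mean - mc$low, mc$high - mc$mean)
  expect_equal(hw_m[1], hw_q[1], tolerance = 0.02)
  expect_equal(hw_m[2], hw_q[2], tolerance = 0.02)
  expect_equal(mc$mean, quad$mean, tolerance = 0.02)
})

test_that("portfolio CI width is nondecreasing when a pathway CI widens", {
  tab <- generate_parameter_table()
  base <- combine_quadrature(pathway_estimates(tab))
  for (i in c(1, 7, 21)) {
    wide <- tab
    wide$ci_low_tg[i] <- wide$ci_low_tg[i] - 30
    wide$ci_high_tg[i] <- wide$ci_high_tg[i] + 30
    got <- combine_quadrature(pathway_estimates(wide))
    expect_gte(got$high - got$low, base$high - base$low)
  }
})

test_that("negative draws are truncated for nonnegative quantities", {
  q <- fit_from_ci(1, 0.5, 1.5)  # sigma ~0.26, mass near zero negligible
  qn <- fit_from_ci(2, 0, 20)    # heavy lower tail at zero
  mc <- combine_monte_carlo(list(qn), n_draws = 5000, seed = 2)
  expect_gte(mc$low, 0)
  expect_gt(attr(mc, "truncated_draws"), 0)
  mc2 <- combine_monte_carlo(list(q, qn), n_draws = 5000, seed = 2)
  expect_gte(mc2$low, 0)
})

test_that("lognormal and uniform families draw within their support", {
  ql <- uncertain_quantity(10, 5, 20, family = "lognormal")
  mc <- combine_monte_carlo(list(ql), n_draws = 5000, seed = 8)
  expect_gt(mc$low, 0)
  qu <- uncertain_quantity(10, 5, 15, family = "uniform")
  mcu <- combine_monte_carlo(list(qu), n_draws = 5000, seed = 8)
  expect_gte(mcu$low, 5)
  expect_lte(mcu$high, 15)
  expect_error(uncertain_quantity(1, -1, 2, family = "lognormal"),
               "lognormal")
})
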