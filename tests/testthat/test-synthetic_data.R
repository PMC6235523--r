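test_that("one seed fixes the landscape bit-for-bit and spares the caller RNG", {
  cfg <- synthetic_config(seed = 5, shape = c(30, 30))
  set.seed(1234)
  marker <- rnorm(1)
  set.seed(1234)
  g1 <- generate_landscape(cfg)
  expect_identical(rnorm(1), marker)
  g2 <- generate_landscape(cfg)
  expect_identical(g1$land_cover, g2$land_cover)
  expect_identical(g1$soil_c_1m, g2$soil_c_1m)
  expect_identical(g1$masks$histosol, g2$masks$histosol)
})

test_that("an all-urban landscape yields no reforestation opportunity", {
  probs <- setNames(rep(0, 8), land_cover_classes())
  probs["urban"] <- 1
  g <- generate_landscape(synthetic_config(seed = 2, shape = c(20, 20),
                                           class_probs = probs))
  expect_equal(reforestation_eligible_area(g), 0)
})

test_that("empirical class frequencies track the configured probabilities", {
  cfg <- synthetic_config(seed = 7, shape = c(200, 200))
  g <- generate_landscape(cfg)
  n <- prod(cfg$shape)
  counts <- tabulate(g$land_cover, nbins = 8)
  for (k in seq_along(land_cover_classes())) {
    p <- cfg$class_probs[[k]]
    sd3 <- 3 * sqrt(n * p * (1 - p))
    expect_lt(abs(counts[k] - n * p), sd3 + 1)
  }
  # layer sanity: bounded fractions, nonnegative stocks, gradient direction
  expect_true(all(g$conifer_frac >= 0 & g$conifer_frac <= 1))
  expect_true(all(g$soil_c_1m >= 0))
  expect_lt(mean(g$mat[1, ]), mean(g$mat[200, ]))
  expect_lt(mean(g$map_mm[, 1]), mean(g$map_mm[, 200]))
  expect_equal(mean(g$soil_c_1m), 122, tolerance = 0.02)
})

test_that("conversion events hit the analytic class-area expectation", {
  g <- generate_landscape(synthetic_config(seed = 3, shape = c(60, 60)))
  zero <- generate_conversion_events(g, c(grassland = 0), seed = 1)
  expect_equal(unname(zero), 0)
  all_conv <- generate_conversion_events(g, c(grassland = 1), seed = 1)
  class_area <- sum(g$land_cover == match("grassland",
                                          land_cover_classes())) *
    g$cell_area_ha / 1e6
  expect_equal(unname(all_conv), class_area)
  # expected value over repeated seeds matches area x rate within 3 sd
  rate <- 0.1
  draws <- vapply(1:100, function(s)
    generate_conversion_events(g, c(grassland = rate), seed = s)[[1]],
    numeric(1))
  n_cells <- class_area * 1e6 / g$cell_area_ha
  se3 <- 3 * sqrt(n_cells * rate * (1 - rate) / 100) * g$cell_area_ha / 1e6
  expect_lt(abs(mean(draws) - class_area * rate), se3)
})

test_that("the fixture table carries the reference portfolio structure", {
  tab <- generate_parameter_table()
  expect_equal(nrow(tab), 21)
  expect_equal(sum(tab$mitigation_tg), 1203)
  expect_equal(tab$mitigation_tg[tab$id == "reforestation"], 307)
  expect_equal(sum(tab$mitigation_tg[11:21]), 122)
  expect_silent(validate_pathway_params(tab))
})

test_that("random tables satisfy the invariants; zero noise is the fixture", {
  for (seed in c(1, 12, 99)) {
    cfg <- synthetic_config(seed = seed, table_noise = 0.25)
    rt <- generate_parameter_table(cfg, mode = "random")
    expect_silent(validate_pathway_params(rt))
    expect_false(identical(rt$mitigation_tg,
                           generate_parameter_table()$mitigation_tg))
  }
  quiet <- generate_parameter_table(synthetic_config(table_noise = 0),
                                    mode = "random")
  expect_identical(quiet, generate_parameter_table())
})

test_that("table validation rejects broken rows", {
  tab <- generate_parameter_table()
  bad <- tab; bad$ci_low_tg[1] <- bad$mitigation_tg[1] + 1
  expect_error(validate_pathway_params(bad), "bracket")
  bad <- tab; bad$frac_soil[2] <- bad$frac_soil[2] + 0.5
  expect_error(validate_pathway_params(bad), "sum to 1")
  bad <- tab; bad$cost10_tg[3] <- bad$cost50_tg[3] + 1
  expect_error(validate_pathway_params(bad), "nondecreasing")
  bad <- tab; bad$id[5] <- "carbon_capture"
  expect_error(validate_pathway_params(bad), "unknown pathway")
  bad <- tab; bad$id[2] <- bad$id[1]
  expect_error(validate_pathway_params(bad), "duplicate")
})

test_that("landscapes round-trip through .asc layers plus manifest", {
  g <- generate_landscape(synthetic_config(seed = 11, shape = c(12, 17)))
  dir <- withr::local_tempdir()
  write_landscape(g, dir)
  expect_true(file.exists(file.path(dir, "manifest.yml")))
  g2 <- read_landscape(dir)
  expect_identical(g2$land_cover, g$land_cover)
  expect_identical(g2$masks, g$masks)
  expect_equal(g2$soil_c_1m, g$soil_c_1m, tolerance = 1e-8)
  expect_equal(g2$cell_area_ha, g$cell_area_ha)
})

test_that("the ESRI ASCII reader enforces its header contract", {
  path <- withr::local_tempfile(fileext = ".asc")
  m <- matrix(c(1.5, 2, NA, 4), 2, 2)
  write_esri_ascii(m, path, cellsize = 500)
  back <- read_esri_ascii(path)
  expect_equal(attr(back, "cellsize"), 500)
  expect_equal(unclass(back)[1:4], m[1:4])
  writeLines(c("ncols 2", "1 2"), path)
  expect_error(read_esri_ascii(path), "nrows")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "1 2 3"), path)
  expect_error(read_esri_ascii(path), "expected 4 values")
})
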