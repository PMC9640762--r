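test_that("hourly banding uses half-open intervals with a 3+ collapse", {
  expect_equal(band_minutes(59.99), "0-1")
  expect_equal(band_minutes(60.0), "1-2")
  expect_equal(band_minutes(0), "0-1")
  expect_equal(band_minutes(200), "3+")
  expect_equal(band_minutes(NA), "unreachable")
  expect_error(band_minutes(-1), class = "ra_band_error")
  expect_equal(band_labels(), c("0-1", "1-2", "2-3", "3+"))
})

test_that("population overlay conserves totals and proportions", {
  bands <- grid_raster(matrix(0, 4, 4), 100)
  pop <- grid_raster(matrix(10, 4, 4), 100)
  tab <- population_by_band(bands, pop)
  expect_equal(tab$percent[tab$band == "0-1"], 100.0)
  expect_equal(sum(tab$percent), 100.0)
  expect_equal(sum(tab$population), 160)

  misaligned <- grid_raster(matrix(10, 5, 5), 100)
  expect_error(population_by_band(bands, misaligned),
               class = "ra_alignment_error")
  zero <- grid_raster(matrix(0, 4, 4), 100)
  expect_error(population_by_band(bands, zero),
               class = "ra_population_error")
})

test_that("unreachable population is kept in the denominator", {
  k <- matrix(0, 2, 2)
  k[2, 2] <- NA
  bands <- grid_raster(k, 100)
  pop <- grid_raster(matrix(25, 2, 2), 100)
  tab <- population_by_band(bands, pop)
  expect_equal(tab$percent[tab$band == "0-1"], 75.0)
  expect_equal(tab$percent[tab$band == "unreachable"], 25.0)
  expect_equal(sum(tab$percent), 100.0)
})

test_that("a known geometry reproduces a manual cell tally", {
  # 1 km cells at 1 km/h: one axial step is exactly 60 min, so rings of
  # cells land in successive hourly bands: 1 cell 0-1, 8 cells 1-2
  # (diagonal ~84.9), 16 cells 2-3 (corner 2*84.9=169.7 < 180)
  cs <- uniform_surface(5, 5, 1, 1000)
  tt <- accumulate_travel_time(cs, cell_center_point(cs, 3, 3))
  tab <- population_by_band(band_minutes(tt),
                            grid_raster(matrix(1, 5, 5), 1000))
  expect_equal(tab$population, c(1, 8, 16, 0))
  expect_equal(tab$percent, c(4.0, 32.0, 64.0, 0.0))
})

test_that("vector mode applies a unit's band to its whole population", {
  tab <- population_by_band(c("0-1", "1-2", "1-2"), c(100, 200, 300))
  expect_equal(tab$population, c(100, 500, 0, 0))
  expect_equal(tab$percent, c(16.7, 83.3, 0, 0))
})

test_that("the access model filters facilities by readiness level", {
  spec <- synthetic_geo_spec(n_rows = 25, n_cols = 25, cell_size_m = 1000,
                             population_total = 20000, n_facilities = 3,
                             road_spacing = 8, seed = 21)
  sc <- gen_rural_scenario(spec)
  # 3 facilities: one difficult-ready, one regular-only, one not ready
  fac <- make_survey(
    make_facility("A", district = "KOLDA", x = sc$facilities$x[1],
                  y = sc$facilities$y[1]),
    make_facility("B", district = "KOLDA", x = sc$facilities$x[2],
                  y = sc$facilities$y[2], n_trained_ultrasound = 0L),
    make_facility("C", district = "KOLDA", x = sc$facilities$x[3],
                  y = sc$facilities$y[3], soap = FALSE))
  geo <- list(type = "rural", surface = sc$surface, roads = sc$roads,
              population = sc$population)

  reg <- run_access_model(fac, geo, level = "REGULAR")
  dif <- run_access_model(fac, geo, level = "DIFFICULT")
  expect_setequal(reg$ready_ids, c("A", "B"))
  expect_equal(dif$ready_ids, "A")
  # fewer ready facilities can only lengthen travel times
  d <- reg$travel_time$values - dif$travel_time$values
  expect_true(all(d <= 1e-9, na.rm = TRUE))
  # cumulative within-k-hours population shares are monotone in readiness
  cum_reg <- cumsum(reg$table$percent[1:4])
  cum_dif <- cumsum(dif$table$percent[1:4])
  expect_true(all(cum_reg >= cum_dif - 0.11))
  expect_equal(sum(reg$table$percent), 100, tolerance = 0.1 / 100)

  expect_error(run_access_model(
    make_survey(make_facility("Z", soap = FALSE, x = sc$facilities$x[1],
                              y = sc$facilities$y[1])),
    geo, level = "REGULAR"), class = "ra_no_facility_error")
})

test_that("unassessed facilities join only with an assumed level", {
  spec <- synthetic_geo_spec(n_rows = 20, n_cols = 20, cell_size_m = 1000,
                             population_total = 5000, n_facilities = 2,
                             road_spacing = 6, seed = 4)
  sc <- gen_rural_scenario(spec)
  df <- rbind(make_facility("A", x = sc$facilities$x[1],
                            y = sc$facilities$y[1], soap = FALSE),
              make_facility("H", x = sc$facilities$x[2],
                            y = sc$facilities$y[2]))
  df$assessed[2] <- FALSE
  for (cl in setdiff(facility_columns(),
                     c("facility_id", "district", "facility_type", "x", "y",
                       "assessed", "refers_to"))) df[[cl]][2] <- NA
  fac <- facility_survey(df)
  geo <- list(type = "rural", surface = sc$surface, roads = sc$roads,
              population = sc$population)
  expect_error(run_access_model(fac, geo, level = "REGULAR"),
               class = "ra_no_facility_error")
  res <- run_access_model(fac, geo, level = "REGULAR",
                          assumed_levels = c(H = "REGULAR"))
  expect_equal(res$ready_ids, "H")
})

test_that("urban model feeds neighborhood bands into the access table", {
  us <- gen_urban_scenario(synthetic_geo_spec(n_neighborhoods = 80,
                                              n_facilities = 4, seed = 9))
  fac <- do.call(make_survey, lapply(seq_len(4), function(i)
    make_facility(us$facilities$facility_id[i], x = us$facilities$x[i],
                  y = us$facilities$y[i])))
  geo <- list(type = "urban", network = us$network,
              neighborhoods = us$neighborhoods, boundary = us$boundary)
  res <- run_access_model(fac, geo, level = "REGULAR")
  expect_equal(res$model, "urban")
  expect_true(all(res$minutes >= 50))
  expect_equal(sum(res$table$percent), 100, tolerance = 0.1 / 100)
  expect_equal(sum(res$table$population), sum(us$neighborhoods$population))

  # round-trip reporting doubles the one-way minutes
  res2 <- run_access_model(fac, geo, level = "REGULAR", round_trip = TRUE)
  expect_equal(res2$minutes, 2 * res$minutes)
})
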