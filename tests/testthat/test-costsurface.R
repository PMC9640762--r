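test_that("road classes override surface classes in the cost surface", {
  lev_s <- c(grassland = 1, wetland = 2)
  lev_r <- c(primary = 1)
  surface <- grid_raster(matrix(c(1, 2, 1, NA), 2, 2), 100, levels = lev_s)
  roads <- grid_raster(matrix(c(1, NA, NA, NA), 2, 2), 100, levels = lev_r)
  cs <- build_cost_surface(surface, roads)
  expect_equal(cs$values[1, 1], 60)   # road over grassland
  expect_equal(cs$values[2, 1], 1.0)  # wetland walking speed
  expect_equal(cs$values[1, 2], 2.5)  # grassland walking speed
  expect_true(is.na(cs$values[2, 2])) # no-data stays impassable
})

test_that("unknown classes and misaligned grids are errors", {
  surface <- grid_raster(matrix(1, 2, 2), 100,
                         levels = c(lava_field = 1))
  expect_error(build_cost_surface(surface), class = "ra_schedule_error")
  expect_error(build_cost_surface(surface), "lava_field")
  a <- grid_raster(matrix(1, 2, 2), 100, levels = c(grassland = 1))
  b <- grid_raster(matrix(1, 3, 3), 100, levels = c(primary = 1))
  expect_error(build_cost_surface(a, b), class = "ra_alignment_error")
})

test_that("accumulation matches closed-form axial and diagonal steps", {
  # 2.5 km/h everywhere, 100 m cells: 41.67 m/min, one row of cells
  cs <- uniform_surface(1, 11, 2.5, 100)
  src <- cell_center_point(cs, 1, 1)
  tt <- accumulate_travel_time(cs, src)
  expect_equal(tt$values[1, 1], 0)
  expect_equal(tt$values[1, 11], 1000 / (2.5 * 1000 / 60), tolerance = 1e-12)
  expect_equal(tt$values[1, 11], 24.0)

  cs2 <- uniform_surface(2, 2, 2.5, 100)
  tt2 <- accumulate_travel_time(cs2, cell_center_point(cs2, 1, 1))
  expect_equal(tt2$values[2, 2], 100 * sqrt(2) * 60 / 2500, tolerance = 1e-12)
  expect_equal(tt2$values[2, 2], 3.394113, tolerance = 1e-6)
})

test_that("sources snap to passable cells within the radius, else error", {
  v <- matrix(2.5, 5, 5)
  v[1:4, 1:4] <- NA
  cs <- uniform_surface(5, 5, 2.5, 100)
  cs$values <- v
  # point on an impassable cell snaps to the nearest passable one
  tt <- accumulate_travel_time(cs, cell_center_point(cs, 3, 3))
  expect_equal(min(tt$values, na.rm = TRUE), 0)
  # snap radius exceeded
  v2 <- matrix(2.5, 15, 15)
  v2[1:14, 1:14] <- NA
  cs2 <- uniform_surface(15, 15, 2.5, 100)
  cs2$values <- v2
  expect_error(accumulate_travel_time(cs2, cell_center_point(cs2, 1, 1),
                                      max_snap_cells = 5),
               class = "ra_source_error")
  # source outside the raster extent
  expect_error(accumulate_travel_time(cs, data.frame(x = -500, y = 0)),
               class = "ra_source_error")
})

test_that("raster accumulation is cell-exact against a brute-force Dijkstra", {
  set.seed(17)
  for (rep in 1:10) {
    cs <- random_speed_raster(12, 12, cell_size = 100, p_na = 0.15)
    passable <- which(!is.na(cs$values), arr.ind = TRUE)
    src_rc <- passable[sample(nrow(passable), 2), , drop = FALSE]
    src <- do.call(rbind, lapply(seq_len(2), function(i)
      cell_center_point(cs, src_rc[i, 1], src_rc[i, 2])))
    got <- accumulate_travel_time(cs, src)
    want <- oracle_accumulate(cs$values, 100,
                              lapply(seq_len(nrow(src_rc)),
                                     function(i) src_rc[i, ]))
    expect_equal(got$values, want, tolerance = 1e-9)
  }
})

test_that("uniform-surface times respect the octile bound", {
  cs <- uniform_surface(21, 21, 4, 250)
  src <- cell_center_point(cs, 11, 11)
  tt <- accumulate_travel_time(cs, src)
  ctr <- cell_centers(cs)
  v_mpm <- 4 * 1000 / 60
  for (r in seq_len(21)) for (cc in seq_len(21)) {
    d <- sqrt((ctr$x[cc] - src$x)^2 + (ctr$y[r] - src$y)^2)
    expect_gte(tt$values[r, cc] + 1e-9, d / v_mpm)
    expect_lte(tt$values[r, cc], 1.0824 * d / v_mpm + 1e-9)
  }
})

test_that("adding a source never increases any cell's travel time", {
  set.seed(23)
  cs <- random_speed_raster(15, 15, cell_size = 200, p_na = 0.1)
  passable <- which(!is.na(cs$values), arr.ind = TRUE)
  pts <- do.call(rbind, lapply(1:3, function(i)
    cell_center_point(cs, passable[i * 20, 1], passable[i * 20, 2])))
  one <- accumulate_travel_time(cs, pts[1, ])
  all3 <- accumulate_travel_time(cs, pts)
  d <- all3$values - one$values
  expect_true(all(d <= 1e-9, na.rm = TRUE))
  # cells reachable from one source remain reachable with three
  expect_true(all(!is.na(all3$values[!is.na(one$values)])))
})

test_that("unreachable pockets stay no-data", {
  v <- matrix(2.5, 5, 5)
  v[, 3] <- NA # impassable wall
  cs <- uniform_surface(5, 5, 2.5, 100)
  cs$values <- v
  tt <- accumulate_travel_time(cs, cell_center_point(cs, 3, 1),
                               max_snap_cells = 0)
  expect_true(all(is.na(tt$values[, 3])))
  expect_true(all(is.na(tt$values[, 4:5])))
  expect_true(all(!is.na(tt$values[, 1:2])))
})

test_that("ascii grid rasters round-trip", {
  set.seed(3)
  r <- grid_raster(matrix(round(runif(30), 3), 5, 6), 250,
                   xmin = 1000, ymin = 2000)
  r$values[2, 3] <- NA
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, r$values)
  expect_equal(back$cell_size_m, r$cell_size_m)
  expect_equal(c(back$xmin, back$ymin), c(1000, 2000))
  unlink(path)
})
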