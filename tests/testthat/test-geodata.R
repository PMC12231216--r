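test_that("haversine distance matches the closed form and is symmetric", {
  expect_equal(haversine_km(c(0, 0), c(0, 0)), 0)
  # one degree of longitude on the equator = pi/180 * 6371
  expect_equal(haversine_km(c(0, 0), c(1, 0)), pi / 180 * 6371,
               tolerance = 1e-8)
  set.seed(1)
  for (i in 1:100) {
    p <- c(runif(1, -180, 180), runif(1, -89, 89))
    q <- c(runif(1, -180, 180), runif(1, -89, 89))
    expect_equal(haversine_km(p, q), haversine_km(q, p))
    expect_equal(haversine_km(p, q), oracle_haversine_km(p, q),
                 tolerance = 1e-8)
  }
  expect_error(haversine_km(c(NA, 0), c(0, 0)), "finite")
})

test_that("point-to-cell mapping respects the half-open cell convention", {
  g <- planar_grid(3, 3, cs = 2)
  # every cell centre maps back to its own cell
  cc <- cell_centers(g)
  rz <- rasterize_points(data.frame(lon = cc$x, lat = cc$y), g)
  expect_equal(rz$cells$row, cc$row)
  expect_equal(rz$cells$col, cc$col)
  expect_length(rz$rejects, 0)

  # brute-force interval arithmetic on a dense lattice incl. shared edges
  pts <- expand.grid(lon = seq(0, 5.999, by = 0.5),
                     lat = seq(0.001, 6, by = 0.5))
  rz <- rasterize_points(pts, g)
  for (i in seq_len(nrow(rz$cells))) {
    p <- pts[rz$cells$point[i], ]
    col <- rz$cells$col[i]; row <- rz$cells$row[i]
    west <- (col - 1) * 2; south <- 6 - row * 2
    expect_true(p$lon >= west && p$lon < west + 2)
    expect_true(p$lat >= south && p$lat < south + 2)
  }

  # out-of-extent points land in rejects, never in the output
  out <- rasterize_points(data.frame(lon = c(-1, 1), lat = c(1, 1)), g)
  expect_equal(out$rejects, 1L)
  expect_equal(out$cells$point, 2L)
  empty <- rasterize_points(data.frame(lon = numeric(), lat = numeric()), g)
  expect_equal(nrow(empty$cells), 0)
})

test_that("distance-to-city raster equals the exhaustive nearest-point oracle", {
  g <- small_grid(5)
  cities <- point_set(data.frame(
    lon = c(52.01, 52.03), lat = c(31.99, 31.97)))
  d <- distance_to_points(g, cities)
  expect_equal(d$values, oracle_distance_raster(g, cities), tolerance = 1e-8)

  # a city exactly on a cell centre gives that cell distance 0
  cc <- cell_centers(g, 2, 3)
  d1 <- distance_to_points(g, point_set(data.frame(lon = cc$x, lat = cc$y)))
  expect_equal(d1$values[2, 3], 0)

  # adding a city can never increase any cell's distance
  more <- point_set(data.frame(lon = c(cities$lon, 52.02),
                               lat = c(cities$lat, 31.96)))
  d2 <- distance_to_points(g, more)
  expect_true(all(d2$values <= d$values + 1e-12))

  expect_error(distance_to_points(g, point_set(
    data.frame(lon = numeric(), lat = numeric()))), "no healthcare")
})

test_that("planar grids use Euclidean distance in grid units", {
  g <- planar_grid(5, 5, cs = 1)
  cities <- point_set(data.frame(lon = 0.5, lat = 4.5), crs = "planar")
  d <- distance_to_points(g, cities)
  expect_equal(d$values,
               oracle_distance_raster(g, cities, geographic = FALSE),
               tolerance = 1e-10)
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[1, 2], 1)
  expect_equal(d$values[2, 2], sqrt(2))
})

test_that("map algebra propagates the union of nodata masks", {
  g <- planar_grid(3, 3)
  a <- raster_layer(g, matrix(1:9, 3, 3),
                    mask = matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  b <- raster_layer(g, matrix(2, 3, 3),
                    mask = matrix(c(rep(FALSE, 8), TRUE), 3, 3))
  prod <- stingrisk:::raster_map2(a, b, `*`)
  expect_true(prod$mask[1, 1] && prod$mask[3, 3])
  expect_equal(sum(prod$mask), 2)
  expect_equal(prod$values[2, 2], 10)
  expect_true(is.na(prod$values[1, 1]))
})

test_that("raster and stack round-trips are exact and errors are descriptive", {
  tmp <- withr::local_tempdir()
  g <- small_grid(10)
  set.seed(7)
  vals <- matrix(rnorm(100), 10, 10)
  mask <- matrix(runif(100) < 0.1, 10, 10)
  r <- raster_layer(g, vals, mask = mask)
  p <- file.path(tmp, "r.asc")
  write_raster(r, p)
  r2 <- read_raster(p)
  expect_identical(r2$values, r$values)
  expect_identical(r2$mask, r$mask)
  expect_true(stingrisk:::same_grid(r2$grid, g))

  # multi-layer stack keeps layer order and names
  stk <- env_stack(g, list(gdd = matrix(rnorm(100), 10),
                           bio4 = matrix(rnorm(100), 10),
                           bio12 = matrix(rnorm(100), 10),
                           bio15 = matrix(rnorm(100), 10),
                           hetero = matrix(rnorm(100), 10)))
  d <- file.path(tmp, "stack")
  write_env_stack(stk, d)
  stk2 <- read_env_stack(d)
  expect_identical(names(stk2$layers), names(stk$layers))
  for (nm in names(stk$layers))
    expect_identical(stk2$layers[[nm]]$values, stk$layers[[nm]]$values)

  # CSV with a missing coordinate column errors naming the column
  bad <- file.path(tmp, "occ.csv")
  utils::write.csv(data.frame(species = "a", lon = 1), bad,
                   row.names = FALSE)
  expect_error(read_points_csv(bad, required = c("species", "lon", "lat")),
               "lat")

  # GeoJSON points round through
  gj <- file.path(tmp, "cities.geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(list(type = "Feature",
                         properties = list(name = "cityA"),
                         geometry = list(type = "Point",
                                         coordinates = c(52.1, 31.5))))),
    auto_unbox = TRUE), gj)
  pts <- read_points_geojson(gj)
  expect_equal(pts$lon, 52.1)
  expect_equal(pts$name, "cityA")
})

test_that("co-registration is enforced across grids", {
  a <- raster_layer(small_grid(5), matrix(1, 5, 5))
  b <- raster_layer(small_grid(6), matrix(1, 6, 6))
  expect_error(stingrisk:::raster_map2(a, b, `*`), "co-registered")
  expect_error(env_stack(small_grid(5), list(x = b)), "co-registered")
})
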