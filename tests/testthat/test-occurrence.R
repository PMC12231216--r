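test_that("thinning enforces the minimum pairwise distance and is maximal", {
  # two points 0.5 km apart: exactly one survives a 1-km thin
  p2 <- point_set(data.frame(species = "s",
                             lon = c(52, 52), lat = c(31, 31 + 0.5 / 111.1949)))
  expect_equal(nrow(thin_occurrences(p2, 1, seed = 1)), 1)

  # points on a 2-km lattice are all retained
  lat_step <- 2 / 111.1949 # ~2 km in degrees of latitude
  lattice <- point_set(data.frame(species = "s",
                                  lon = rep(52, 6),
                                  lat = 31 + (0:5) * lat_step))
  expect_equal(nrow(thin_occurrences(lattice, 1, seed = 1)), 6)

  # single point returns unchanged
  one <- point_set(data.frame(species = "s", lon = 52, lat = 31))
  expect_equal(nrow(thin_occurrences(one, 1, seed = 1)), 1)

  # O(n^2) oracle on a clustered cloud: all pairwise distances >= min_dist
  # and every removed point is within min_dist of a retained one
  set.seed(10)
  n <- 200
  cloud <- point_set(data.frame(
    species = "s",
    lon = 52 + rnorm(n, sd = 0.02),
    lat = 31 + rnorm(n, sd = 0.02)))
  th <- thin_occurrences(cloud, 1, seed = 10)
  xy <- cbind(th$lon, th$lat)
  for (i in seq_len(nrow(th) - 1)) {
    d <- haversine_km(xy[rep(i, nrow(th) - i), , drop = FALSE],
                      xy[(i + 1):nrow(th), , drop = FALSE])
    expect_true(all(d >= 1))
  }
  removed <- !paste(cloud$lon, cloud$lat) %in% paste(th$lon, th$lat)
  for (i in which(removed)) {
    d <- haversine_km(cbind(cloud$lon[i], cloud$lat[i])[rep(1, nrow(th)), ],
                      xy)
    expect_lt(min(d), 1)
  }

  # idempotence: thinning a thinned set changes nothing
  th2 <- thin_occurrences(th, 1, seed = 99)
  expect_setequal(paste(th2$lon, th2$lat), paste(th$lon, th$lat))
  expect_true(attr(th, "thinned"))
  expect_equal(attr(th, "min_dist_km"), 1)
})

test_that("occupied-ecoregion census matches exhaustive cell lookup", {
  g <- small_grid(10)
  eco <- simulate_ecoregions(g, 5, seed = 21)
  # place one presence in each of three chosen regions
  targets <- c(1, 3, 5)
  pts <- do.call(rbind, lapply(targets, function(lab) {
    cell <- which(eco$values == lab, arr.ind = TRUE)[1, ]
    cc <- cell_centers(g, cell[1], cell[2])
    data.frame(species = "s", lon = cc$x, lat = cc$y)
  }))
  occ <- point_set(pts)
  expect_equal(occupied_ecoregions(occ, eco), targets)

  expect_error(occupied_ecoregions(point_set(
    data.frame(species = character(), lon = numeric(), lat = numeric())),
    eco), "empty")

  masked <- raster_layer(g, eco$values, mask = matrix(TRUE, 10, 10))
  expect_error(occupied_ecoregions(occ, masked), "unmasked")
})

test_that("pseudo-absences respect ecoregion and presence-cell constraints", {
  sys <- small_system(n = 25, n_occ = 40, n_bg = 200, seed = 31)
  eco <- sys$land$ecoregions
  occupied <- occupied_ecoregions(sys$occ, eco)
  bg <- sys$bg
  expect_equal(nrow(bg), 200)
  rz_bg <- rasterize_points(bg, eco$grid)
  rz_occ <- rasterize_points(sys$occ, eco$grid)
  # exhaustive membership check: every point in an occupied region,
  # no point sharing a cell with a presence
  bg_labels <- eco$values[cbind(rz_bg$cells$row, rz_bg$cells$col)]
  expect_true(all(bg_labels %in% occupied))
  occ_cells <- paste(rz_occ$cells$row, rz_occ$cells$col)
  expect_false(any(paste(rz_bg$cells$row, rz_bg$cells$col) %in% occ_cells))
  # unoccupied regions contribute nothing
  expect_length(setdiff(unique(bg_labels), occupied), 0)
  # distinct cells: each background point occupies its own cell
  expect_false(any(duplicated(rz_bg$cells[c("row", "col")])))
  # determinism
  bg2 <- sample_background(eco, occupied, sys$occ, n = 200, seed = 31)
  expect_identical(as.data.frame(bg), as.data.frame(bg2))
})

test_that("background sampling warns and truncates when candidates run out", {
  g <- small_grid(5)
  eco <- simulate_ecoregions(g, 2, seed = 1)
  occ <- point_set(data.frame(species = "s",
                              lon = cell_centers(g, 1, 1)$x,
                              lat = cell_centers(g, 1, 1)$y))
  expect_warning(bg <- sample_background(eco, 1:2, occ, n = 5000, seed = 1),
                 "candidate cells")
  expect_lte(nrow(bg), 24)
})

test_that("training-table weights balance the prevalence to one half", {
  sys <- small_system(n = 20, n_occ = 30, n_bg = 300, seed = 41)
  tab <- sys$tab
  n_p <- sum(tab$response == 1); n_a <- sum(tab$response == 0)
  expect_true(all(tab$weight[tab$response == 1] == 1))
  expect_equal(unique(tab$weight[tab$response == 0]), n_p / n_a)
  expect_equal(weighted_prevalence(tab), 0.5, tolerance = 1e-12)
  expect_equal(attr(tab, "layer_names"), names(sys$land$env$layers))
  expect_false(anyNA(tab))

  # closed form at the published sizes: 100 presences, 5000 absences
  expect_equal(100 / (100 + 5000 * (100 / 5000)), 0.5)

  # the identity holds for arbitrary class sizes
  set.seed(5)
  for (i in 1:50) {
    n_p <- sample(1:500, 1); n_a <- sample(1:5000, 1)
    w <- c(rep(1, n_p), rep(n_p / n_a, n_a))
    y <- c(rep(1, n_p), rep(0, n_a))
    expect_equal(sum(w * y) / sum(w), 0.5, tolerance = 1e-9)
  }
})

test_that("rows on masked predictor cells are dropped and counted", {
  g <- small_grid(6)
  vals <- matrix(rnorm(36), 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[1, 1] <- TRUE
  env <- env_stack(g, list(env1 = raster_layer(g, vals, mask = mask),
                           env2 = matrix(rnorm(36), 6, 6)))
  cc_bad <- cell_centers(g, 1, 1)
  cc_ok <- cell_centers(g, c(2, 3, 4), c(2, 3, 4))
  occ <- point_set(data.frame(species = "s",
                              lon = c(cc_bad$x, cc_ok$x),
                              lat = c(cc_bad$y, cc_ok$y)))
  bg <- point_set(data.frame(lon = cell_centers(g, 5:6, 5:6)$x,
                             lat = cell_centers(g, 5:6, 5:6)$y))
  tab <- training_table(occ, bg, env)
  expect_equal(sum(tab$response == 1), 3) # masked presence dropped
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_equal(weighted_prevalence(tab), 0.5)

  all_masked <- env_stack(g, list(env1 = raster_layer(
    g, vals, mask = matrix(TRUE, 6, 6))))
  expect_error(training_table(occ, bg, all_masked), "at least one")
})
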