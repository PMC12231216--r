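test_that("simulated environmental fields carry the requested correlation", {
  g <- small_grid(100)
  stk <- simulate_env_stack(g, n_layers = 3, seed = 5)
  x <- sapply(stk$layers, function(l) as.vector(l$values))
  cors <- cor(x)
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.1)
  expect_equal(unname(colMeans(x)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 3), tolerance = 1e-8)

  g <- small_grid(50)
  r <- matrix(c(1, 0.99, 0.99, 1), 2)
  stk2 <- simulate_env_stack(g, n_layers = 2, cross_corr = r, seed = 5)
  x2 <- sapply(stk2$layers, function(l) as.vector(l$values))
  expect_gt(cor(x2[, 1], x2[, 2]), 0.9)
})

test_that("generators are bit-identical under the same seed", {
  g <- small_grid(15)
  a <- simulate_env_stack(g, 3, seed = 9)
  b <- simulate_env_stack(g, 3, seed = 9)
  expect_identical(lapply(a$layers, `[[`, "values"),
                   lapply(b$layers, `[[`, "values"))
  expect_identical(simulate_ecoregions(g, 4, seed = 9)$values,
                   simulate_ecoregions(g, 4, seed = 9)$values)
  expect_identical(as.data.frame(simulate_cities(g, 5, seed = 9)),
                   as.data.frame(simulate_cities(g, 5, seed = 9)))
  vs <- virtual_species(simulate_env_stack(g, 2, seed = 9),
                        list(intercept = 0, linear = c(env1 = 1)))
  expect_identical(as.data.frame(sample_occurrences(vs, 20, seed = 9)),
                   as.data.frame(sample_occurrences(vs, 20, seed = 9)))
  # and generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_env_stack(g, 2, seed = 1))
  expect_identical(runif(1), before)
})

test_that("ecoregion simulation yields a full labelled partition", {
  g <- small_grid(50)
  eco <- simulate_ecoregions(g, 4, seed = 2)
  labs <- as.vector(eco$values)
  expect_setequal(unique(labs), 1:4) # every label occurs
  expect_false(any(is.na(labs)))

  mask <- matrix(FALSE, 10, 10); mask[1:3, ] <- TRUE
  gm <- small_grid(10)
  ecom <- simulate_ecoregions(gm, 3, mask = mask, seed = 2)
  expect_true(all(is.na(ecom$values[mask])))
  expect_false(any(is.na(ecom$values[!mask])))

  expect_error(simulate_ecoregions(g, 1, seed = 1), ">= 2")
  expect_error(simulate_ecoregions(small_grid(2), 5, seed = 1), "exceeds")
})

test_that("virtual species follow the linear-quadratic logistic response", {
  g <- small_grid(12)
  env <- simulate_env_stack(g, 3, seed = 4)
  # all-zero coefficients give suitability 1/2 everywhere
  vs0 <- virtual_species(env, list(intercept = 0))
  expect_true(all(vs0$suitability$values == 0.5))
  # negating all coefficients flips s to 1 - s
  co <- list(intercept = 0.5, linear = c(env1 = 1, env3 = -2),
             quadratic = c(env2 = -1.5))
  neg <- list(intercept = -0.5, linear = c(env1 = -1, env3 = 2),
              quadratic = c(env2 = 1.5))
  expect_equal(virtual_species(env, co)$suitability$values,
               1 - virtual_species(env, neg)$suitability$values,
               tolerance = 1e-12)
  # spot-check random cells against a direct evaluation of the formula
  vs <- virtual_species(env, co)
  set.seed(1)
  for (i in 1:10) {
    r <- sample(12, 1); c <- sample(12, 1)
    eta <- 0.5 + env$layers$env1$values[r, c] -
      2 * env$layers$env3$values[r, c] -
      1.5 * env$layers$env2$values[r, c]^2
    expect_equal(vs$suitability$values[r, c], 1 / (1 + exp(-eta)),
                 tolerance = 1e-12)
    expect_equal(vs$binary$values[r, c],
                 as.numeric(vs$suitability$values[r, c] >= 0.5))
  }
  expect_error(virtual_species(env, list(linear = c(nope = 1))), "unknown")
})

test_that("occurrence sampling follows the suitability surface", {
  g <- small_grid(10)
  env <- simulate_env_stack(g, 2, seed = 6)
  # degenerate: suitability concentrated in one cell
  vs <- virtual_species(env, list(intercept = 0))
  vs$suitability$values[] <- 0
  vs$suitability$values[4, 7] <- 1
  occ <- sample_occurrences(vs, 25, seed = 6)
  rz <- rasterize_points(occ, g)
  expect_true(all(rz$cells$row == 4 & rz$cells$col == 7))

  # sampled cells are suitability-biased relative to the landscape mean
  land <- simulate_landscape(small_grid(40), n_cities = 3, seed = 6)
  vs2 <- virtual_species(land$env, strong_niche())
  occ2 <- sample_occurrences(vs2, 200, seed = 6)
  rz2 <- rasterize_points(occ2, land$env$grid)
  s_at <- vs2$suitability$values[cbind(rz2$cells$row, rz2$cells$col)]
  expect_gt(mean(s_at), mean(vs2$suitability$values))

  vs$suitability$values[] <- 0
  expect_error(sample_occurrences(vs, 5, seed = 1), "zero everywhere")
})

test_that("clustered sampling stays on suitable cells and is reproducible", {
  land <- simulate_landscape(small_grid(30), n_cities = 2, seed = 16)
  vs <- virtual_species(land$env, strong_niche())
  cl <- list(n_parents = 10, sd_cells = 1.5)
  occ <- sample_occurrences(vs, 120, cluster = cl, seed = 16)
  expect_equal(nrow(occ), 120)
  rz <- rasterize_points(occ, land$env$grid)
  expect_length(rz$rejects, 0)
  s_at <- vs$suitability$values[cbind(rz$cells$row, rz$cells$col)]
  expect_true(all(s_at > 0))
  # clumping around few parents concentrates points in fewer distinct cells
  # than independent sampling of the same size
  occ_ind <- sample_occurrences(vs, 120, seed = 16)
  rz_ind <- rasterize_points(occ_ind, land$env$grid)
  expect_lt(nrow(unique(rz$cells[c("row", "col")])),
            nrow(unique(rz_ind$cells[c("row", "col")])))
  expect_identical(as.data.frame(sample_occurrences(vs, 40, cluster = cl,
                                                    seed = 4)),
                   as.data.frame(sample_occurrences(vs, 40, cluster = cl,
                                                    seed = 4)))
})

test_that("city simulation places distinct cities on unmasked cells", {
  g <- small_grid(8)
  mask <- matrix(FALSE, 8, 8); mask[, 1:4] <- TRUE
  cities <- simulate_cities(g, 6, mask = mask, seed = 3)
  expect_equal(nrow(cities), 6)
  rz <- rasterize_points(cities, g)
  expect_true(all(!mask[cbind(rz$cells$row, rz$cells$col)]))
  expect_false(any(duplicated(rz$cells[c("row", "col")])))
  expect_error(simulate_cities(g, 0, seed = 1), "at least one")
})

test_that("simulated landscapes satisfy their structural invariants", {
  land <- simulate_landscape(small_grid(25), n_regions = 4, n_cities = 6,
                             seed = 77)
  expect_s3_class(land$env, "env_stack")
  expect_true(stingrisk:::same_grid(land$env$grid, land$ecoregions$grid))
  labs <- land$ecoregions$values[!land$ecoregions$mask]
  expect_gte(length(unique(labs)), 2)
  expect_equal(sort(unique(labs)), seq_along(unique(labs))) # 1..K labels
  expect_gte(nrow(land$cities), 1)
})
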