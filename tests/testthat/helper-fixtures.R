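# Shared fixture builders. Everything is generated in code at test time.

small_grid <- function(n = 20, crs = "EPSG:4326") {
  grid_spec(n, n, x_origin = 52, y_origin = 32, cell_size = 1 / 120,
            crs = crs)
}

planar_grid <- function(nr = 10, nc = 10, cs = 1) {
  grid_spec(nr, nc, x_origin = 0, y_origin = nr * cs, cell_size = cs,
            crs = "planar")
}

# a small complete study system: landscape, strong-niche virtual species,
# thinned occurrences, background and training table
small_system <- function(n = 30, n_occ = 80, n_bg = 400, seed = 42) {
  land <- simulate_landscape(small_grid(n), n_regions = 4, n_cities = 5,
                             seed = seed)
  vs <- virtual_species(land$env, strong_niche())
  occ <- thin_occurrences(sample_occurrences(vs, n_occ, seed = seed),
                          min_dist_km = 1, seed = seed)
  bg <- sample_background(land$ecoregions,
                          occupied_ecoregions(occ, land$ecoregions),
                          occ, n = n_bg, seed = seed)
  tab <- training_table(occ, bg, land$env)
  list(land = land, vs = vs, occ = occ, bg = bg, tab = tab)
}

# the strong unimodal linear-quadratic niche used throughout: a sharp,
# near-threshold response to env1/env2 with a milder env3 gradient,
# occupying ~5-10% of cells
strong_niche <- function() {
  list(intercept = 2,
       linear = c(env1 = 8, env2 = -8, env3 = 4),
       quadratic = c(env1 = -24, env2 = -24))
}

# a cleanly separable toy table: presences at high env1, absences at low
separable_table <- function(n = 40, seed = 3) {
  set.seed(seed)
  df <- data.frame(
    response = rep(c(1, 0), each = n),
    weight = 1,
    env1 = c(runif(n, 2, 3), runif(n, -3, -2)),
    env2 = rnorm(2 * n))
  structure(df, layer_names = c("env1", "env2"), species = "toy",
            class = c("training_table", "data.frame"))
}
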