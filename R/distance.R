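#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are recycled;
#' each of `p` and `q` is a length-2 vector `c(lon, lat)` or a two-column
#' matrix/data frame of longitude and latitude in decimal degrees.
#'
#' @param p,q Points as `c(lon, lat)` or two-column matrices.
#' @return Numeric vector of distances in km; symmetric and nonnegative.
#' @export
#' @examples
#' haversine_km(c(0, 0), c(1, 0)) # one degree of longitude at the equator
haversine_km <- function(p, q) {
  p <- coerce_lonlat(p)
  q <- coerce_lonlat(q)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("coordinates must be finite")
  as.numeric(geosphere::distHaversine(p, q, r = 6371))
}

coerce_lonlat <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("lon", "lat")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = TRUE)
  storage.mode(x) <- "double"
  x
}

# distance between each row of a (n x 2 lon/lat) and each row of b (m x 2),
# respecting the grid's metric: km great-circle on geographic grids,
# Euclidean grid units on planar grids
point_cross_dist <- function(a, b, geographic = TRUE) {
  if (geographic) {
    geosphere::distm(a, b, fun = function(x, y)
      geosphere::distHaversine(x, y, r = 6371))
  } else {
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    sqrt(dx^2 + dy^2)
  }
}

#' Distance to the nearest city
#'
#' Builds the accessibility layer used for vulnerability mapping: each
#' unmasked cell's value is the distance from its centre to the nearest
#' point in `cities`. On geographic grids this is the great-circle distance
#' in km; on planar grids it is Euclidean distance in grid units. Cells that
#' contain a city get the (small) centre-to-point distance, not an exact
#' zero, unless the city sits on the centre.
#'
#' @param grid A [grid_spec()].
#' @param cities A [point_set()] with at least one point.
#' @param mask Optional logical nodata matrix carried to the output.
#' @return A [raster_layer()] of distances (km on geographic grids).
#' @export
distance_to_points <- function(grid, cities, mask = NULL) {
  cities <- as.data.frame(cities)
  if (!nrow(cities)) stop("no healthcare locations provided")
  cc <- cell_centers(grid)
  d <- point_cross_dist(cbind(cc$x, cc$y),
                        cbind(cities$lon, cities$lat),
                        geographic = grid_is_geographic(grid))
  vals <- matrix(apply(d, 1, min), nrow = grid$n_rows, ncol = grid$n_cols)
  raster_layer(grid, vals, mask = mask)
}
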