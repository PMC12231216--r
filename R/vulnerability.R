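# Vulnerability mapping: exposure to medically important species crossed
# with accessibility to healthcare (distance to the nearest city).

#' Per-species vulnerability map
#'
#' Cellwise product of the binary exposure map and the distance-to-city
#' layer: zero where the species is absent, the distance (km) where it is
#' present. Masked wherever either input is masked.
#'
#' @param binary A binary (0/1) [raster_layer()], e.g. from [binarize()].
#' @param distance A distance [raster_layer()] from [distance_to_points()],
#'   co-registered with `binary`.
#' @return A [raster_layer()] of vulnerability values (exposure x km) with
#'   attributes `species`, `exposure` (`"single-species"`) and
#'   `distance_units`.
#' @export
species_vulnerability <- function(binary, distance) {
  v <- binary$values[!binary$mask]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("'binary' must contain only 0/1 values")
  out <- raster_map2(binary, distance, `*`)
  attr(out, "species") <- attr(binary, "species") %||% "unknown"
  attr(out, "exposure") <- "single-species"
  attr(out, "distance_units") <-
    if (grid_is_geographic(binary$grid)) "km" else "grid units"
  out
}

#' Combined all-species vulnerability map
#'
#' Exposure across species is either richness (the sum of the binary maps
#' — cumulative hazard, the default) or union (any species present);
#' vulnerability is exposure times distance. The exposure definition is
#' recorded in the output so maps are never ambiguous. With one species
#' both definitions reduce to [species_vulnerability()].
#'
#' @param binaries Non-empty list of co-registered binary
#'   [raster_layer()]s.
#' @param distance Distance [raster_layer()].
#' @param exposure `"richness"` or `"union"`.
#' @return A [raster_layer()] with attributes `species = "combined"`,
#'   `exposure`, `distance_units`.
#' @export
combined_vulnerability <- function(binaries, distance,
                                   exposure = c("richness", "union")) {
  exposure <- match.arg(exposure)
  if (!length(binaries)) stop("empty list of binary maps")
  expo <- Reduce(function(a, b) raster_map2(a, b, `+`), binaries)
  if (exposure == "union")
    expo <- raster_map1(expo, function(v) (v > 0) + 0)
  out <- raster_map2(expo, distance, `*`)
  attr(out, "species") <- "combined"
  attr(out, "exposure") <- exposure
  attr(out, "distance_units") <-
    if (grid_is_geographic(distance$grid)) "km" else "grid units"
  out
}

#' Extract the per-cell vulnerability index
#'
#' One record per unmasked cell with its location and vulnerability value,
#' plus a five-number summary (min, quartiles, max).
#'
#' @param vmap A vulnerability [raster_layer()].
#' @param distance Optional distance layer to include a `distance` column.
#' @return A data frame `row`, `col`, `lon`, `lat`, `vulnerability`
#'   (and `distance` when given), with the summary in the `summary`
#'   attribute.
#' @export
vulnerability_index <- function(vmap, distance = NULL) {
  if (all(vmap$mask)) stop("vulnerability map is fully masked")
  g <- vmap$grid
  cc <- cell_centers(g)
  keep <- !as.vector(vmap$mask)
  out <- data.frame(row = cc$row[keep], col = cc$col[keep],
                    lon = cc$x[keep], lat = cc$y[keep],
                    vulnerability = as.vector(vmap$values)[keep])
  if (!is.null(distance)) {
    stop_if_grid_mismatch(g, distance$grid)
    out$distance <- as.vector(distance$values)[keep]
  }
  attr(out, "summary") <- stats::quantile(out$vulnerability,
                                          c(0, 0.25, 0.5, 0.75, 1))
  out
}
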