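#' Read and write rasters as ESRI ASCII grids
#'
#' Rasters are stored in the plain-text ESRI ASCII grid format (`.asc`):
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from north to south. Values
#' are written with 17 significant digits, so write-then-read round-trips
#' doubles exactly. The coordinate reference tag, which the `.asc` format
#' cannot carry, goes to a JSON sidecar `<path>.aux.json`; `read_raster`
#' uses it when present.
#'
#' @param x A [raster_layer()].
#' @param path File path (conventionally ending in `.asc`).
#' @param crs Fallback CRS tag when no sidecar is present.
#' @return `read_raster` returns a [raster_layer()]; `write_raster` returns
#'   `path` invisibly.
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "raster_layer"))
  g <- x$grid
  nodata <- -9999
  vals <- x$values
  vals[x$mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$x_origin),
    sprintf("yllcorner %.17g", g$y_origin - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %d", nodata)), con)
  writeLines(apply(vals, 1, function(r) paste(sprintf("%.17g", r),
                                              collapse = " ")), con)
  jsonlite::write_json(list(crs = g$crs), paste0(path, ".aux.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, crs = "EPSG:4326") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid payload size does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  aux <- paste0(path, ".aux.json")
  if (file.exists(aux)) crs <- jsonlite::read_json(aux)$crs
  g <- grid_spec(hdr$nrows, hdr$ncols, x_origin = hdr$xllcorner,
                 y_origin = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                 cell_size = hdr$cellsize, crs = crs)
  raster_layer(g, m)
}

#' Read and write environmental stacks
#'
#' A stack is stored as a directory of one `.asc` file per layer plus a
#' `stack.json` manifest recording the layer order, names and CRS, so the
#' ordered-layer-name contract survives the round trip. All layers must be
#' co-registered; `read_env_stack` verifies this and errors otherwise.
#'
#' @param x An [env_stack()].
#' @param dir Directory to write into (created if needed) or read from.
#' @return `read_env_stack` returns an [env_stack()]; `write_env_stack`
#'   returns `dir` invisibly.
#' @export
write_env_stack <- function(x, dir) {
  stopifnot(inherits(x, "env_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(x$layers))
    write_raster(x$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  jsonlite::write_json(list(layers = names(x$layers), crs = x$grid$crs),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir) {
  man_path <- file.path(dir, "stack.json")
  if (!file.exists(man_path)) stop("no stack.json manifest in ", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  layers <- lapply(man$layers, function(nm)
    read_raster(file.path(dir, paste0(nm, ".asc")), crs = man$crs))
  names(layers) <- man$layers
  g <- layers[[1]]$grid
  for (l in layers) stop_if_grid_mismatch(g, l$grid, "stack layers")
  env_stack(g, layers)
}

#' Read and write point tables
#'
#' Occurrence files are CSV with columns `species`, `lon`, `lat`; city files
#' are CSV with `name`, `lon`, `lat` or GeoJSON `Point`/`MultiPoint`
#' features. Missing required columns raise an error naming the column.
#'
#' @param path File path.
#' @param required Column names that must be present.
#' @param crs CRS tag attached to the returned [point_set()].
#' @return A [point_set()].
#' @export
read_points_csv <- function(path, required = c("lon", "lat"),
                            crs = "EPSG:4326") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  point_set(df, crs = crs)
}

#' @rdname read_points_csv
#' @param x A [point_set()] or data frame with `lon`/`lat`.
#' @export
write_points_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_points_csv
#' @export
read_points_geojson <- function(path, crs = "EPSG:4326") {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  rows <- list()
  for (f in feats) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    props <- if (identical(f$type, "Feature")) f$properties else NULL
    nm <- if (!is.null(props$name)) props$name else NA_character_
    coords <- switch(geom$type,
                     Point = list(geom$coordinates),
                     MultiPoint = geom$coordinates,
                     stop("unsupported GeoJSON geometry type: ", geom$type))
    for (xy in coords)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, lon = as.numeric(xy[[1]]), lat = as.numeric(xy[[2]]))
  }
  if (!length(rows)) stop("no point features found in ", path)
  point_set(do.call(rbind, rows), crs = crs)
}
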