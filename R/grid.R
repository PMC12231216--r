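#' Define a raster grid
#'
#' A `grid_spec` describes a regular cell-centre-registered grid. Row 1 is the
#' northernmost row; `x_origin` is the western edge of column 1 and `y_origin`
#' the northern edge of row 1. Cells are half-open intervals
#' `[edge, edge + cell_size)` on both axes (measured from the western and
#' southern edges), so every point strictly inside the extent belongs to
#' exactly one cell.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_origin,y_origin Western and northern edge coordinates of the grid.
#' @param cell_size Cell edge length, in degrees for geographic grids or in
#'   arbitrary planar units otherwise. Must be positive.
#' @param crs Coordinate reference tag. `"EPSG:4326"` (the default) marks a
#'   geographic longitude/latitude grid on which great-circle distances are
#'   used; any tag containing `"planar"` marks a synthetic planar grid with
#'   Euclidean distances in grid units.
#'
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' g <- grid_spec(10, 10, x_origin = 52, y_origin = 32, cell_size = 1 / 120)
#' g
grid_spec <- function(n_rows, n_cols, x_origin, y_origin, cell_size,
                      crs = "EPSG:4326") {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L)
  if (!is.finite(n_rows) || !is.finite(n_cols) || n_rows < 1 || n_cols < 1)
    stop("grid dimensions must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("'cell_size' must be a positive number")
  if (!is.finite(x_origin) || !is.finite(y_origin))
    stop("grid origin must be finite")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         cell_size = as.numeric(cell_size), crs = as.character(crs)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, cell size %g, crs %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs))
  cat(sprintf("  x: [%g, %g)  y: (%g, %g]\n",
              x$x_origin, x$x_origin + x$n_cols * x$cell_size,
              x$y_origin - x$n_rows * x$cell_size, x$y_origin))
  invisible(x)
}

grid_is_geographic <- function(grid) {
  !grepl("planar", tolower(grid$crs), fixed = TRUE)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$x_origin, b$x_origin)) &&
    isTRUE(all.equal(a$y_origin, b$y_origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    identical(a$crs, b$crs)
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must be co-registered ",
         "(identical dimensions, origin, cell size and crs)")
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @param rows,cols Optional row/column indices (1-based, recycled against
#'   each other). When omitted, centres of all cells are returned in
#'   column-major order (column 1 top to bottom, then column 2, ...), matching
#'   how matrix values are stored.
#' @return A data frame with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(grid, rows = NULL, cols = NULL) {
  if (is.null(rows) != is.null(cols))
    stop("give both 'rows' and 'cols', or neither")
  if (is.null(rows)) {
    rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
    cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  }
  n <- max(length(rows), length(cols))
  rows <- rep_len(as.integer(rows), n)
  cols <- rep_len(as.integer(cols), n)
  if (any(rows < 1 | rows > grid$n_rows | cols < 1 | cols > grid$n_cols))
    stop("cell index out of range")
  data.frame(
    row = rows, col = cols,
    x = grid$x_origin + (cols - 0.5) * grid$cell_size,
    y = grid$y_origin - (rows - 0.5) * grid$cell_size)
}

#' Create a raster layer
#'
#' A `raster_layer` couples a [grid_spec()] with an `n_rows x n_cols` numeric
#' matrix and a logical nodata mask. Masked cells carry `NA` and propagate
#' through all map algebra (union-mask semantics); unmasked cells must be
#' finite.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows x n_cols` (row 1 =
#'   north). Non-finite entries are masked.
#' @param mask Optional logical matrix; `TRUE` marks nodata cells. Merged with
#'   non-finite entries of `values`.
#' @return An object of class `raster_layer` with elements `grid`, `values`
#'   (masked cells set to `NA`) and `mask`.
#' @export
raster_layer <- function(grid, values, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop(sprintf("values must be a %d x %d matrix", grid$n_rows, grid$n_cols))
  storage.mode(values) <- "double"
  m <- !is.finite(values)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(values))) stop("mask dimensions differ from values")
    m <- m | (mask %in% TRUE & !is.na(mask)) | mask
    m[is.na(m)] <- TRUE
  }
  values[m] <- NA_real_
  structure(list(grid = grid, values = values, mask = m),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf("raster_layer: %d x %d, %d masked cell(s), crs %s\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$mask), x$grid$crs))
  if (length(v))
    cat(sprintf("  values: min %.4g, median %.4g, max %.4g\n",
                min(v), stats::median(v), max(v)))
  invisible(x)
}

#' Plot a raster layer
#'
#' Draws the layer with [graphics::image()], oriented so that north (row 1)
#' is at the top.
#'
#' @param x A [raster_layer()].
#' @param main Plot title.
#' @param col Colour ramp.
#' @param ... Passed on to [graphics::image()].
#' @export
plot.raster_layer <- function(x, main = "", col = grDevices::hcl.colors(64), ...) {
  g <- x$grid
  xs <- g$x_origin + (seq_len(g$n_cols) - 0.5) * g$cell_size
  ys <- g$y_origin - (rev(seq_len(g$n_rows)) - 0.5) * g$cell_size
  z <- t(x$values[g$n_rows:1, , drop = FALSE])
  graphics::image(xs, ys, z, main = main, col = col, xlab = "x", ylab = "y", ...)
  invisible(x)
}

# elementwise algebra with union-mask semantics
raster_map2 <- function(a, b, f) {
  stopifnot(inherits(a, "raster_layer"), inherits(b, "raster_layer"))
  stop_if_grid_mismatch(a$grid, b$grid)
  out <- f(a$values, b$values)
  raster_layer(a$grid, out, mask = a$mask | b$mask)
}

raster_map1 <- function(a, f) {
  raster_layer(a$grid, f(a$values), mask = a$mask)
}

#' Create an environmental stack
#'
#' An ordered collection of co-registered [raster_layer()]s with unique
#' names. The combined nodata mask is the union of the layer masks; cells
#' masked in any layer are unusable for modelling.
#'
#' @param grid A [grid_spec()] shared by all layers.
#' @param layers Named list of numeric matrices or `raster_layer`s.
#' @return An object of class `env_stack` with elements `grid`, `layers`
#'   (named list of `raster_layer`) and `mask` (combined nodata mask).
#' @export
env_stack <- function(grid, layers) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("layers must have unique non-empty names")
  layers <- lapply(layers, function(l) {
    if (inherits(l, "raster_layer")) {
      stop_if_grid_mismatch(grid, l$grid, "stack layers")
      l
    } else raster_layer(grid, l)
  })
  mask <- Reduce(`|`, lapply(layers, `[[`, "mask"))
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) on a %d x %d grid (%s)\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, x$grid$crs))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  combined nodata cells: %d\n", sum(x$mask)))
  invisible(x)
}

# predictor matrix at given cells (rows of data.frame(row, col));
# rows falling on the combined mask get NA across all layers
stack_extract <- function(stack, cells) {
  idx <- cbind(cells$row, cells$col)
  out <- vapply(stack$layers, function(l) l$values[idx], numeric(nrow(idx)))
  out <- matrix(out, nrow = nrow(idx),
                dimnames = list(NULL, names(stack$layers)))
  out
}

#' Create a point set
#'
#' @param df Data frame with at least `lon` and `lat` columns (planar grids
#'   reuse the same column names for x and y). Extra columns are kept.
#' @param crs Coordinate reference tag (see [grid_spec()]).
#' @return The data frame, classed `point_set`, with a `crs` attribute.
#' @export
point_set <- function(df, crs = "EPSG:4326") {
  df <- as.data.frame(df)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("point set requires 'lon' and 'lat' columns")
  if (nrow(df) && (!all(is.finite(df$lon)) || !all(is.finite(df$lat))))
    stop("point coordinates must be finite")
  geo <- !grepl("planar", tolower(crs), fixed = TRUE)
  if (geo && nrow(df) &&
      (any(df$lon < -180 | df$lon > 180) || any(df$lat < -90 | df$lat > 90)))
    stop("geographic coordinates out of range: lon in [-180,180], lat in [-90,90]")
  attr(df, "crs") <- crs
  class(df) <- c("point_set", "data.frame")
  df
}

#' Map points to grid cells
#'
#' Assigns each point to the cell whose half-open interval
#' `[edge, edge + cell_size)` (western/southern edges) contains it. Points
#' outside the grid extent are reported in `rejects`, never silently dropped.
#'
#' @param pts A [point_set()] or data frame with `lon`/`lat`.
#' @param grid A [grid_spec()].
#' @return A list with `cells` (data frame `row`, `col`, plus the point index
#'   `point` it came from) and `rejects` (integer indices of out-of-extent
#'   points).
#' @export
rasterize_points <- function(pts, grid) {
  pts <- as.data.frame(pts)
  if (!nrow(pts)) return(list(cells = data.frame(point = integer(),
                                                 row = integer(),
                                                 col = integer()),
                              rejects = integer()))
  col <- floor((pts$lon - grid$x_origin) / grid$cell_size) + 1
  # y measured from the southern extent so intervals are [edge, edge+cs)
  y_south <- grid$y_origin - grid$n_rows * grid$cell_size
  k <- floor((pts$lat - y_south) / grid$cell_size) + 1
  row <- grid$n_rows - k + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  list(cells = data.frame(point = which(ok), row = as.integer(row[ok]),
                          col = as.integer(col[ok])),
       rejects = which(!ok))
}
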