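# Presence handling: thinning, ecoregion census, background sampling and
# training-table assembly.

occ_dist <- function(a, b, geographic) {
  if (geographic) haversine_km(a, b)
  else sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

#' Spatially thin occurrence records
#'
#' Enforces a minimum pairwise distance between presence points so the data
#' match the working resolution and spatial autocorrelation is reduced.
#' Greedy seeded thinning: points are shuffled by `seed`, then accepted iff
#' at least `min_dist_km` from every previously accepted point. The retained
#' set has all pairwise distances `>= min_dist_km` and is maximal: every
#' removed point lies within `min_dist_km` of a retained one. Idempotent.
#'
#' @param occ A [point_set()] (or data frame with `lon`/`lat`) of presences.
#' @param min_dist_km Minimum pairwise distance. Kilometres on geographic
#'   point sets; grid units on planar ones.
#' @param seed Integer seed controlling the shuffle.
#' @return The retained subset, same class and columns as `occ`, with
#'   attributes `thinned = TRUE` and `min_dist_km`.
#' @export
thin_occurrences <- function(occ, min_dist_km = 1, seed = 1) {
  crs <- attr(occ, "crs") %||% "EPSG:4326"
  df <- as.data.frame(occ)
  if (!nrow(df)) stop("no occurrence points to thin")
  geo <- !grepl("planar", tolower(crs), fixed = TRUE)
  keep <- with_seed(seed, {
    ord <- sample.int(nrow(df))
    xy <- cbind(df$lon, df$lat)
    acc <- integer()
    for (i in ord) {
      if (!length(acc) ||
          all(occ_dist(xy[acc, , drop = FALSE],
                       xy[rep(i, length(acc)), , drop = FALSE],
                       geo) >= min_dist_km))
        acc <- c(acc, i)
    }
    sort(acc)
  })
  out <- point_set(df[keep, , drop = FALSE], crs = crs)
  rownames(out) <- NULL
  attr(out, "thinned") <- TRUE
  attr(out, "min_dist_km") <- min_dist_km
  out
}

#' Ecoregions occupied by a species
#'
#' @param occ Presence [point_set()].
#' @param ecoregions Integer-labelled [raster_layer()].
#' @return Sorted integer vector of labels of cells holding at least one
#'   presence. Errors if every presence falls on a masked cell or outside
#'   the grid.
#' @export
occupied_ecoregions <- function(occ, ecoregions) {
  if (!nrow(as.data.frame(occ))) stop("empty occurrence set")
  rz <- rasterize_points(occ, ecoregions$grid)
  labs <- ecoregions$values[cbind(rz$cells$row, rz$cells$col)]
  labs <- labs[!is.na(labs)]
  if (!length(labs))
    stop("no presence falls on an unmasked ecoregion cell")
  sort(unique(as.integer(labs)))
}

#' Sample ecoregion-constrained pseudo-absences
#'
#' Draws background points by uniform sampling of distinct unmasked cells
#' within the ecoregions the species occupies, excluding cells that contain
#' a presence (so no cell carries both labels), and jittering each point
#' uniformly within its cell. If fewer candidate cells than `n` exist, all
#' candidates are used with a warning.
#'
#' @param ecoregions Integer-labelled [raster_layer()].
#' @param occupied Integer labels to sample from (see
#'   [occupied_ecoregions()]).
#' @param occ Presence [point_set()] whose cells are excluded.
#' @param n Number of pseudo-absences requested (default 5000).
#' @param allow_presence_cells Keep presence cells in the candidate pool.
#' @param seed Integer seed.
#' @return A [point_set()] with columns `lon`, `lat`, and attributes
#'   `n_requested`, `ecoregion_labels_used`, `seed`.
#' @export
sample_background <- function(ecoregions, occupied, occ, n = 5000,
                              allow_presence_cells = FALSE, seed = 1) {
  g <- ecoregions$grid
  cand <- !ecoregions$mask & matrix(ecoregions$values %in% occupied,
                                    g$n_rows, g$n_cols)
  if (!allow_presence_cells) {
    rz <- rasterize_points(occ, g)
    cand[cbind(rz$cells$row, rz$cells$col)] <- FALSE
  }
  pool <- which(cand)
  if (!length(pool)) stop("no candidate cells for pseudo-absence sampling")
  if (length(pool) < n) {
    warning(sprintf(paste0("only %d candidate cells available; sampling ",
                           "all of them instead of %d"), length(pool), n))
    n <- length(pool)
  }
  with_seed(seed, {
    cells <- sample(pool, n)
    rows <- (cells - 1) %% g$n_rows + 1
    cols <- (cells - 1) %/% g$n_rows + 1
    cc <- cell_centers(g, rows, cols)
    out <- point_set(data.frame(
      lon = cc$x + stats::runif(n, -0.5, 0.5) * g$cell_size,
      lat = cc$y + stats::runif(n, -0.5, 0.5) * g$cell_size), crs = g$crs)
    attr(out, "n_requested") <- n
    attr(out, "ecoregion_labels_used") <- occupied
    attr(out, "seed") <- seed
    out
  })
}

#' Assemble the weighted presence/background training table
#'
#' Extracts predictor values at presence and background points and attaches
#' the prevalence weights: presences weigh 1 and each absence weighs
#' `n_presence / n_absence`, so the weighted prevalence
#' `sum(w * y) / sum(w)` is balanced to 0.5 regardless of the class ratio.
#' Rows falling on masked predictor cells (or outside the grid) are dropped
#' and counted in the `n_dropped` attribute.
#'
#' @param occ Presence [point_set()].
#' @param bg Background [point_set()] from [sample_background()].
#' @param env An [env_stack()] of predictors.
#' @param species Species label.
#' @return A data frame of class `training_table` with columns `response`
#'   (1/0), `weight`, one column per predictor layer, `lon`, `lat`;
#'   attributes `species`, `layer_names`, `n_dropped`.
#' @export
training_table <- function(occ, bg, env, species = NULL) {
  stopifnot(inherits(env, "env_stack"))
  build <- function(pts, y) {
    pts <- as.data.frame(pts)
    rz <- rasterize_points(pts, env$grid)
    n_out <- length(rz$rejects)
    x <- stack_extract(env, rz$cells)
    keep <- stats::complete.cases(x)
    list(df = data.frame(response = rep(y, sum(keep)),
                         x[keep, , drop = FALSE],
                         lon = pts$lon[rz$cells$point][keep],
                         lat = pts$lat[rz$cells$point][keep],
                         check.names = FALSE),
         dropped = n_out + sum(!keep))
  }
  p <- build(occ, 1)
  a <- build(bg, 0)
  n_p <- nrow(p$df); n_a <- nrow(a$df)
  if (n_p == 0 || n_a == 0)
    stop("need at least one presence and one absence after dropping ",
         "masked rows")
  tab <- rbind(cbind(p$df, weight = 1),
               cbind(a$df, weight = n_p / n_a))
  tab <- tab[, c("response", "weight", names(env$layers), "lon", "lat")]
  rownames(tab) <- NULL
  if (is.null(species))
    species <- if ("species" %in% names(as.data.frame(occ)))
      as.character(as.data.frame(occ)$species[1]) else "unknown"
  structure(tab, species = species, layer_names = names(env$layers),
            n_dropped = p$dropped + a$dropped,
            class = c("training_table", "data.frame"))
}

#' Weighted prevalence of a training table
#'
#' @param table A [training_table()].
#' @return `sum(weight * response) / sum(weight)` — 0.5 by construction.
#' @export
weighted_prevalence <- function(table) {
  sum(table$weight * table$response) / sum(table$weight)
}
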