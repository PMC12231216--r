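#' Topographic heterogeneity from a DEM
#'
#' Local variability of elevation: by default the population standard
#' deviation of the DEM inside a `window x window` neighbourhood centred on
#' each cell. Masked cells are excluded from the neighbourhood; a cell whose
#' whole neighbourhood is masked becomes masked. `method = "tri"` gives the
#' terrain ruggedness index instead (mean absolute difference between the
#' centre and its neighbours; centre cell must be unmasked).
#'
#' @param dem A [raster_layer()] of elevations.
#' @param window Odd neighbourhood width, >= 3.
#' @param method `"sd"` (default) or `"tri"`.
#' @return A [raster_layer()] of heterogeneity values.
#' @export
topo_heterogeneity <- function(dem, window = 3, method = c("sd", "tri")) {
  method <- match.arg(method)
  if (window < 3 || window %% 2 == 0) stop("'window' must be odd and >= 3")
  if (all(dem$mask)) stop("DEM is fully masked")
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  half <- (window - 1) / 2
  v <- dem$values
  ok <- !dem$mask
  v0 <- ifelse(ok, v, 0)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- m[rs + dr, cs + dc]
    out
  }
  if (method == "sd") {
    s <- s2 <- cnt <- matrix(0, nr, nc)
    for (dr in -half:half) for (dc in -half:half) {
      s <- s + shift(v0, dr, dc)
      s2 <- s2 + shift(v0^2, dr, dc)
      cnt <- cnt + shift(ok + 0, dr, dc)
    }
    mu <- s / cnt
    out <- sqrt(pmax(s2 / cnt - mu^2, 0))
    out[cnt == 0] <- NA_real_
  } else {
    s <- cnt <- matrix(0, nr, nc)
    for (dr in -half:half) for (dc in -half:half) {
      if (dr == 0 && dc == 0) next
      nb_ok <- shift(ok + 0, dr, dc)
      s <- s + abs(shift(v0, dr, dc) - v0) * nb_ok
      cnt <- cnt + nb_ok
    }
    out <- s / cnt
    out[cnt == 0 | !ok] <- NA_real_
  }
  raster_layer(dem$grid, out)
}

#' Variance inflation factor of one predictor
#'
#' `VIF = 1 / (1 - R^2)` where `R^2` comes from the ordinary least-squares
#' regression of the named predictor on all the others (with intercept).
#' Perfect collinearity is reported as `Inf`.
#'
#' @param data Data frame or matrix of predictor columns only.
#' @param name Column whose VIF is wanted.
#' @return A single nonnegative number (possibly `Inf`).
#' @export
compute_vif <- function(data, name) {
  data <- as.data.frame(data)
  if (ncol(data) < 2) stop("VIF needs at least two predictors")
  if (!name %in% names(data)) stop("unknown predictor: ", name)
  if (nrow(data) < ncol(data) + 1)
    stop("too few rows for VIF: need at least n_predictors + 1")
  consts <- names(data)[vapply(data, function(x) stats::var(x) == 0,
                               logical(1))]
  if (length(consts))
    stop("constant predictor(s): ", paste(consts, collapse = ", "))
  y <- data[[name]]
  x <- as.matrix(data[setdiff(names(data), name)])
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

#' Stepwise VIF predictor selection
#'
#' Iteratively removes the predictor with the largest VIF while any VIF is
#' at or above the threshold, keeping earlier-listed predictors on ties,
#' until all remaining VIFs fall below the threshold (the screening rule
#' VIF < 10) or a single predictor remains.
#'
#' @param data Data frame or matrix of predictor columns only.
#' @param threshold Drop predictors while any VIF >= this value.
#' @return An object of class `vif_report`: `retained` (names, input
#'   order), `dropped` (data frame `name`, `vif_at_drop` in drop order),
#'   `final_vifs` (named vector, all < threshold unless one predictor
#'   remains), `threshold`.
#' @export
vif_select <- function(data, threshold = 10) {
  data <- as.data.frame(data)
  if (ncol(data) < 2) stop("VIF selection needs at least two predictors")
  current <- names(data)
  dropped <- data.frame(name = character(), vif_at_drop = numeric())
  repeat {
    if (length(current) < 2) break
    vifs <- vapply(current, function(nm)
      compute_vif(data[current], nm), numeric(1))
    if (max(vifs) < threshold) break
    # on ties drop the later-listed predictor so earlier-listed names survive
    worst <- max(which(vifs == max(vifs)))
    dropped <- rbind(dropped, data.frame(name = current[worst],
                                         vif_at_drop = vifs[[worst]]))
    current <- current[-worst]
  }
  final <- if (length(current) >= 2)
    vapply(current, function(nm) compute_vif(data[current], nm), numeric(1))
  else stats::setNames(rep(NA_real_, length(current)), current)
  structure(list(retained = current, dropped = dropped, final_vifs = final,
                 threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF selection (threshold %g): %d retained, %d dropped\n",
              x$threshold, length(x$retained), nrow(x$dropped)))
  if (length(x$final_vifs) && !all(is.na(x$final_vifs))) {
    cat("  retained VIFs:\n")
    for (nm in names(x$final_vifs))
      cat(sprintf("    %-20s %.3f\n", nm, x$final_vifs[[nm]]))
  }
  if (nrow(x$dropped))
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %-13s (VIF %.3g at removal)\n",
                  x$dropped$name[i], x$dropped$vif_at_drop[i]))
  invisible(x)
}
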