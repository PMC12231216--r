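# Independent brute-force oracles. These deliberately use the most naive
# formulation available (exhaustive pair enumeration, nested loops, direct
# normal equations) and share no code with the package internals.

oracle_haversine_km <- function(p, q) {
  to_rad <- pi / 180
  dlat <- (q[2] - p[2]) * to_rad
  dlon <- (q[1] - p[1]) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(p[2] * to_rad) * cos(q[2] * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(min(1, sqrt(a)))
}

oracle_auc <- function(scores, labels, weights = rep(1, length(scores))) {
  ip <- which(labels == 1); ia <- which(labels == 0)
  num <- 0; den <- 0
  for (i in ip) for (j in ia) {
    w <- weights[i] * weights[j]
    num <- num + w * (if (scores[i] > scores[j]) 1
                      else if (scores[i] == scores[j]) 0.5 else 0)
    den <- den + w
  }
  num / den
}

oracle_confusion <- function(scores, labels, threshold,
                             weights = rep(1, length(scores))) {
  pred <- scores >= threshold
  c(sensitivity = sum(weights[labels == 1 & pred]) /
      sum(weights[labels == 1]),
    specificity = sum(weights[labels == 0 & !pred]) /
      sum(weights[labels == 0]))
}

oracle_max_ss <- function(scores, labels, weights = rep(1, length(scores))) {
  cand <- c(-Inf, sort(unique(scores)))
  sums <- vapply(cand, function(t)
    sum(oracle_confusion(scores, labels, t, weights)), numeric(1))
  best <- cand[which(sums >= max(sums) - 1e-12)[1]]
  cs <- oracle_confusion(scores, labels, best, weights)
  list(threshold = best, sensitivity = cs[["sensitivity"]],
       specificity = cs[["specificity"]], sum = sum(cs))
}

oracle_distance_raster <- function(grid, cities, geographic = TRUE) {
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) for (c in seq_len(grid$n_cols)) {
    cx <- grid$x_origin + (c - 0.5) * grid$cell_size
    cy <- grid$y_origin - (r - 0.5) * grid$cell_size
    d <- Inf
    for (k in seq_len(nrow(cities))) {
      dk <- if (geographic)
        oracle_haversine_km(c(cx, cy), c(cities$lon[k], cities$lat[k]))
      else sqrt((cx - cities$lon[k])^2 + (cy - cities$lat[k])^2)
      d <- min(d, dk)
    }
    out[r, c] <- d
  }
  out
}

oracle_neighborhood_sd <- function(values, mask, window) {
  nr <- nrow(values); nc <- ncol(values)
  half <- (window - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (dr in -half:half) for (dc in -half:half) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && !mask[rr, cc])
        vals <- c(vals, values[rr, cc])
    }
    if (length(vals))
      out[r, c] <- sqrt(mean((vals - mean(vals))^2))
  }
  out
}

# VIF via explicit normal equations rather than lm
oracle_vif <- function(data, name) {
  y <- data[[name]]
  x <- cbind(1, as.matrix(data[setdiff(names(data), name)]))
  beta <- solve(t(x) %*% x, t(x) %*% y)
  r2 <- 1 - sum((y - x %*% beta)^2) / sum((y - mean(y))^2)
  1 / (1 - r2)
}

jaccard <- function(a, b) {
  sum(a == 1 & b == 1, na.rm = TRUE) / sum(a == 1 | b == 1, na.rm = TRUE)
}
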