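#' Fit an ensemble ecological niche model
#'
#' The central fitting function: trains the requested ensemble members on a
#' weighted presence/background [training_table()], optionally estimates
#' predictive performance by repeated stratified split-sample evaluation
#' ([repeated_split_evaluate()]), and refits every member on the full table
#' for prediction. Ensemble prediction is the weighted mean of the member
#' scores — uniform weights by default, or weights proportional to each
#' member's mean evaluation AUC (`weighting = "auc"`).
#'
#' @param table A [training_table()].
#' @param algorithms Character vector from `"glm"`, `"gam"`, `"gbm"`,
#'   `"rf"`, `"maxent"`; all five by default.
#' @param weighting `"uniform"` or `"auc"` member weighting.
#' @param evaluate Run the repeated split-sample evaluation (required for
#'   `weighting = "auc"`).
#' @param n_reps,train_frac Evaluation protocol: number of stratified
#'   splits (default 20) and training fraction (default 0.7).
#' @param control Named list of per-algorithm control overrides, e.g.
#'   `list(rf = list(num_trees = 250))`.
#' @param seed Master seed; member fits and every split derive their own
#'   seeds from it, so the whole object is reproducible.
#' @return An object of class `enm`: `members` (full-data fits), `weights`
#'   (named, summing to 1), `evaluation` (an `enm_eval` or `NULL`),
#'   `table`, `layer_names`, `species`, `seed`, `call`.
#' @seealso [predict.enm()], [binarize()], [repeated_split_evaluate()]
#' @export
#' @examples
#' \donttest{
#' land <- simulate_landscape(grid_spec(40, 40, 52, 32, 1 / 120), seed = 7)
#' vs <- virtual_species(land$env, list(intercept = 1,
#'   linear = c(env1 = 2, env2 = -2), quadratic = c(env1 = -6, env2 = -6)))
#' occ <- sample_occurrences(vs, 120, seed = 7)
#' bg <- sample_background(land$ecoregions, occupied_ecoregions(occ, land$ecoregions),
#'                         occ, n = 1000, seed = 7)
#' tab <- training_table(occ, bg, land$env)
#' fit <- enm(tab, algorithms = c("glm", "gbm"), n_reps = 3, seed = 7)
#' summary(fit)
#' }
enm <- function(table, algorithms = ALGORITHMS,
                weighting = c("uniform", "auc"), evaluate = TRUE,
                n_reps = 20, train_frac = 0.7, control = list(), seed = 1) {
  weighting <- match.arg(weighting)
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  if (weighting == "auc" && !evaluate)
    stop("'weighting = \"auc\"' requires evaluate = TRUE")
  layer_names <- attr(table, "layer_names") %||%
    setdiff(names(table), c("response", "weight", "lon", "lat"))
  evaluation <- if (evaluate)
    repeated_split_evaluate(table, algorithms = algorithms,
                            n_reps = n_reps, train_frac = train_frac,
                            control = control, seed = seed)
  members <- lapply(algorithms, function(a)
    fit_algorithm(a, table, layer_names = layer_names,
                  control = control[[a]] %||% list(),
                  seed = derive_seed(seed, paste0("fit-", a))))
  names(members) <- algorithms
  w <- if (weighting == "auc") {
    m <- evaluation$member_mean_auc[algorithms]
    m / sum(m)
  } else stats::setNames(rep(1 / length(algorithms), length(algorithms)),
                         algorithms)
  structure(list(members = members, weights = w, evaluation = evaluation,
                 table = table, layer_names = layer_names,
                 species = attr(table, "species") %||% "unknown",
                 weighting = weighting, seed = seed,
                 call = match.call()),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat("Ensemble niche model —", x$species, "\n")
  cat(sprintf("  members (%s weights): %s\n", x$weighting,
              paste(sprintf("%s (%.2f)", names(x$weights), x$weights),
                    collapse = ", ")))
  cat(sprintf("  training rows: %d presences, %d absences (weighted prevalence %.3f)\n",
              sum(x$table$response == 1), sum(x$table$response == 0),
              weighted_prevalence(x$table)))
  if (!is.null(x$evaluation))
    cat(sprintf("  evaluation: mean AUC %.3f, mean TSS %.3f over %d splits\n",
                x$evaluation$mean_auc, x$evaluation$mean_tss,
                nrow(x$evaluation$repetitions)))
  invisible(x)
}

#' @export
summary.enm <- function(object, ...) {
  structure(list(fit = object), class = "summary.enm")
}

#' @export
print.summary.enm <- function(x, ...) {
  print(x$fit)
  ev <- x$fit$evaluation
  if (!is.null(ev)) {
    cat("\nRepeated split-sample evaluation (held-out 30%):\n")
    print(ev)
  }
  invisible(x)
}

#' Predict habitat suitability from an ensemble model
#'
#' For an [env_stack()] the result is a suitability [raster_layer()] in
#' `[0, 1]`, masked wherever any predictor is masked, with provenance
#' (species, members, weights) attached; for a data frame of predictor
#' columns a numeric score vector is returned.
#'
#' @param object An [enm()] fit.
#' @param newdata An [env_stack()] or a data frame containing the training
#'   layers.
#' @param members Return the per-member score matrix/list instead of the
#'   ensemble mean.
#' @param ... Unused.
#' @export
predict.enm <- function(object, newdata, members = FALSE, ...) {
  if (inherits(newdata, "env_stack")) {
    g <- newdata$grid
    cc <- cell_centers(g)
    x <- as.data.frame(stack_extract(newdata, cc))
    ok <- stats::complete.cases(x)
    scores <- matrix(NA_real_, nrow(x), length(object$members),
                     dimnames = list(NULL, names(object$members)))
    for (a in names(object$members))
      scores[ok, a] <- predict(object$members[[a]], x[ok, , drop = FALSE])
    ens <- as.numeric(scores %*% object$weights)
    out <- raster_layer(g, matrix(ens, g$n_rows, g$n_cols),
                        mask = newdata$mask)
    attr(out, "provenance") <- list(species = object$species,
                                    algorithms = names(object$members),
                                    weights = object$weights,
                                    weighting = object$weighting)
    if (members) list(ensemble = out, member_scores = scores) else out
  } else {
    nd <- as.data.frame(newdata)
    scores <- vapply(object$members, function(m) predict(m, nd),
                     numeric(nrow(nd)))
    scores <- matrix(scores, nrow = nrow(nd),
                     dimnames = list(NULL, names(object$members)))
    if (members) scores else as.numeric(scores %*% object$weights)
  }
}

#' Ensemble a list of fitted members directly
#'
#' Lower-level ensemble prediction over an environmental stack: the
#' cellwise weighted mean of each member's scores.
#'
#' @param models List of `enm_member` objects (see [fit_algorithm()]).
#' @param env An [env_stack()].
#' @param weights Per-model weights; uniform by default, renormalized.
#' @return A suitability [raster_layer()].
#' @export
ensemble_predict <- function(models, env, weights = NULL) {
  if (!length(models)) stop("empty model list")
  if (is.null(weights)) weights <- rep(1, length(models))
  if (length(weights) != length(models) || any(weights < 0) ||
      sum(weights) == 0)
    stop("'weights' must be nonnegative, one per model, not all zero")
  weights <- weights / sum(weights)
  g <- env$grid
  x <- as.data.frame(stack_extract(env, cell_centers(g)))
  ok <- stats::complete.cases(x)
  ens <- rep(NA_real_, nrow(x))
  ens[ok] <- 0
  for (j in seq_along(models))
    ens[ok] <- ens[ok] + weights[j] * predict(models[[j]],
                                              x[ok, , drop = FALSE])
  raster_layer(g, matrix(ens, g$n_rows, g$n_cols), mask = env$mask)
}

#' Repeated stratified split-sample evaluation
#'
#' The evaluation protocol behind the reported AUC and TSS: `n_reps`
#' repetitions of a stratified 70/30 split (per class, `floor(train_frac *
#' n)` rows train, the remainder test), refitting the ensemble on the
#' training part and scoring the held-out part. Per repetition it records
#' the weighted held-out AUC and the TSS at the held-out
#' sensitivity-specificity-maximizing threshold; aggregates are means and
#' SDs over repetitions. Fully reproducible: the split memberships derive
#' from `seed`.
#'
#' @inheritParams enm
#' @return An object of class `enm_eval`: `repetitions` (data frame `rep`,
#'   `auc`, `tss`, `threshold`), `mean_auc`, `mean_tss`, `sd_auc`,
#'   `sd_tss`, `member_mean_auc`, `n_reps`, `train_frac`, `splits` (list of
#'   training-row index vectors).
#' @export
repeated_split_evaluate <- function(table, algorithms = ALGORITHMS,
                                    n_reps = 20, train_frac = 0.7,
                                    control = list(), seed = 1) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("'train_frac' must be strictly between 0 and 1")
  y <- table$response
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  if (length(idx1) < 2 || length(idx0) < 2)
    stop("each class needs at least 2 rows for split evaluation")
  n1 <- floor(train_frac * length(idx1))
  n0 <- floor(train_frac * length(idx0))
  if (n1 < 1 || n0 < 1 || n1 == length(idx1) || n0 == length(idx0))
    stop("split leaves an empty class; adjust 'train_frac' or add data")
  layer_names <- attr(table, "layer_names") %||%
    setdiff(names(table), c("response", "weight", "lon", "lat"))
  w <- if (!is.null(table$weight)) table$weight else rep(1, nrow(table))
  reps <- vector("list", n_reps)
  member_auc <- matrix(NA_real_, n_reps, length(algorithms),
                       dimnames = list(NULL, algorithms))
  splits <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    split_seed <- derive_seed(seed, paste0("split-", r))
    train <- with_seed(split_seed,
                       c(sample(idx1, n1), sample(idx0, n0)))
    test <- setdiff(seq_along(y), train)
    splits[[r]] <- sort(train)
    tr_tab <- table[train, , drop = FALSE]
    attr(tr_tab, "layer_names") <- layer_names
    scores <- matrix(NA_real_, length(test), length(algorithms),
                     dimnames = list(NULL, algorithms))
    for (a in algorithms) {
      m <- fit_algorithm(a, tr_tab, layer_names = layer_names,
                         control = control[[a]] %||% list(),
                         seed = derive_seed(split_seed, a))
      scores[, a] <- predict(m, table[test, , drop = FALSE])
      member_auc[r, a] <- auc(scores[, a], y[test], w[test])
    }
    ens <- rowMeans(scores)
    mx <- max_ss_threshold(ens, y[test], w[test])
    reps[[r]] <- data.frame(rep = r, auc = auc(ens, y[test], w[test]),
                            tss = mx$tss, threshold = mx$threshold)
  }
  repetitions <- do.call(rbind, reps)
  structure(list(repetitions = repetitions,
                 mean_auc = mean(repetitions$auc),
                 mean_tss = mean(repetitions$tss),
                 sd_auc = stats::sd(repetitions$auc),
                 sd_tss = stats::sd(repetitions$tss),
                 member_mean_auc = colMeans(member_auc),
                 n_reps = n_reps, train_frac = train_frac,
                 splits = splits, seed = seed),
            class = "enm_eval")
}

#' @export
print.enm_eval <- function(x, ...) {
  cat(sprintf("split-sample evaluation: %d repetitions, train fraction %.2f\n",
              x$n_reps, x$train_frac))
  cat(sprintf("  ensemble AUC %.3f (sd %.3f), TSS %.3f (sd %.3f)\n",
              x$mean_auc, x$sd_auc, x$mean_tss, x$sd_tss))
  cat("  member mean AUC:",
      paste(sprintf("%s %.3f", names(x$member_mean_auc),
                    x$member_mean_auc), collapse = ", "), "\n")
  invisible(x)
}

#' Plot an ensemble model
#'
#' Without `env`, draws the per-repetition evaluation AUC and TSS; with an
#' [env_stack()], draws the predicted suitability map.
#'
#' @param x An [enm()] fit.
#' @param env Optional [env_stack()] to map suitability over.
#' @param ... Passed to the underlying plotting function.
#' @export
plot.enm <- function(x, env = NULL, ...) {
  if (!is.null(env)) {
    plot(predict(x, env), main = paste("ensemble suitability —", x$species),
         ...)
  } else if (!is.null(x$evaluation)) {
    rp <- x$evaluation$repetitions
    graphics::boxplot(list(AUC = rp$auc, TSS = rp$tss),
                      main = "held-out performance over repetitions", ...)
  } else {
    stop("nothing to plot: no evaluation stored and no 'env' given")
  }
  invisible(x)
}

#' Binarize a suitability map by sensitivity-specificity maximization
#'
#' Recomputes the ensemble scores at the training rows, finds the
#' [max_ss_threshold()], and thresholds the suitability map at it
#' (`suitability >= threshold` is mapped to 1). The threshold and rule are
#' attached to the result.
#'
#' @param object An [enm()] fit (method `binarize.enm`) or a suitability
#'   [raster_layer()] (method `binarize.raster_layer`, which needs
#'   `scores`, `labels`, `weights`).
#' @param ... Method arguments.
#' @return A binary [raster_layer()] (values 0/1, masked cells `NA`) with
#'   attributes `threshold`, `rule = "max-sens-spec-sum"`, `species`.
#' @export
binarize <- function(object, ...) UseMethod("binarize")

#' @rdname binarize
#' @param env An [env_stack()] to predict and threshold over.
#' @param table Training table supplying the thresholding rows; defaults to
#'   the table the model was fitted on.
#' @export
binarize.enm <- function(object, env, table = object$table, ...) {
  suit <- predict(object, env)
  scores <- predict(object, table)
  binarize(suit, scores = scores, labels = table$response,
           weights = table$weight, species = object$species)
}

#' @rdname binarize
#' @param scores,labels,weights Scores at the training rows and their 0/1
#'   labels and weights, used to locate the threshold.
#' @param species Species tag carried into the map attributes.
#' @export
binarize.raster_layer <- function(object, scores, labels, weights = NULL,
                                  species = "unknown", ...) {
  mx <- max_ss_threshold(scores, labels, weights)
  out <- raster_map1(object, function(v) (v >= mx$threshold) + 0)
  attr(out, "threshold") <- mx$threshold
  attr(out, "rule") <- "max-sens-spec-sum"
  attr(out, "species") <- species
  attr(out, "sensitivity") <- mx$sensitivity
  attr(out, "specificity") <- mx$specificity
  out
}
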