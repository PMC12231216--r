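# Adapters for the five ensemble members. Each takes the weighted training
# table and returns an object with a unified predict_scores() contract:
# scores in [0, 1] for any predictor data frame over the training layers.
# All members consume the row weights (weighted likelihood, weighted
# deviance or weighted bootstrap as appropriate) and are deterministic
# given the seed.

ALGORITHMS <- c("glm", "gam", "gbm", "rf", "maxent")

default_control <- function(name) {
  switch(name,
    glm = list(),
    gam = list(k = 10),
    gbm = list(nrounds = 100, eta = 0.1, max_depth = 3, subsample = 0.7),
    rf = list(num_trees = 500, min_node_size = 5),
    maxent = list(n_knots = 10, holdout_frac = 0.2, nlambda = 60),
    stop("unknown algorithm: ", name))
}

#' Fit one ensemble member
#'
#' Realizations: `glm` — weighted binomial GLM with linear and quadratic
#' terms per layer; `gam` — weighted binomial additive model with a
#' thin-plate smooth per layer (mgcv); `gbm` — weighted stochastic
#' gradient-boosted trees (xgboost, logistic objective); `rf` — probability
#' random forest with the row weights as bootstrap case weights (ranger);
#' `maxent` — L1-penalized weighted logistic regression on a linear +
#' quadratic + pairwise-product + hinge feature expansion (glmnet), the
#' penalized-logistic formulation of Maxent, with the penalty chosen by
#' weighted deviance on an internal stratified 20% holdout.
#'
#' @param name One of `"glm"`, `"gam"`, `"gbm"`, `"rf"`, `"maxent"`.
#' @param table A [training_table()] (any data frame with `response`,
#'   `weight` and predictor columns works).
#' @param layer_names Predictor columns; defaults to the table's
#'   `layer_names` attribute.
#' @param control Named list overriding the algorithm's hyperparameter
#'   defaults (see `stingrisk:::default_control`).
#' @param seed Integer seed for the stochastic members.
#' @return An object of class `enm_member` with a `predict_scores(newdata)`
#'   closure; scores are probabilities in `[0, 1]`.
#' @export
fit_algorithm <- function(name, table, layer_names = NULL,
                          control = list(), seed = 1) {
  name <- match.arg(name, ALGORITHMS)
  if (is.null(layer_names))
    layer_names <- attr(table, "layer_names") %||%
      setdiff(names(table), c("response", "weight", "lon", "lat"))
  y <- table$response
  if (length(unique(y)) < 2)
    stop("degenerate training table: both classes required")
  w <- if (!is.null(table$weight)) table$weight else rep(1, nrow(table))
  x <- as.data.frame(table)[layer_names]
  ctrl <- utils::modifyList(default_control(name), control)
  fitted <- with_seed(seed, switch(name,
    glm = fit_glm(x, y, w, layer_names),
    gam = fit_gam(x, y, w, layer_names, ctrl),
    gbm = fit_gbm(x, y, w, ctrl, seed),
    rf = fit_rf(x, y, w, ctrl, seed),
    maxent = fit_maxent(x, y, w, ctrl, seed)))
  structure(list(algorithm = name, layer_names = layer_names,
                 control = ctrl, seed = seed, fit = fitted$fit,
                 predict_scores = fitted$predict_scores,
                 n_presence = sum(y == 1), n_absence = sum(y == 0)),
            class = "enm_member")
}

#' @export
print.enm_member <- function(x, ...) {
  cat(sprintf("enm_member '%s' on %d layer(s); trained on %d presences / %d absences\n",
              x$algorithm, length(x$layer_names), x$n_presence, x$n_absence))
  invisible(x)
}

#' @export
predict.enm_member <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$layer_names, names(newdata))
  if (length(missing))
    stop("newdata lacks layer(s): ", paste(missing, collapse = ", "))
  p <- object$predict_scores(newdata[object$layer_names])
  pmin(pmax(as.numeric(p), 0), 1)
}

fit_glm <- function(x, y, w, layer_names) {
  df <- cbind(response = y, x)
  rhs <- paste(vapply(layer_names, function(nm)
    sprintf("`%s` + I(`%s`^2)", nm, nm), character(1)), collapse = " + ")
  fml <- stats::as.formula(paste("response ~", rhs))
  fit <- suppressWarnings(
    stats::glm(fml, data = df, family = stats::binomial(), weights = w))
  list(fit = fit, predict_scores = function(nd)
    suppressWarnings(stats::predict(fit, newdata = nd, type = "response")))
}

fit_gam <- function(x, y, w, layer_names, ctrl) {
  df <- cbind(response = y, x)
  # k is capped by the number of distinct values per layer
  terms <- vapply(layer_names, function(nm) {
    k <- min(ctrl$k, length(unique(x[[nm]])) - 1)
    if (k >= 3) sprintf("s(`%s`, k = %d)", nm, k) else sprintf("`%s`", nm)
  }, character(1))
  fml <- stats::as.formula(paste("response ~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(
    mgcv::gam(fml, data = df, family = stats::binomial(), weights = w,
              method = "REML"))
  list(fit = fit, predict_scores = function(nd)
    as.numeric(suppressWarnings(
      mgcv::predict.gam(fit, newdata = nd, type = "response"))))
}

fit_gbm <- function(x, y, w, ctrl, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, weight = w)
  params <- list(objective = "binary:logistic", eta = ctrl$eta,
                 max_depth = ctrl$max_depth, subsample = ctrl$subsample,
                 nthread = 1, seed = seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = ctrl$nrounds, verbose = 0)
  nms <- colnames(x)
  list(fit = fit, predict_scores = function(nd)
    stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(nd[nms]))))
}

fit_rf <- function(x, y, w, ctrl, seed) {
  df <- cbind(response = factor(y, levels = c(0, 1)), x)
  fit <- ranger::ranger(response ~ ., data = df, probability = TRUE,
                        num.trees = ctrl$num_trees,
                        min.node.size = ctrl$min_node_size,
                        case.weights = w, seed = seed, num.threads = 1)
  list(fit = fit, predict_scores = function(nd)
    stats::predict(fit, data = nd, num.threads = 1)$predictions[, "1"])
}

# Maxent feature expansion: per layer the linear and squared terms and
# forward/reverse hinges at n_knots interior quantile knots; plus all
# pairwise products of the linear terms.
maxent_features <- function(x, knots) {
  nms <- names(knots)
  cols <- list()
  for (nm in nms) {
    v <- x[[nm]]
    cols[[nm]] <- v
    cols[[paste0(nm, "^2")]] <- v^2
    for (k in knots[[nm]]) {
      cols[[sprintf("h+(%s,%.6g)", nm, k)]] <- pmax(0, v - k)
      cols[[sprintf("h-(%s,%.6g)", nm, k)]] <- pmax(0, k - v)
    }
  }
  if (length(nms) > 1) {
    pairs <- utils::combn(nms, 2)
    for (j in seq_len(ncol(pairs)))
      cols[[paste(pairs[1, j], pairs[2, j], sep = "*")]] <-
        x[[pairs[1, j]]] * x[[pairs[2, j]]]
  }
  do.call(cbind, cols)
}

fit_maxent <- function(x, y, w, ctrl, seed) {
  knots <- lapply(x, function(v)
    unique(stats::quantile(v, probs = seq_len(ctrl$n_knots) /
                             (ctrl$n_knots + 1), names = FALSE)))
  feats <- maxent_features(x, knots)
  # stratified internal holdout to pick lambda by weighted deviance
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  hold <- c(sample(idx1, max(1, floor(ctrl$holdout_frac * length(idx1)))),
            sample(idx0, max(1, floor(ctrl$holdout_frac * length(idx0)))))
  tr <- setdiff(seq_along(y), hold)
  path <- glmnet::glmnet(feats[tr, , drop = FALSE], y[tr],
                         family = "binomial", weights = w[tr],
                         alpha = 1, nlambda = ctrl$nlambda)
  p_hold <- stats::predict(path, feats[hold, , drop = FALSE],
                           type = "response")
  eps <- 1e-12
  dev <- apply(p_hold, 2, function(p)
    -2 * sum(w[hold] * (y[hold] * log(pmax(p, eps)) +
                          (1 - y[hold]) * log(pmax(1 - p, eps)))))
  lam <- path$lambda[which.min(dev)]
  fit <- glmnet::glmnet(feats, y, family = "binomial", weights = w,
                        alpha = 1, lambda = lam)
  list(fit = fit, predict_scores = function(nd)
    as.numeric(stats::predict(fit, maxent_features(nd, knots),
                              type = "response")))
}
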