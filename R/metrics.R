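# Threshold-free and threshold-dependent discrimination metrics for
# weighted presence/background data.

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
}

#' Weighted AUC (Mann-Whitney form)
#'
#' Probability that a randomly drawn presence outscores a randomly drawn
#' absence, with ties counting one half and each presence/absence pair
#' weighted by the product of the row weights. Rank-based, so invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 response, both classes present.
#' @param weights Positive row weights; unit weights by default.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, weights = NULL) {
  check_two_classes(labels)
  if (is.null(weights)) weights <- rep(1, length(scores))
  stopifnot(length(scores) == length(labels),
            length(weights) == length(labels))
  o <- order(scores)
  s <- scores[o]; y <- labels[o]; w <- weights[o]
  # aggregate weights per distinct score value
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  wp <- tapply(w * (y == 1), grp, sum)
  wa <- tapply(w * (y == 0), grp, sum)
  cum_wa <- c(0, cumsum(wa)[-length(wa)]) # absence weight strictly below
  conc <- sum(wp * cum_wa) + 0.5 * sum(wp * wa)
  conc / (sum(wp) * sum(wa))
}

#' Weighted sensitivity and specificity at a threshold
#'
#' Presences scoring at or above the threshold are predicted present.
#' Sensitivity is the weighted fraction of presences predicted present;
#' specificity the weighted fraction of absences predicted absent.
#'
#' @inheritParams auc
#' @param threshold Classification threshold (score `>= threshold` is a
#'   predicted presence).
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
confusion_at <- function(scores, labels, threshold, weights = NULL) {
  check_two_classes(labels)
  if (is.null(weights)) weights <- rep(1, length(scores))
  pred <- scores >= threshold
  c(sensitivity = sum(weights * (labels == 1 & pred)) /
      sum(weights * (labels == 1)),
    specificity = sum(weights * (labels == 0 & !pred)) /
      sum(weights * (labels == 0)))
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`, ranging from -1 to 1 with 0 for
#' no skill.
#'
#' @param sensitivity,specificity Values in `[0, 1]`, e.g. from
#'   [confusion_at()].
#' @return The TSS value.
#' @export
tss <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Sensitivity-specificity sum maximizing threshold
#'
#' Scans the candidate thresholds (the observed distinct scores, plus a
#' `-Inf` sentinel where everything is predicted present) and returns the
#' one maximizing sensitivity + specificity; ties are broken by the
#' smallest such threshold. This is the binarization rule used to turn
#' continuous suitability into presence/absence range maps.
#'
#' @inheritParams auc
#' @return A list with `threshold`, `sensitivity`, `specificity` (and the
#'   implied `tss`).
#' @export
max_ss_threshold <- function(scores, labels, weights = NULL) {
  check_two_classes(labels)
  if (is.null(weights)) weights <- rep(1, length(scores))
  o <- order(scores)
  s <- scores[o]; y <- labels[o]; w <- weights[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  u <- s[!duplicated(grp)]
  wp <- as.numeric(tapply(w * (y == 1), grp, sum))
  wa <- as.numeric(tapply(w * (y == 0), grp, sum))
  wp_tot <- sum(wp); wa_tot <- sum(wa)
  # candidate thresholds: -Inf (all predicted present) then each distinct
  # score; at threshold u[k], groups < k fall below it
  cand <- c(-Inf, u)
  sens <- c(1, 1 - c(0, cumsum(wp)[-length(wp)]) / wp_tot)
  spec <- c(0, c(0, cumsum(wa)[-length(wa)]) / wa_tot)
  ss <- sens + spec
  best <- which(ss >= max(ss) - 1e-12)[1] # smallest threshold among ties
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], tss = ss[best] - 1)
}
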