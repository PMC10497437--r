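#' ROC analysis with empirical thresholds
#'
#' Builds the full empirical ROC over all unique score values plus a
#' sentinel threshold that calls nothing positive. With the default
#' `"greater"` orientation (higher variability parameters indicate a
#' T2-positive segment) a positive call is score >= threshold. The AUC is
#' computed two ways — trapezoidal area under (1 - specificity,
#' sensitivity) and the midrank Mann-Whitney statistic U / (n1 * n0) —
#' and the two must agree to 1e-12; the rank form is stored.
#'
#' @param scores Numeric scores (e.g. per-segment T2-MI).
#' @param labels Binary labels (logical or 0/1); 1 = positive class. Both
#'   classes must be present.
#' @param direction `"greater"` (default): higher scores indicate the
#'   positive class; `"less"`: lower scores do (positive call is
#'   score <= threshold).
#' @return A [RocResult-class].
#' @examples
#' roc <- rocAnalysis(c(2, 4, 1, 3), c(1, 1, 0, 0))
#' auc(roc)  # 0.75
#' @export
rocAnalysis <- function(scores, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    .cordError("inputError", "scores and labels must match and be complete")
  if (!any(labels) || all(labels))
    .cordError("inputError", "both label classes must be present")
  s <- if (direction == "greater") scores else -scores
  thr <- c(sort(unique(s)), Inf)
  pos <- s[labels]; neg <- s[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), 1)
  spec <- vapply(thr, function(t) mean(neg < t), 1)

  # trapezoid over the ROC path, ascending false-positive rate
  fpr <- rev(1 - spec); tpr <- rev(sens)
  aucTrap <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  r <- rank(s)
  n1 <- length(pos); n0 <- length(neg)
  aucU <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (abs(aucTrap - aucU) > 1e-12)
    .cordError("internalError",
               "trapezoidal and rank AUC disagree (%.3g)", aucTrap - aucU)

  if (direction == "less") {  # map thresholds back to the original scale
    thr <- -thr
    ord <- order(thr)
    thr <- thr[ord]; sens <- sens[ord]; spec <- spec[ord]
  }
  new("RocResult", thresholds = thr, sensitivity = sens, specificity = spec,
      auc = aucU, direction = direction)
}

#' All Youden-optimal cutoffs
#'
#' Returns every threshold maximizing Youden's J = sensitivity +
#' specificity - 1, in ascending threshold order. Ties are surfaced, never
#' silently broken: co-optimal cutoffs are all reported.
#'
#' @param roc A [RocResult-class].
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`; one row per co-optimal threshold.
#' @export
youdenCutoffs <- function(roc) {
  stopifnot(is(roc, "RocResult"))
  j <- roc@sensitivity + roc@specificity - 1
  keep <- which(j >= max(j) - 1e-12)
  out <- data.frame(threshold = roc@thresholds[keep],
                    sensitivity = roc@sensitivity[keep],
                    specificity = roc@specificity[keep],
                    youden_j = j[keep])
  out[order(out$threshold), , drop = FALSE]
}

#' Closest-to-top-left ROC cutoff
#'
#' The threshold minimizing the Euclidean distance of the ROC point to the
#' ideal corner (false-positive rate 0, sensitivity 1):
#' sqrt((1 - sens)^2 + (1 - spec)^2). Ties go to the smaller threshold.
#'
#' @param roc A [RocResult-class].
#' @return One-row data frame: `threshold`, `sensitivity`, `specificity`,
#'   `distance`.
#' @export
closestTopLeftCutoff <- function(roc) {
  stopifnot(is(roc, "RocResult"))
  d <- sqrt((1 - roc@sensitivity)^2 + (1 - roc@specificity)^2)
  ord <- order(d, roc@thresholds)
  i <- ord[1L]
  data.frame(threshold = roc@thresholds[i], sensitivity = roc@sensitivity[i],
             specificity = roc@specificity[i], distance = d[i])
}

#' Export a ROC curve as a data frame
#'
#' @param x A [RocResult-class].
#' @param ... Ignored.
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
as.data.frame.RocResult <- function(x, ...) {
  data.frame(threshold = x@thresholds, sensitivity = x@sensitivity,
             specificity = x@specificity)
}
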