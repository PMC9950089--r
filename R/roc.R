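#' ROC curve over a candidate threshold grid
#'
#' Computes sensitivity and specificity of the rule "positive iff score
#' compared to threshold per `direction`" at every candidate threshold,
#' the trapezoidal AUC over (1 - specificity, sensitivity), and the
#' Youden-optimal cutoff (maximal sensitivity + specificity; ties resolved
#' to the smallest threshold).
#'
#' @param scores numeric per-observation feature values.
#' @param truth logical (or 0/1) per-observation positive-class labels.
#' @param grid candidate thresholds, ordered.
#' @param direction `"ge"`: positive when `score >= threshold`;
#'   `"le"`: positive when `score <= threshold`.
#' @return object of class `walk_roc`: data.frame `curve` (threshold,
#'   sensitivity, specificity, youden), `auc`, `optimal`.
#' @export
roc_tune <- function(scores, truth, grid, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  ok <- !is.na(truth)
  scores <- scores[ok]; truth <- truth[ok]
  if (length(scores) != length(truth)) stop("scores and truth differ in length")
  if (!any(truth) || all(truth))
    stop("degenerate input: both classes must be present")
  grid <- sort(grid)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  sens <- spec <- numeric(length(grid))
  for (i in seq_along(grid)) {
    pred <- if (direction == "ge") scores >= grid[i] else scores <= grid[i]
    pred[is.na(pred)] <- FALSE
    sens[i] <- sum(pred & truth) / n_pos
    spec[i] <- sum(!pred & !truth) / n_neg
  }
  curve <- data.frame(threshold = grid, sensitivity = sens,
                      specificity = spec, youden = sens + spec - 1)
  opt <- grid[which.max(sens + spec)]  # which.max takes first (smallest) tie
  structure(list(curve = curve, auc = roc_auc(1 - spec, sens),
                 optimal = opt, direction = direction),
            class = "walk_roc")
}

# Trapezoidal AUC over operating points, endpoints (0,0) and (1,1) added.
roc_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord], 1); y <- c(0, tpr[ord], 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.walk_roc <- function(x, ...) {
  cat(sprintf("<walk_roc> AUC = %.3f, Youden-optimal threshold = %g (%s)\n",
              x$auc, x$optimal, x$direction))
  invisible(x)
}

#' @export
plot.walk_roc <- function(x, ...) {
  plot(1 - x$curve$specificity, x$curve$sensitivity, type = "b", pch = 16,
       cex = 0.6, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  i <- which.max(x$curve$youden)
  points(1 - x$curve$specificity[i], x$curve$sensitivity[i], col = "red",
         pch = 19)
  invisible(x)
}
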