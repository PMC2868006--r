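# Evaluation of imbalanced binary PPI prediction: confusion-matrix
# metrics, trivial baseline predictors, precision-sensitivity curves and
# aggregation over repeated random dataset draws.

#' Confusion counts from labels and predictions
#'
#' @param truth,predicted Logical vectors (`TRUE` = interacting) of equal
#'   length.
#' @return Named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(truth, predicted) {
    stopifnot(is.logical(truth), is.logical(predicted),
              length(truth) == length(predicted), !anyNA(truth),
              !anyNA(predicted))
    c(TP = sum(truth & predicted), FP = sum(!truth & predicted),
      TN = sum(!truth & !predicted), FN = sum(truth & !predicted))
}

#' Classification metric panel
#'
#' The five standard measurements for binary classification:
#' precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/total` and F-measure
#' `2TP/(2TP+FP+FN)`.  A ratio with zero denominator is reported as `NA`
#' (never silently 0); the one exception is the F-measure with `TP = 0`
#' but a positive denominator, which is exactly 0 by its own formula.
#' On a 1:r dataset the all-negative predictor therefore scores accuracy
#' `r/(r+1)` — 93.8% at 1:15 — while its F-measure is 0, which is why
#' accuracy is a misleading objective under class imbalance.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN` (from
#'   [confusionCounts()]).
#' @return Named list with `precision`, `sensitivity`, `specificity`,
#'   `accuracy`, `f_measure`, all in \[0, 1\] or `NA` where undefined.
#' @examples
#' computeMetrics(c(TP = 2, FP = 1, TN = 12, FN = 1))
#' @export
computeMetrics <- function(counts) {
    need <- c("TP", "FP", "TN", "FN")
    stopifnot(all(need %in% names(counts)))
    counts <- counts[need]
    if (any(counts < 0)) .stopf("confusion counts must be non-negative")
    total <- sum(counts)
    if (total == 0) .stopf("no evaluated instances (all counts zero)")
    tp <- counts[["TP"]]; fp <- counts[["FP"]]
    tn <- counts[["TN"]]; fn <- counts[["FN"]]
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    list(precision   = ratio(tp, tp + fp),
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         accuracy    = (tp + tn) / total,
         f_measure   = ratio(2 * tp, 2 * tp + fp + fn))
}

#' Trivial baseline predictors
#'
#' `random` predicts interacting with probability 0.5 per instance;
#' `opportunistic_neg` always predicts non-interacting (maximises accuracy
#' on imbalanced data without detecting anything); `opportunistic_pos`
#' always predicts interacting (maximises sensitivity and, among the
#' constant predictors, F-measure).
#'
#' @param kind One of `"random"`, `"opportunistic_neg"`,
#'   `"opportunistic_pos"`.
#' @param n Number of instances.
#' @param seed Seed for the random baseline.
#' @return Logical prediction vector of length `n`.
#' @export
baselinePredict <- function(kind = c("random", "opportunistic_neg",
                                     "opportunistic_pos"),
                            n, seed = 1L) {
    kind <- match.arg(kind)
    stopifnot(n >= 1)
    switch(kind,
           random = .withSeed(seed, stats::runif(n) < 0.5),
           opportunistic_neg = rep(FALSE, n),
           opportunistic_pos = rep(TRUE, n))
}

#' Precision-sensitivity curve
#'
#' Sweeps a decision threshold over the unique scores in descending order
#' (instances scoring at least the threshold are predicted interacting);
#' tied scores are grouped at a single threshold, with no interpolation
#' between points.  The final point predicts everything positive and
#' therefore has sensitivity 1 and precision equal to the positive
#' prevalence or higher.
#'
#' @param scores Numeric decision scores (higher = more likely
#'   interacting).
#' @param labels Logical true labels; both classes must be present.
#' @return Data frame with columns `threshold`, `precision`,
#'   `sensitivity`, one row per distinct threshold.
#' @export
prCurve <- function(scores, labels) {
    stopifnot(is.numeric(scores), is.logical(labels),
              length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
    if (!any(labels) || all(labels)) {
        .stopf("precision-sensitivity curve needs both classes present")
    }
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- labels[ord]
    cumTP <- cumsum(y)
    cumP <- seq_along(y)
    last <- cumP[!duplicated(s, fromLast = TRUE)]  # last index of each tie group
    data.frame(threshold = s[last],
               precision = cumTP[last] / cumP[last],
               sensitivity = cumTP[last] / sum(y))
}

#' Aggregate metric panels over repetitions
#'
#' @param panels List of metric panels (from [computeMetrics()]), one per
#'   repeated dataset draw; at least two.
#' @return Data frame with one row per metric and columns `mean` and `sd`
#'   (sample standard deviation across repetitions, the dispersion used in
#'   `mean +/- sd` reporting), both on the \[0, 1\] scale.
#' @export
aggregateRepetitions <- function(panels) {
    stopifnot(is.list(panels), length(panels) >= 2L)
    metrics <- names(panels[[1L]])
    m <- vapply(panels, function(p) unlist(p[metrics]),
                numeric(length(metrics)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    data.frame(metric = metrics,
               mean = rowMeans(m),
               sd = apply(m, 1L, stats::sd),
               row.names = NULL)
}

#' Format a metric value as a percentage
#'
#' @param x Numeric value(s) in \[0, 1\] (or `NA`).
#' @param digits Decimal places (default 1, the conventional reporting
#'   precision).
#' @return Character vector like `"93.8"`; `NA` becomes `"undef"`.
#' @export
formatPercent <- function(x, digits = 1L) {
    ifelse(is.na(x), "undef", formatC(100 * x, format = "f", digits = digits))
}

#' F-measure ceiling of a perfect predictor under incomplete annotation
#'
#' If the full interactome holds `pinSize` interactions but only
#' `knownInteractions` of them are annotated as positives, a predictor that
#' recovers every true interaction still has precision
#' `known/pinSize`, so its F-measure cannot exceed
#' `2*known/(known + pinSize)`.  With ~17,855 curated in-vivo pairs against
#' an estimated ~650,000-interaction human interactome this ceiling is
#' about 5.3%, i.e. below 6% — the reason comprehensive-dataset F-measures
#' are overly pessimistic.
#'
#' @param knownInteractions Number of annotated positive pairs.
#' @param pinSize Estimated total interactions in the network.
#' @return The F-measure bound on the \[0, 1\] scale.
#' @examples
#' formatPercent(perfectPredictorFBound(17855, 650000))
#' @export
perfectPredictorFBound <- function(knownInteractions, pinSize) {
    stopifnot(knownInteractions >= 1, pinSize >= knownInteractions)
    2 * knownInteractions / (knownInteractions + pinSize)
}
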