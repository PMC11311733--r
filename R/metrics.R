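#' Area under the ROC curve (Mann-Whitney form)
#'
#' Tie-corrected AUC computed from midranks: the probability that a random
#' case scores above a random control, counting ties as 1/2.
#'
#' @param scores numeric classifier scores.
#' @param y binary labels (1 = case).
#' @return AUC in [0, 1].
#' @export
aucMW <- function(scores, y) {
    checkBinaryLabels(y)
    r <- rank(scores)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-integrated area under the precision-recall curve: precision is
#' evaluated at each distinct score threshold and weighted by the recall
#' increment it contributes. With constant scores this reduces to the
#' prevalence.
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param y binary labels (1 = case).
#' @return average precision in [0, 1].
#' @export
averagePrecision <- function(scores, y) {
    checkBinaryLabels(y)
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; yy <- y[o]
    tp <- cumsum(yy == 1); fp <- cumsum(yy == 0)
    last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each threshold
    tp <- tp[last]; fp <- fp[last]
    n1 <- sum(y == 1)
    dtp <- diff(c(0, tp))
    prec <- tp / (tp + fp)
    sum(dtp / n1 * prec)
}

#' Composite classification metrics: AUC, average PPV, average NPV
#'
#' Average PPV is the area under the precision-recall (PPV versus
#' sensitivity) curve; average NPV is the same quantity for the negative
#' class, i.e. the area under the NPV-specificity curve obtained by
#' reversing scores and labels.
#'
#' @param scores numeric classifier scores.
#' @param y binary labels (1 = case).
#' @return named numeric vector `c(auc, avg_ppv, avg_npv)`.
#' @export
evaluateMetrics <- function(scores, y) {
    c(auc = aucMW(scores, y),
      avg_ppv = averagePrecision(scores, y),
      avg_npv = averagePrecision(-scores, 1 - y))
}
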