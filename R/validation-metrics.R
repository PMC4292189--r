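# Figures of merit for two-class discriminant models: NMC, AUROC
# (Mann-Whitney formulation) and discriminant Q2.

#' Number of misclassifications
#'
#' @param truth,predicted label vectors of equal length.
#' @return integer count of positions where the labels differ.
#' @export
nmc <- function(truth, predicted) {
    if (length(truth) != length(predicted))
        stop("'truth' and 'predicted' must have equal length")
    sum(as.character(truth) != as.character(predicted))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random
#' positive-negative pair is ordered correctly by the scores, with ties
#' counted one half. Positives are the subjects coded 1. A value of 1 is
#' perfect separation; 0.5 is chance level (scores carrying no class
#' information), and values below 0.5 indicate inverted ranking.
#'
#' @param scores numeric vector of predicted responses (higher = more
#'   positive-like).
#' @param truth 0/1 vector of true class codes.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, truth) {
    if (length(scores) != length(truth))
        stop("'scores' and 'truth' must have equal length")
    if (any(!is.finite(scores))) stop("non-finite scores")
    truth <- as.numeric(truth)
    nPos <- sum(truth == 1); nNeg <- sum(truth == 0)
    if (nPos == 0 || nNeg == 0)
        stop("both classes must be present to compute AUROC")
    r <- rank(scores)  # midranks handle ties as 1/2
    (sum(r[truth == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Discriminant Q2
#'
#' Cross-validated explained variance adapted to classification:
#' \eqn{DQ^2 = 1 - PRESS_D / TSS} with \eqn{TSS = \sum (y - \bar y)^2},
#' where per-subject residuals are truncated so that predictions beyond
#' the class code in the correct direction (above 1 for class 1, below 0
#' for class 0) contribute zero error — a model is not penalised for
#' predicting "too correctly". With no overshoot DQ2 equals the ordinary
#' Q2; unlike Q2 it is not bounded below and can be negative for models
#' worse than the class-mean predictor.
#'
#' @param yPred numeric vector of predicted dummy responses.
#' @param truth 0/1 vector of true class codes; both classes must be
#'   present (otherwise the total sum of squares is zero).
#' @return DQ2, a real number at most 1.
#' @export
dq2 <- function(yPred, truth) {
    if (length(yPred) != length(truth))
        stop("'yPred' and 'truth' must have equal length")
    truth <- as.numeric(truth)
    tss <- sum((truth - mean(truth))^2)
    if (tss <= 0)
        stop("total sum of squares is zero (single-class input)")
    resid <- truth - yPred
    resid[truth == 1 & yPred > 1] <- 0
    resid[truth == 0 & yPred < 0] <- 0
    1 - sum(resid^2) / tss
}

# Merits of a vector of predicted dummy responses against 0/1 truth.
meritSet <- function(yPred, truth, coding = classCoding()) {
    predLab <- classifyScores(yPred, coding)
    truthLab <- ifelse(truth == 1, coding$positive, coding$negative)
    list(nmc = nmc(truthLab, predLab),
         auroc = auroc(yPred, truth),
         dq2 = dq2(yPred, truth),
         rmse = sqrt(mean((truth - yPred)^2)),
         q2 = 1 - sum((truth - yPred)^2) / sum((truth - mean(truth))^2))
}
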