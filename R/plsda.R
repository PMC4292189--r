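# Two-class discriminant layer on top of PLS1: dummy coding of class
# labels, thresholded classification of predicted responses, and VIP
# marker selection.

#' Class coding for two-group discrimination
#'
#' The dummy-coding convention used throughout: the positive class maps to
#' 1 (normal walkers by default), the negative class to 0 (slow walkers),
#' and predicted responses are classified against a threshold of 0.5.
#' Predictions exactly at the threshold go to the negative class — the
#' published decision rule only specifies the strict "greater than 0.5"
#' branch, so the complement is closed deterministically.
#'
#' @param positive label coded 1.
#' @param negative label coded 0.
#' @param threshold decision threshold, strictly between the two codes.
#' @return a list of class `"classCoding"`.
#' @export
classCoding <- function(positive = "NW", negative = "SW", threshold = 0.5) {
    positive <- as.character(positive); negative <- as.character(negative)
    if (identical(positive, negative))
        stop("the two class labels must be distinct")
    threshold <- as.numeric(threshold)
    if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
        stop("'threshold' must lie strictly between the codes 0 and 1")
    structure(list(positive = positive, negative = negative,
                   threshold = threshold), class = "classCoding")
}

#' Dummy-code class labels
#'
#' Maps the positive label to 1 and the negative label to 0, turning the
#' classification problem into a regression on a dummy response.
#'
#' @param labels character/factor vector of group labels.
#' @param coding a [classCoding()].
#' @return numeric 0/1 vector.
#' @examples
#' encodeClasses(c("NW", "SW", "NW"))  # 1 0 1
#' @export
encodeClasses <- function(labels, coding = classCoding()) {
    labels <- as.character(labels)
    unseen <- setdiff(unique(labels), c(coding$positive, coding$negative))
    if (length(unseen))
        stop("label(s) not covered by the class coding: ",
             paste(unseen, collapse = ", "))
    as.numeric(labels == coding$positive)
}

#' Classify predicted responses
#'
#' Predictions strictly greater than the threshold are assigned the
#' positive label; everything else (including predictions outside [0, 1]
#' and exact ties at the threshold) the negative label.
#'
#' @param yPred numeric vector of predicted dummy responses; must be
#'   finite.
#' @param coding a [classCoding()].
#' @return character vector of labels.
#' @export
classifyScores <- function(yPred, coding = classCoding()) {
    if (any(!is.finite(yPred)))
        stop("non-finite prediction(s) cannot be classified")
    ifelse(yPred > coding$threshold, coding$positive, coding$negative)
}

#' Variable importance in projection (VIP)
#'
#' Computes the Wold VIP score of every predictor from a fitted PLS1
#' model:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a = q_a^2\, t_a' t_a} is the response variance explained
#' by component a. The scores are scaled so their mean square over the p
#' predictors is exactly 1, which is what licenses the conventional
#' "greater than 1" selection rule. The sign of each predictor's
#' regression coefficient (on the autoscaled scale) is reported alongside:
#' with the positive class coded 1, a positive coefficient means a higher
#' concentration in the positive group.
#'
#' @param model a fitted [PLSModel-class] with at least one latent
#'   variable.
#' @param selectionThreshold markers with VIP strictly above this value
#'   are flagged as selected (default 1).
#' @return data frame with columns `marker`, `vip`, `coefficient`, `sign`
#'   (`"+"`, `"-"`, or `"0"`), `selected`, ordered by decreasing VIP.
#' @export
computeVIP <- function(model, selectionThreshold = 1) {
    stopifnot(is(model, "PLSModel"))
    if (model@nLV < 1L)
        stop("VIP requires a model with at least one latent variable")
    W <- model@weights
    p <- nrow(W)
    tt <- colSums(model@scores^2)
    ssy <- model@yLoadings^2 * tt
    if (sum(ssy) <= 0)
        stop("model explains no response variance; VIP is undefined")
    # NIPALS weight vectors are unit-norm, so w_aj / ||w_a|| = W[j, a].
    vip <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
    B <- model@coefficients
    out <- data.frame(marker = model@markerNames,
                      vip = vip,
                      coefficient = as.numeric(B),
                      sign = ifelse(B > 0, "+", ifelse(B < 0, "-", "0")),
                      selected = vip > selectionThreshold,
                      stringsAsFactors = FALSE)
    out[order(-out$vip), , drop = FALSE]
}

#' Write a VIP report as CSV
#'
#' Columns `marker`, `vip`, `coefficient_sign`, `selected`, mirroring the
#' conventional tabular presentation of discriminant markers.
#'
#' @param vipReport output of [computeVIP()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeVIPReport <- function(vipReport, path) {
    out <- data.frame(marker = vipReport$marker,
                      vip = vipReport$vip,
                      coefficient_sign = vipReport$sign,
                      selected = vipReport$selected)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Fit a PLS-DA model from a cohort
#'
#' Convenience wrapper: dummy-codes the cohort's group labels with the
#' given coding and fits a PLS1 model to the concentrations.
#'
#' @param cohort a [BiomarkerCohort-class].
#' @param nLV number of latent variables.
#' @param coding a [classCoding()].
#' @param center,scale preprocessing flags (default autoscaling).
#' @return a [PLSModel-class].
#' @export
fitPLSDA <- function(cohort, nLV, coding = classCoding(),
                     center = TRUE, scale = TRUE) {
    stopifnot(is(cohort, "BiomarkerCohort"))
    y <- encodeClasses(groupLabels(cohort), coding)
    fitPLS(cohortMatrix(cohort), y, nLV = nLV, center = center,
           scale = scale)
}
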