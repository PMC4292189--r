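# Inner k-fold cross-validation for complexity selection and the double
# (nested) cross-validation procedure that separates complexity selection
# from error estimation.

# Out-of-fold prediction matrix: one column per candidate complexity
# a = 1..amax, preprocessing re-estimated inside every training fold.
# Returns NULL columns trimmed if some fold supports fewer components.
.cvPredictions <- function(X, y, folds, amax, center = TRUE, scale = TRUE) {
    n <- nrow(X); p <- ncol(X)
    k <- max(folds)
    amaxEff <- amax
    for (f in seq_len(k)) {
        nTrain <- sum(folds != f)
        amaxEff <- min(amaxEff, nTrain - 1L, p)
    }
    preds <- matrix(NA_real_, n, amaxEff)
    for (f in seq_len(k)) {
        trainIdx <- which(folds != f)
        testIdx <- which(folds == f)
        yTrain <- y[trainIdx]
        if (length(unique(yTrain)) < 2L)
            stop("a class is absent from the training portion of fold ", f,
                 "; use fewer folds")
        st <- columnStats(X[trainIdx, , drop = FALSE], scale)
        Xtr <- applyPreprocessing(X[trainIdx, , drop = FALSE], center,
                                  scale, st$center, st$scale)
        Xte <- applyPreprocessing(X[testIdx, , drop = FALSE], center,
                                  scale, st$center, st$scale)
        ym <- if (center) mean(yTrain) else 0
        fit <- .plsCore(Xtr, yTrain - ym, amaxEff)
        a <- fit$nLV
        if (a > 0L)
            preds[testIdx, seq_len(a)] <- ym + Xte %*% fit$B
        if (a < amaxEff && a > 0L)  # rank exhausted: carry last column on
            preds[testIdx, (a + 1L):amaxEff] <- preds[testIdx, a]
        else if (a == 0L)
            preds[testIdx, ] <- ym
    }
    preds
}

# Complexity choice from an out-of-fold prediction matrix: minimise NMC,
# break ties by lower RMSECV, then by the smaller component count.
.chooseComplexity <- function(preds, y, threshold = 0.5) {
    wrong <- (preds > threshold) != (y == 1)
    nmcs <- colSums(wrong)
    rmse <- sqrt(colMeans((y - preds)^2))
    order(nmcs, rmse, seq_along(nmcs))[1L]
}

# Lean double CV: only the per-subject averaged external predictions,
# consuming the RNG stream exactly as doubleCV() does, so both agree
# under a common seed. Used inside permutation loops.
.leanExternalPredictions <- function(X, y, outerFraction, innerK,
                                     iterations, nLVMax,
                                     threshold = 0.5,
                                     center = TRUE, scale = TRUE) {
    n <- nrow(X)
    sums <- numeric(n); cnt <- integer(n)
    for (it in seq_len(iterations)) {
        ext <- stratifiedHoldout(y, outerFraction)
        rem <- setdiff(seq_len(n), ext)
        Xrem <- X[rem, , drop = FALSE]
        yRem <- y[rem]
        folds <- stratifiedFolds(yRem, innerK)
        preds <- .cvPredictions(Xrem, yRem, folds, nLVMax, center, scale)
        a <- .chooseComplexity(preds, yRem, threshold)
        st <- columnStats(Xrem, scale)
        Xtr <- applyPreprocessing(Xrem, center, scale, st$center, st$scale)
        Xte <- applyPreprocessing(X[ext, , drop = FALSE], center, scale,
                                  st$center, st$scale)
        ym <- if (center) mean(yRem) else 0
        fit <- .plsCore(Xtr, yRem - ym, a)
        p <- if (fit$nLV > 0L) as.numeric(ym + Xte %*% fit$B[, fit$nLV])
             else rep(ym, length(ext))
        sums[ext] <- sums[ext] + p
        cnt[ext] <- cnt[ext] + 1L
    }
    list(pred = ifelse(cnt > 0L, sums / pmax(cnt, 1L), NA_real_),
         count = cnt)
}

#' Inner k-fold cross-validation for PLS-DA complexity selection
#'
#' Stratified k-fold cross-validation of the dummy-coded PLS-DA model over
#' candidate complexities a = 1..`nLVMax`: out-of-fold predictions are
#' pooled across folds and summarised as NMC, AUROC, DQ2, RMSECV and Q2
#' per complexity. The selected complexity minimises NMC; ties are broken
#' by lower RMSECV, remaining ties by the smaller number of latent
#' variables (parsimony).
#'
#' @param X n-by-p predictor matrix.
#' @param y numeric 0/1 dummy response.
#' @param nLVMax largest complexity to evaluate (capped at what the
#'   smallest training fold supports).
#' @param k number of folds (default 6, the package's standard fold
#'   count); `k = n` gives deterministic leave-one-out.
#' @param coding a [classCoding()].
#' @param seed optional integer seed controlling the fold assignment.
#' @param center,scale preprocessing flags, re-estimated inside every
#'   training fold.
#' @return list with `merits` (data frame, one row per complexity),
#'   `chosen` (selected number of LVs), `folds` (fold assignment) and
#'   `predictions` (n-by-amax out-of-fold prediction matrix).
#' @export
kfoldCV <- function(X, y, nLVMax = 10L, k = 6L, coding = classCoding(),
                    seed = NULL, center = TRUE, scale = TRUE) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    folds <- withSeed(seed, stratifiedFolds(y, k))
    preds <- .cvPredictions(X, y, folds, nLVMax, center, scale)
    amax <- ncol(preds)
    merits <- do.call(rbind, lapply(seq_len(amax), function(a) {
        m <- meritSet(preds[, a], y, coding)
        data.frame(nLV = a, nmc = m$nmc, auroc = m$auroc, dq2 = m$dq2,
                   rmsecv = m$rmse, q2 = m$q2)
    }))
    ord <- order(merits$nmc, merits$rmsecv, merits$nLV)
    chosen <- merits$nLV[ord[1L]]
    list(merits = merits, chosen = chosen, folds = folds,
         predictions = preds)
}

#' Double (nested) cross-validation of a PLS-DA model
#'
#' Separates honest error estimation from complexity selection. At every
#' outer iteration a stratified external validation set (`outerFraction`
#' of each class, at least one subject) is withheld; an inner stratified
#' `innerK`-fold cross-validation on the remainder selects the number of
#' latent variables; a model at that complexity is then fitted on the full
#' remainder. Correct-classification rates are recorded at three levels:
#' calibration (refit model evaluated on its own training remainder),
#' internal validation (the inner out-of-fold predictions at the chosen
#' complexity), and external validation (the withheld subjects, never seen
#' by selection or fitting). Preprocessing is re-estimated inside every
#' training partition at every level. Results are averaged over
#' iterations; identical seeds reproduce the result exactly.
#'
#' @param X n-by-p matrix or a [BiomarkerCohort-class].
#' @param labels group labels (ignored when `X` is a cohort).
#' @param outerFraction fraction of each class withheld externally
#'   (default 0.2).
#' @param innerK inner fold count (default 6).
#' @param iterations outer repetitions (default 50).
#' @param nLVMax largest complexity the inner loop may select.
#' @param coding a [classCoding()].
#' @param seed integer seed for the whole procedure.
#' @param center,scale preprocessing flags.
#' @return a [DoubleCVResult-class].
#' @export
doubleCV <- function(X, labels = NULL, outerFraction = 0.2, innerK = 6L,
                     iterations = 50L, nLVMax = 10L,
                     coding = classCoding(), seed = NULL,
                     center = TRUE, scale = TRUE) {
    if (is(X, "BiomarkerCohort")) {
        labels <- groupLabels(X)
        X <- cohortMatrix(X)
    }
    X <- as.matrix(X)
    labels <- as.character(labels)
    if (outerFraction <= 0 || outerFraction > 0.5)
        stop("'outerFraction' must lie in (0, 0.5]")
    y <- encodeClasses(labels, coding)
    if (min(table(labels)) < 2L)
        stop("both classes need at least 2 subjects")
    n <- nrow(X)
    classes <- c(coding$positive, coding$negative)
    extCount <- integer(n)
    extSum <- numeric(n)
    extN <- integer(n)
    rows <- withSeed(seed, {
        lapply(seq_len(iterations), function(it) {
            extIdx <- stratifiedHoldout(labels, outerFraction)
            remIdx <- setdiff(seq_len(n), extIdx)
            extCount[extIdx] <<- extCount[extIdx] + 1L
            Xrem <- X[remIdx, , drop = FALSE]
            yRem <- y[remIdx]
            inner <- kfoldCV(Xrem, yRem, nLVMax = nLVMax, k = innerK,
                             coding = coding, seed = NULL,
                             center = center, scale = scale)
            a <- inner$chosen
            model <- fitPLS(Xrem, yRem, nLV = a, center = center,
                            scale = scale)
            labRem <- labels[remIdx]
            calPred <- classifyScores(predict(model, Xrem), coding)
            intPred <- classifyScores(inner$predictions[, a], coding)
            extScores <- predict(model, X[extIdx, , drop = FALSE])
            extPred <- classifyScores(extScores, coding)
            extSum[extIdx] <<- extSum[extIdx] + extScores
            extN[extIdx] <<- extN[extIdx] + 1L
            cal <- classificationRates(labRem, calPred, classes)
            int <- classificationRates(labRem, intPred, classes)
            ext <- classificationRates(labels[extIdx], extPred, classes)
            data.frame(iteration = it, nLV = a,
                       cal_pos = cal[[1]], cal_neg = cal[[2]],
                       cal_overall = cal[["overall"]],
                       cal_balanced = cal[["balanced"]],
                       int_pos = int[[1]], int_neg = int[[2]],
                       int_overall = int[["overall"]],
                       int_balanced = int[["balanced"]],
                       ext_pos = ext[[1]], ext_neg = ext[[2]],
                       ext_overall = ext[["overall"]],
                       ext_balanced = ext[["balanced"]])
        })
    })
    iterDf <- do.call(rbind, rows)
    extMean <- ifelse(extN > 0L, extSum / pmax(extN, 1L), NA_real_)
    names(extCount) <- rownames(X)
    cfg <- list(outerFraction = outerFraction, innerK = innerK,
                iterations = as.integer(iterations),
                nLVMax = as.integer(nLVMax),
                positive = coding$positive, negative = coding$negative,
                threshold = coding$threshold,
                center = center, scale = scale)
    new("DoubleCVResult", iterations = iterDf,
        externalCounts = extCount, externalPredictions = extMean,
        config = cfg,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @describeIn doubleCV per-iteration results data frame.
#' @param result a [DoubleCVResult-class].
#' @export
cvIterations <- function(result) {
    stopifnot(is(result, "DoubleCVResult"))
    result@iterations
}

#' @describeIn doubleCV averages over iterations: one row per validation
#'   level with per-class, overall (class-size-weighted) and balanced
#'   (unweighted class-mean) correct-classification percentages, plus the
#'   modal selected complexity.
#' @export
cvSummary <- function(result) {
    stopifnot(is(result, "DoubleCVResult"))
    it <- result@iterations
    lvl <- c(calibration = "cal", internal = "int", external = "ext")
    out <- do.call(rbind, lapply(names(lvl), function(nm) {
        pre <- lvl[[nm]]
        data.frame(level = nm,
                   positive = mean(it[[paste0(pre, "_pos")]]),
                   negative = mean(it[[paste0(pre, "_neg")]]),
                   overall = mean(it[[paste0(pre, "_overall")]]),
                   balanced = mean(it[[paste0(pre, "_balanced")]]))
    }))
    rownames(out) <- NULL
    out
}

#' @describeIn doubleCV modal inner-selected number of latent variables
#'   across iterations (ties resolved toward the smaller count).
#' @export
modalNLV <- function(result) {
    stopifnot(is(result, "DoubleCVResult"))
    tab <- table(result@iterations$nLV)
    as.integer(names(tab)[which.max(tab)])  # which.max takes first = smaller
}

setMethod("show", "DoubleCVResult", function(object) {
    s <- cvSummary(object)
    cfg <- object@config
    cat("DoubleCVResult:", cfg$iterations, "outer iterations,",
        sprintf("%.0f%%", 100 * cfg$outerFraction),
        "external holdout,", cfg$innerK, "inner folds\n")
    cat("  modal complexity:", modalNLV(object), "latent variable(s)\n")
    for (i in seq_len(nrow(s))) {
        cat(sprintf(
            "  %-11s %5.1f%% %s / %5.1f%% %s / overall %5.1f%% (balanced %5.1f%%)\n",
            s$level[i], s$positive[i], cfg$positive, s$negative[i],
            cfg$negative, s$overall[i], s$balanced[i]))
    }
})

#' Export a double-CV result as CSV
#'
#' One row per outer iteration (chosen complexity and the twelve rates),
#' written without a summary so the aggregate is recomputable from the
#' file.
#'
#' @param result a [DoubleCVResult-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeDoubleCVResult <- function(result, path) {
    stopifnot(is(result, "DoubleCVResult"))
    df <- result@iterations
    num <- vapply(df, is.numeric, logical(1)) &
        !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
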