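# Permutation tests: empirical null distributions of NMC, AUROC and DQ2
# under random label reassignment, re-running the whole modelling stage
# (including complexity selection, unless frozen) for every permutation.

# Evaluate the three figures of merit for one label assignment.
# mode "doublecv": per-subject mean external prediction from a (reduced)
# double CV; subjects never withheld are dropped from the merit
# computation (with >= 10 iterations at the default holdout this is
# rare). mode "kfold": pooled out-of-fold predictions from one stratified
# k-fold CV, at the inner-selected complexity (or a frozen one).
.evaluateMerits <- function(X, labels, config, coding) {
    y <- encodeClasses(labels, coding)
    if (config$mode == "doublecv") {
        lean <- .leanExternalPredictions(
            X, y, outerFraction = config$outerFraction,
            innerK = config$innerK, iterations = config$iterations,
            nLVMax = config$nLVMax, threshold = coding$threshold)
        keep <- !is.na(lean$pred)
        meritSet(lean$pred[keep], y[keep], coding)[c("nmc", "auroc", "dq2")]
    } else {
        folds <- stratifiedFolds(y, config$innerK)
        preds <- .cvPredictions(X, y, folds, config$nLVMax, TRUE, TRUE)
        a <- if (is.null(config$nLV))
                 .chooseComplexity(preds, y, coding$threshold)
             else min(config$nLV, ncol(preds))
        meritSet(preds[, a], y, coding)[c("nmc", "auroc", "dq2")]
    }
}

#' Permutation test of PLS-DA classification merits
#'
#' Builds empirical null distributions of the number of misclassifications
#' (NMC), AUROC and discriminant Q2 by randomly reassigning the class
#' labels (class sizes preserved) and re-running the whole modelling stage
#' — resampling, complexity selection, fitting and prediction — for every
#' permutation. Empirical p-values use the permutation-inclusive formula
#' \eqn{p = (b + 1)/(N + 1)}, where b counts null merits at least as
#' extreme as the observed one (NMC: less than or equal; AUROC and DQ2:
#' greater than or equal), so p is never zero and is bounded below by
#' 1/(N + 1).
#'
#' The modelling stage defaults to a reduced-iteration double
#' cross-validation (10 outer iterations) whose merits are computed on the
#' per-subject averaged external predictions; set `mode = "kfold"` for a
#' single stratified cross-validation (faster), or `nLV` to freeze the
#' complexity instead of re-selecting it inside every permutation.
#'
#' @param X n-by-p matrix or [BiomarkerCohort-class].
#' @param labels group labels (ignored for a cohort).
#' @param nPermutations number of label randomisations (default 1000).
#' @param coding a [classCoding()].
#' @param seed integer seed governing the entire procedure.
#' @param mode `"doublecv"` (default) or `"kfold"`.
#' @param iterations outer iterations of the reduced double CV.
#' @param innerK inner fold count.
#' @param outerFraction external holdout fraction.
#' @param nLVMax largest complexity the selection may pick.
#' @param nLV freeze the complexity at this value instead of re-selecting
#'   per permutation (`NULL`, the default, re-selects).
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(X, labels = NULL, nPermutations = 1000L,
                            coding = classCoding(), seed = NULL,
                            mode = c("doublecv", "kfold"),
                            iterations = 10L, innerK = 6L,
                            outerFraction = 0.2, nLVMax = 10L,
                            nLV = NULL) {
    mode <- match.arg(mode)
    if (is(X, "BiomarkerCohort")) {
        labels <- groupLabels(X)
        X <- cohortMatrix(X)
    }
    X <- as.matrix(X)
    labels <- as.character(labels)
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 1L) stop("'nPermutations' must be at least 1")
    if (length(unique(labels)) < 2L) stop("both classes must be present")
    config <- list(mode = mode, iterations = as.integer(iterations),
                   innerK = as.integer(innerK),
                   outerFraction = outerFraction,
                   nLVMax = as.integer(nLVMax), nLV = nLV)
    res <- withSeed(seed, {
        observed <- .evaluateMerits(X, labels, config, coding)
        null <- matrix(NA_real_, nPermutations, 3L,
                       dimnames = list(NULL, c("nmc", "auroc", "dq2")))
        for (b in seq_len(nPermutations)) {
            permLabels <- labels[sample.int(length(labels))]
            m <- .evaluateMerits(X, permLabels, config, coding)
            null[b, ] <- c(m$nmc, m$auroc, m$dq2)
        }
        list(observed = observed, null = as.data.frame(null))
    })
    pv <- c(nmc = permutationPValue(res$null$nmc, res$observed$nmc,
                                    "lower"),
            auroc = permutationPValue(res$null$auroc, res$observed$auroc,
                                      "upper"),
            dq2 = permutationPValue(res$null$dq2, res$observed$dq2,
                                    "upper"))
    new("PermutationResult", observed = res$observed, null = res$null,
        pValues = pv, nPermutations = nPermutations,
        config = config,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Empirical permutation p-value
#'
#' \eqn{p = (b + 1)/(N + 1)} with b the number of null values at least as
#' extreme as the observed one; `tail = "lower"` counts null values
#' \eqn{\le} observed (extremeness = small, as for NMC), `"upper"` counts
#' \eqn{\ge} observed (as for AUROC and DQ2).
#'
#' @param null numeric vector of null merits.
#' @param observed observed merit.
#' @param tail `"lower"` or `"upper"`.
#' @return p-value in [1/(N+1), 1].
#' @export
permutationPValue <- function(null, observed, tail = c("upper", "lower")) {
    tail <- match.arg(tail)
    b <- if (tail == "upper") sum(null >= observed) else sum(null <= observed)
    (b + 1) / (length(null) + 1)
}

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult:", object@nPermutations, "randomisations",
        sprintf("(%s evaluation)\n", object@config$mode))
    obs <- object@observed
    cat(sprintf("  NMC   = %d    p = %.4g\n", obs$nmc,
                object@pValues[["nmc"]]))
    cat(sprintf("  AUROC = %.3f  p = %.4g\n", obs$auroc,
                object@pValues[["auroc"]]))
    cat(sprintf("  DQ2   = %.3f  p = %.4g\n", obs$dq2,
                object@pValues[["dq2"]]))
})

#' Export permutation null distributions
#'
#' Writes a CSV with one row per permutation (columns `nmc`, `auroc`,
#' `dq2`), preceded by a `#`-prefixed header block recording the observed
#' merits and p-values. [readNullDistributions()] reproduces the null
#' vectors bitwise.
#'
#' @param result a [PermutationResult-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
exportNullDistributions <- function(result, path) {
    stopifnot(is(result, "PermutationResult"))
    con <- file(path, "w")
    on.exit(close(con))
    obs <- result@observed
    writeLines(c(
        sprintf("# n_permutations: %d", result@nPermutations),
        sprintf("# observed_nmc: %.17g", obs$nmc),
        sprintf("# observed_auroc: %.17g", obs$auroc),
        sprintf("# observed_dq2: %.17g", obs$dq2),
        sprintf("# p_nmc: %.17g", result@pValues[["nmc"]]),
        sprintf("# p_auroc: %.17g", result@pValues[["auroc"]]),
        sprintf("# p_dq2: %.17g", result@pValues[["dq2"]]),
        "nmc,auroc,dq2"), con)
    writeLines(sprintf("%.17g,%.17g,%.17g", result@null$nmc,
                       result@null$auroc, result@null$dq2), con)
    invisible(path)
}

#' @rdname exportNullDistributions
#' @return `readNullDistributions` returns a list with elements
#'   `null` (data frame), `observed`, and `pValues`.
#' @export
readNullDistributions <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    val <- function(key) {
        ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
        as.numeric(sub(".*: ", "", ln))
    }
    body <- lines[!grepl("^#", lines)]
    df <- read.csv(text = paste(body, collapse = "\n"))
    df[] <- lapply(df, as.numeric)
    list(null = df,
         observed = list(nmc = val("observed_nmc"),
                         auroc = val("observed_auroc"),
                         dq2 = val("observed_dq2")),
         pValues = c(nmc = val("p_nmc"), auroc = val("p_auroc"),
                     dq2 = val("p_dq2")))
}
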