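# End-to-end orchestration: optional age-confounding check, double-CV
# PLS-DA, permutation tests, VIP table, and deterministic exports.

#' Age-confounding regression check
#'
#' Before interpreting a biomarker-based classifier of a performance
#' category that itself correlates with age, one should check whether the
#' markers simply encode age. Fits a PLS regression of age on the marker
#' block, selects the complexity minimising RMSECV in a stratification-free
#' k-fold cross-validation, and reports calibration (R2, RMSE) and
#' cross-validated (Q2, RMSECV) performance at that complexity. A
#' cross-validated Q2 below `qThreshold` (default 0.1) raises the
#' `noAgeSignal` flag: the markers carry no usable age information.
#'
#' @param X n-by-p matrix or [BiomarkerCohort-class].
#' @param age numeric vector of ages (or the name of a `colData` column
#'   when `X` is a cohort).
#' @param k fold count (default 6).
#' @param nLVMax largest complexity evaluated.
#' @param qThreshold flag threshold on Q2.
#' @param seed seed for the fold assignment.
#' @return list with `nLV`, `r2`, `rmse`, `q2`, `rmsecv`, `noAgeSignal`,
#'   and `fitted` (calibration fitted values).
#' @export
ageConfoundingCheck <- function(X, age, k = 6L, nLVMax = 10L,
                                qThreshold = 0.1, seed = NULL) {
    if (is(X, "BiomarkerCohort")) {
        if (is.character(age) && length(age) == 1L)
            age <- SummarizedExperiment::colData(X)[[age]]
        X <- cohortMatrix(X)
    }
    X <- as.matrix(X)
    age <- as.numeric(age)
    if (anyNA(age)) stop("missing age values")
    if (any(age <= 0)) stop("ages must be positive")
    n <- nrow(X)
    folds <- withSeed(seed, {
        idx <- sample.int(n)
        f <- integer(n); f[idx] <- rep_len(seq_len(k), n); f
    })
    amaxEff <- min(nLVMax, ncol(X),
                   min(vapply(seq_len(k), function(f) sum(folds != f),
                              integer(1))) - 1L)
    preds <- matrix(NA_real_, n, amaxEff)
    for (f in seq_len(k)) {
        tr <- which(folds != f); te <- which(folds == f)
        st <- columnStats(X[tr, , drop = FALSE], TRUE)
        Xtr <- applyPreprocessing(X[tr, , drop = FALSE], TRUE, TRUE,
                                  st$center, st$scale)
        Xte <- applyPreprocessing(X[te, , drop = FALSE], TRUE, TRUE,
                                  st$center, st$scale)
        ym <- mean(age[tr])
        fit <- .plsCore(Xtr, age[tr] - ym, amaxEff)
        a <- fit$nLV
        if (a > 0L) preds[te, seq_len(a)] <- ym + Xte %*% fit$B
        if (a < amaxEff && a > 0L) preds[te, (a + 1L):amaxEff] <- preds[te, a]
        else if (a == 0L) preds[te, ] <- ym
    }
    tss <- sum((age - mean(age))^2)
    rmsecvs <- sqrt(colMeans((age - preds)^2))
    a <- which.min(rmsecvs)
    model <- fitPLS(X, age, nLV = a)
    fitted <- predict(model, X)
    rss <- sum((age - fitted)^2)
    q2 <- 1 - sum((age - preds[, a])^2) / tss
    list(nLV = as.integer(a),
         r2 = 1 - rss / tss,
         rmse = sqrt(mean((age - fitted)^2)),
         q2 = q2,
         rmsecv = rmsecvs[a],
         noAgeSignal = q2 < qThreshold,
         fitted = fitted)
}

#' Assemble a run configuration
#'
#' Collects every knob of the full analysis into one validated list:
#' input (a cohort file path or a [SyntheticCohortSpec-class]), class
#' coding, preprocessing flags, complexity bound, inner fold count, outer
#' holdout fraction and iteration count, permutation count, seed, and an
#' optional output directory for the exports.
#'
#' @param input path to a cohort CSV/TSV, a [BiomarkerCohort-class], or a
#'   [SyntheticCohortSpec-class] to simulate from.
#' @param coding a [classCoding()].
#' @param center,scale preprocessing flags.
#' @param nLVMax largest candidate complexity.
#' @param innerK inner fold count.
#' @param outerFraction external holdout fraction, in (0, 0.5].
#' @param iterations outer double-CV iterations.
#' @param nPermutations permutation count.
#' @param permutationIterations outer iterations used inside each
#'   permutation (reduced for tractability).
#' @param ageColumn optional age column name for the confounding check.
#' @param seed integer seed recorded in every output.
#' @param outputDir directory for exports, or `NULL` for none.
#' @return a validated configuration list of class `"plsdaRunConfig"`.
#' @export
runConfig <- function(input, coding = classCoding(), center = TRUE,
                      scale = TRUE, nLVMax = 10L, innerK = 6L,
                      outerFraction = 0.2, iterations = 50L,
                      nPermutations = 199L, permutationIterations = 10L,
                      ageColumn = NULL, seed = 1L, outputDir = NULL) {
    stopifnot(nLVMax >= 1L, innerK >= 2L, iterations >= 1L,
              nPermutations >= 1L, permutationIterations >= 1L)
    if (outerFraction <= 0 || outerFraction > 0.5)
        stop("'outerFraction' must lie in (0, 0.5]")
    structure(list(input = input, coding = coding, center = center,
                   scale = scale, nLVMax = as.integer(nLVMax),
                   innerK = as.integer(innerK),
                   outerFraction = outerFraction,
                   iterations = as.integer(iterations),
                   nPermutations = as.integer(nPermutations),
                   permutationIterations =
                       as.integer(permutationIterations),
                   ageColumn = ageColumn, seed = as.integer(seed),
                   outputDir = outputDir),
              class = "plsdaRunConfig")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [runConfig()] (`input`,
#' `positive`, `negative`, `threshold`, `center`, `scale`, `n_lv_max`,
#' `inner_k`, `outer_fraction`, `iterations`, `n_permutations`,
#' `permutation_iterations`, `age_column`, `seed`, `output_dir`).
#'
#' @param path YAML file path.
#' @param overrides named list of values taking precedence over the file.
#' @return a `"plsdaRunConfig"` list.
#' @export
readRunConfig <- function(path, overrides = list()) {
    y <- yaml::read_yaml(path)
    y[names(overrides)] <- overrides
    pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
    runConfig(input = pick("input", stop("config must name an input")),
              coding = classCoding(pick("positive", "NW"),
                                   pick("negative", "SW"),
                                   pick("threshold", 0.5)),
              center = pick("center", TRUE), scale = pick("scale", TRUE),
              nLVMax = pick("n_lv_max", 10L),
              innerK = pick("inner_k", 6L),
              outerFraction = pick("outer_fraction", 0.2),
              iterations = pick("iterations", 50L),
              nPermutations = pick("n_permutations", 199L),
              permutationIterations = pick("permutation_iterations", 10L),
              ageColumn = pick("age_column", NULL),
              seed = pick("seed", 1L),
              outputDir = pick("output_dir", NULL))
}

.resolveCohort <- function(config) {
    input <- config$input
    if (is(input, "BiomarkerCohort")) return(input)
    if (is(input, "SyntheticCohortSpec"))
        return(generateCohort(input, seed = config$seed))
    readCohort(input, coding = config$coding,
               ageColumn = config$ageColumn)
}

#' Run the full PLS-DA analysis pipeline
#'
#' Executes the complete analysis sequence on a cohort: (1) optional
#' age-confounding PLS regression check, (2) double cross-validation of
#' the PLS-DA classifier, (3) permutation tests of NMC, AUROC and DQ2,
#' (4) a full-data model at the modal inner-selected complexity, with its
#' VIP/coefficient-sign marker table. When `outputDir` is set, all
#' intermediates are exported as plain text (cohort, per-iteration CV
#' rows, null distributions, VIP table, scores matrix for a
#' latent-space projection plot, serialised model, YAML report); given the
#' same configuration and seed, every export except the timing log is
#' byte-identical across runs.
#'
#' @param config a [runConfig()] list.
#' @return an [AnalysisReport-class].
#' @export
runFullAnalysis <- function(config) {
    stopifnot(inherits(config, "plsdaRunConfig"))
    t0 <- proc.time()[["elapsed"]]
    timings <- c()
    cohort <- .resolveCohort(config)
    coding <- config$coding
    X <- cohortMatrix(cohort)
    labels <- groupLabels(cohort)

    ageCheck <- list()
    if (!is.null(config$ageColumn) &&
        config$ageColumn %in%
            colnames(SummarizedExperiment::colData(cohort))) {
        ageCheck <- ageConfoundingCheck(
            cohort, config$ageColumn, k = config$innerK,
            nLVMax = config$nLVMax, seed = config$seed)
        timings["age_check"] <- proc.time()[["elapsed"]] - t0
    }

    t1 <- proc.time()[["elapsed"]]
    dcv <- doubleCV(X, labels, outerFraction = config$outerFraction,
                    innerK = config$innerK,
                    iterations = config$iterations,
                    nLVMax = config$nLVMax, coding = coding,
                    seed = config$seed, center = config$center,
                    scale = config$scale)
    timings["double_cv"] <- proc.time()[["elapsed"]] - t1

    t2 <- proc.time()[["elapsed"]]
    perm <- permutationTest(X, labels,
                            nPermutations = config$nPermutations,
                            coding = coding, seed = config$seed,
                            iterations = config$permutationIterations,
                            innerK = config$innerK,
                            outerFraction = config$outerFraction,
                            nLVMax = config$nLVMax)
    timings["permutation"] <- proc.time()[["elapsed"]] - t2

    a <- modalNLV(dcv)
    model <- fitPLS(X, encodeClasses(labels, coding), nLV = a,
                    center = config$center, scale = config$scale)
    vip <- computeVIP(model)

    report <- new("AnalysisReport", ageCheck = ageCheck, doubleCV = dcv,
                  permutation = perm, vip = vip, model = model,
                  modalNLV = a, config = unclass(config),
                  outputDir = if (is.null(config$outputDir)) ""
                              else config$outputDir)
    if (!is.null(config$outputDir))
        .exportReport(report, cohort, timings)
    report
}

.exportReport <- function(report, cohort, timings) {
    dir <- report@outputDir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cfg <- report@config
    writeCohort(cohort, file.path(dir, "cohort.csv"))
    writeDoubleCVResult(report@doubleCV,
                        file.path(dir, "doublecv_iterations.csv"))
    exportNullDistributions(report@permutation,
                            file.path(dir, "null_distributions.csv"))
    writeVIPReport(report@vip, file.path(dir, "vip_table.csv"))
    writePLSModel(report@model, file.path(dir, "model.yaml"))
    sc <- plsScores(report@model)
    scDf <- data.frame(subject_id = colnames(cohort),
                       group = groupLabels(cohort))
    for (j in seq_len(ncol(sc)))
        scDf[[paste0("LV", j)]] <- sprintf("%.17g", sc[, j])
    write.csv(scDf, file.path(dir, "scores.csv"), row.names = FALSE,
              quote = FALSE)
    s <- cvSummary(report@doubleCV)
    yaml::write_yaml(list(
        seed = cfg$seed,
        config = list(n_lv_max = cfg$nLVMax, inner_k = cfg$innerK,
                      outer_fraction = cfg$outerFraction,
                      iterations = cfg$iterations,
                      n_permutations = cfg$nPermutations,
                      positive = cfg$coding$positive,
                      negative = cfg$coding$negative,
                      threshold = cfg$coding$threshold),
        modal_n_lv = report@modalNLV,
        explained_x_variance =
            sum(report@model@explainedVarX),
        rates = lapply(seq_len(nrow(s)), function(i)
            list(level = s$level[i], positive = s$positive[i],
                 negative = s$negative[i], overall = s$overall[i],
                 balanced = s$balanced[i])),
        permutation = list(
            observed = report@permutation@observed,
            p_values = as.list(report@permutation@pValues)),
        age_check = if (length(report@ageCheck))
            report@ageCheck[c("nLV", "r2", "rmse", "q2", "rmsecv",
                              "noAgeSignal")]
            else NULL,
        vip_selected = report@vip$marker[report@vip$selected]),
        file.path(dir, "report.yaml"), precision = 12)
    # Timing log: the one deliberately non-deterministic artifact.
    writeLines(c(sprintf("seed: %d", cfg$seed),
                 sprintf("%s_seconds: %.2f", names(timings), timings)),
               file.path(dir, "run.log"))
    invisible(dir)
}

setMethod("show", "AnalysisReport", function(object) {
    cat("PLS-DA analysis report\n")
    cat("======================\n")
    if (length(object@ageCheck)) {
        a <- object@ageCheck
        cat(sprintf(
            "Age check: %d LVs, R2 = %.2f, RMSE = %.1f, Q2 = %.2f, RMSECV = %.1f%s\n",
            a$nLV, a$r2, a$rmse, a$q2, a$rmsecv,
            if (a$noAgeSignal) " [no age signal]" else ""))
    }
    cat("Classification (double cross-validation):\n")
    show(object@doubleCV)
    cat(sprintf("Final model: %d LVs, %.1f%% of X variance\n",
                object@modalNLV,
                100 * sum(object@model@explainedVarX)))
    show(object@permutation)
    sel <- object@vip[object@vip$selected, , drop = FALSE]
    cat("Discriminant markers (VIP > 1):\n")
    for (i in seq_len(nrow(sel)))
        cat(sprintf("  %-12s VIP %.2f  sign %s\n", sel$marker[i],
                    sel$vip[i], sel$sign[i]))
})

setMethod("show", "BiomarkerCohort", function(object) {
    tab <- table(groupLabels(object))
    cat("BiomarkerCohort:", ncol(object), "subjects (",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "),", nrow(object), "markers\n")
    callNextMethod()
})

setMethod("show", "SyntheticCohortSpec", function(object) {
    cat("SyntheticCohortSpec:", paste(object@groupSizes, collapse = "/"),
        "subjects,", length(object@markerNames), "markers,",
        object@family, "marginals\n")
    if (length(object@effectDirections))
        cat("  effect markers:",
            paste(sprintf("%s(%+d)", names(object@effectDirections),
                          object@effectDirections), collapse = ", "),
            "\n")
})
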