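#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd predict rnorm runif qnorm pnorm dnorm quantile
#' @importFrom utils read.csv write.csv head
NULL

#' BiomarkerCohort: a subjects-by-markers concentration table with group labels
#'
#' `BiomarkerCohort` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold a panel of circulating-biomarker concentrations (markers in rows,
#' subjects in columns, assay `"concentrations"`) together with a two-level
#' group factor in `colData` (e.g. normal walkers `"NW"` vs slow walkers
#' `"SW"` at the 0.8 m/s gait-speed cutoff). All concentrations must be
#' finite and non-negative; subject identifiers must be unique.
#'
#' @slot .Data inherited `SummarizedExperiment` structure.
#' @seealso [BiomarkerCohort()], [cohortMatrix()], [groupLabels()]
#' @export
setClass("BiomarkerCohort", contains = "SummarizedExperiment")

setValidity("BiomarkerCohort", function(object) {
    msg <- character()
    if (!"concentrations" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'concentrations' is missing")
    else {
        x <- SummarizedExperiment::assay(object, "concentrations")
        if (!is.numeric(x))
            msg <- c(msg, "concentrations must be numeric")
        else if (any(!is.finite(x)))
            msg <- c(msg, "concentrations contain missing or non-finite values")
        else if (any(x < 0))
            msg <- c(msg, "concentrations must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- cd$group
        if (nlevels(factor(g)) != 2L)
            msg <- c(msg, "'group' must take exactly two distinct values")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate subject ids")
    if (length(msg)) msg else TRUE
})

#' Construct a BiomarkerCohort
#'
#' @param X numeric matrix of concentrations, one row per subject and one
#'   column per marker (the orientation used throughout the modelling
#'   functions; it is transposed internally to the markers-by-subjects
#'   assay layout).
#' @param groups character or factor of per-subject group labels with
#'   exactly two distinct values.
#' @param subjectIds optional subject identifiers (default `S1..Sn`).
#' @param markerNames optional marker names (default taken from
#'   `colnames(X)`).
#' @param units optional per-marker unit strings, carried as `rowData`
#'   metadata only (no conversion is ever performed).
#' @return a validated [BiomarkerCohort-class] object.
#' @examples
#' X <- matrix(rlnorm(40), 10, 4,
#'             dimnames = list(NULL, paste0("M", 1:4)))
#' bc <- BiomarkerCohort(X, rep(c("NW", "SW"), each = 5))
#' bc
#' @export
BiomarkerCohort <- function(X, groups, subjectIds = NULL, markerNames = NULL,
                            units = NULL) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    n <- nrow(X)
    if (length(groups) != n)
        stop("'groups' must have one entry per row of 'X'")
    if (is.null(markerNames)) markerNames <- colnames(X)
    if (is.null(markerNames))
        markerNames <- paste0("marker", seq_len(ncol(X)))
    if (length(markerNames) != ncol(X))
        stop("'markerNames' length must equal the number of columns of 'X'")
    if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(n))
    assay <- t(X)
    dimnames(assay) <- list(markerNames, as.character(subjectIds))
    rd <- S4Vectors::DataFrame(row.names = markerNames)
    if (!is.null(units)) {
        if (length(units) != length(markerNames))
            stop("'units' length must equal the number of markers")
        rd$unit <- units
    }
    cd <- S4Vectors::DataFrame(
        subject_id = as.character(subjectIds),
        group = factor(as.character(groups)),
        row.names = as.character(subjectIds))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(concentrations = assay), rowData = rd, colData = cd)
    new("BiomarkerCohort", se)
}

#' @describeIn BiomarkerCohort subjects-by-markers numeric matrix (the X
#'   block handed to the PLS engine).
#' @param object a `BiomarkerCohort`.
#' @export
cohortMatrix <- function(object) {
    stopifnot(is(object, "BiomarkerCohort"))
    t(SummarizedExperiment::assay(object, "concentrations"))
}

#' @describeIn BiomarkerCohort per-subject group labels as a character
#'   vector.
#' @export
groupLabels <- function(object) {
    stopifnot(is(object, "BiomarkerCohort"))
    as.character(SummarizedExperiment::colData(object)$group)
}

#' @describeIn BiomarkerCohort marker names, in assay row order.
#' @export
markerNames <- function(object) {
    stopifnot(is(object, "BiomarkerCohort"))
    rownames(object)
}

#' Specification of a synthetic biomarker cohort
#'
#' Describes the generative model for a two-group synthetic cohort:
#' per-group, per-marker target means and SDs in original concentration
#' units, a strictly positive marginal family (`"lognormal"`, the default,
#' or `"truncated-normal"`), an optional inter-marker correlation imposed
#' through a Gaussian copula, and the subset of markers designated as truly
#' discriminative together with the sign convention (+1 means higher in the
#' positive/NW group).
#'
#' @slot groupSizes named integer vector of length 2 (subjects per group).
#' @slot markerNames character vector of marker identifiers.
#' @slot targetMeans,targetSds 2-by-p numeric matrices (rows = groups).
#' @slot family marginal distribution family tag.
#' @slot correlation p-by-p correlation matrix of the latent normals.
#' @slot effectDirections named numeric (+1/-1) for the designated
#'   discriminative markers; may be empty.
#' @slot units per-marker unit strings (metadata only).
#' @slot seed default random seed used by [generateCohort()].
#' @export
setClass("SyntheticCohortSpec",
    representation(groupSizes = "integer", markerNames = "character",
                   targetMeans = "matrix", targetSds = "matrix",
                   family = "character", correlation = "matrix",
                   effectDirections = "numeric", units = "character",
                   seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
    msg <- character()
    p <- length(object@markerNames)
    if (length(object@groupSizes) != 2L || any(object@groupSizes < 2L))
        msg <- c(msg, "groupSizes must be two integers >= 2")
    for (nm in c("targetMeans", "targetSds")) {
        m <- slot(object, nm)
        if (!all(dim(m) == c(2L, p)))
            msg <- c(msg, sprintf("%s must be a 2-by-%d matrix", nm, p))
        else if (any(!is.finite(m)) || any(m <= 0))
            msg <- c(msg, sprintf("all %s must be positive", nm))
    }
    if (!object@family %in% c("lognormal", "truncated-normal"))
        msg <- c(msg, "family must be 'lognormal' or 'truncated-normal'")
    C <- object@correlation
    if (!all(dim(C) == c(p, p)))
        msg <- c(msg, "correlation must be p-by-p")
    else {
        if (max(abs(C - t(C))) > 1e-8 || max(abs(diag(C) - 1)) > 1e-8)
            msg <- c(msg, "correlation must be symmetric with unit diagonal")
        else if (min(eigen(C, symmetric = TRUE,
                           only.values = TRUE)$values) < -1e-8)
            msg <- c(msg, "correlation matrix is not positive semi-definite")
    }
    ed <- object@effectDirections
    if (length(ed) &&
        (!all(names(ed) %in% object@markerNames) || !all(abs(ed) == 1)))
        msg <- c(msg, "effectDirections must be +/-1, named by known markers")
    if (length(msg)) msg else TRUE
})

#' A fitted PLS1 latent-variable model
#'
#' Holds the NIPALS decomposition of a single-response PLS regression:
#' weights W, x-loadings P, the projection matrix R = W (P'W)^-1 that maps
#' (preprocessed) predictor rows to scores T = X R, the y-loadings q used
#' to predict the response from the scores, and the regression coefficients
#' B = R q that express the model as y = X B on the preprocessed scale.
#' Preprocessing (per-column centring/autoscaling) is estimated from the
#' training set only and stored so new data are projected with frozen
#' parameters.
#'
#' @slot weights p-by-a matrix W of unit-norm weight vectors.
#' @slot xLoadings p-by-a matrix P.
#' @slot projection p-by-a matrix R.
#' @slot yLoadings length-a numeric q.
#' @slot coefficients length-p numeric B (preprocessed scale).
#' @slot scores n-by-a training score matrix T, mutually orthogonal columns.
#' @slot nLV number of latent variables actually extracted.
#' @slot center,scale logicals recording the preprocessing in force.
#' @slot xCenter,xScale per-column preprocessing parameters.
#' @slot yCenter training mean of the response.
#' @slot explainedVarX,explainedVarY per-LV fractions of preprocessed-X and
#'   centred-y variance captured.
#' @slot markerNames predictor names.
#' @export
setClass("PLSModel",
    representation(weights = "matrix", xLoadings = "matrix",
                   projection = "matrix", yLoadings = "numeric",
                   coefficients = "numeric", scores = "matrix",
                   nLV = "integer", center = "logical", scale = "logical",
                   xCenter = "numeric", xScale = "numeric",
                   yCenter = "numeric", explainedVarX = "numeric",
                   explainedVarY = "numeric", markerNames = "character"))

#' Result of a double (nested) cross-validation run
#'
#' One row per outer iteration: the inner-CV-selected number of latent
#' variables and per-class / overall / balanced correct-classification
#' rates (in percent) at the calibration, internal-validation and
#' external-validation levels.
#'
#' @slot iterations per-iteration data frame.
#' @slot externalCounts how often each subject fell in the external set.
#' @slot externalPredictions per-subject mean external-set prediction
#'   (NA for subjects never withheld).
#' @slot config the resampling configuration used.
#' @slot seed the seed the run was performed under.
#' @export
setClass("DoubleCVResult",
    representation(iterations = "data.frame", externalCounts = "integer",
                   externalPredictions = "numeric", config = "list",
                   seed = "integer"))

#' Permutation-test null distributions for a PLS-DA model
#'
#' Null distributions of the number of misclassifications (NMC), AUROC and
#' discriminant Q2 obtained by re-running the whole modelling stage on
#' label-permuted data, together with the observed merits and empirical
#' p-values computed as (b + 1) / (N + 1).
#'
#' @slot observed named list with elements `nmc`, `auroc`, `dq2`.
#' @slot null data frame with one row per permutation, columns
#'   `nmc`, `auroc`, `dq2`.
#' @slot pValues named numeric vector of empirical p-values.
#' @slot nPermutations number of label randomisations.
#' @slot config evaluation configuration (resampling scheme the merits
#'   were computed under).
#' @slot seed seed of the run.
#' @export
setClass("PermutationResult",
    representation(observed = "list", null = "data.frame",
                   pValues = "numeric", nPermutations = "integer",
                   config = "list", seed = "integer"))

#' Full-pipeline analysis report
#'
#' Bundles the outputs of [runFullAnalysis()]: the optional age-confounding
#' regression check, the double-cross-validated PLS-DA classification
#' result, the permutation test, the VIP marker table computed on the
#' full-data model at the modal complexity, and the final model itself.
#'
#' @slot ageCheck list (possibly empty) with the age-regression summary.
#' @slot doubleCV a [DoubleCVResult-class].
#' @slot permutation a [PermutationResult-class].
#' @slot vip the VIP report data frame.
#' @slot model the final full-data [PLSModel-class].
#' @slot modalNLV the modal inner-selected number of latent variables.
#' @slot config the run configuration.
#' @slot outputDir directory the intermediates were exported to ("" if
#'   none).
#' @export
setClass("AnalysisReport",
    representation(ageCheck = "list", doubleCV = "DoubleCVResult",
                   permutation = "PermutationResult", vip = "data.frame",
                   model = "PLSModel", modalNLV = "integer",
                   config = "list", outputDir = "character"))
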