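# NIPALS PLS1: latent-variable projection T = X R, response prediction
# y = T q', and regression coefficients B = R q'. X is deflated after each
# component; y is not (unnecessary for a single response).

# Core decomposition on already-preprocessed Xc (n x p) and centred yc.
# Returns all components up to amax, terminating early (with the achieved
# count) when the weight vector collapses below tol relative to the first.
.plsCore <- function(Xc, yc, amax, tol = 1e-12) {
    n <- nrow(Xc); p <- ncol(Xc)
    W <- matrix(0, p, amax); P <- matrix(0, p, amax)
    Tm <- matrix(0, n, amax); q <- numeric(amax)
    Xd <- Xc
    firstNorm <- NA_real_
    a <- 0L
    truncated <- FALSE
    for (i in seq_len(amax)) {
        w <- crossprod(Xd, yc)
        nw <- sqrt(sum(w * w))
        if (i == 1L) firstNorm <- nw
        if (nw <= tol * firstNorm || firstNorm == 0) {
            truncated <- TRUE
            break
        }
        w <- w / nw
        tvec <- Xd %*% w
        tt <- sum(tvec * tvec)
        if (tt < .Machine$double.eps) {
            truncated <- TRUE
            break
        }
        pvec <- crossprod(Xd, tvec) / tt
        q[i] <- sum(tvec * yc) / tt
        Xd <- Xd - tcrossprod(tvec, pvec)
        W[, i] <- w; P[, i] <- pvec; Tm[, i] <- tvec
        a <- i
    }
    keep <- seq_len(a)
    W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]
    # R = W (P'W)^-1; P'W is unit-diagonal upper triangular for NIPALS.
    R <- if (a > 0L) W %*% backsolve(crossprod(P, W), diag(a)) else W
    # Cumulative coefficients: column a gives B for an a-component model.
    Bcum <- if (a > 0L) {
        apply(sweep(R, 2L, q, "*"), 1L, cumsum)
    } else NULL
    Bcum <- if (a > 1L) t(Bcum) else if (a == 1L) matrix(Bcum, p, 1L)
            else matrix(0, p, 0L)
    list(W = W, P = P, T = Tm, q = q, R = R, B = Bcum, nLV = a,
         truncated = truncated)
}

#' Fit a PLS1 regression model
#'
#' Fits a single-response partial least squares model by NIPALS: latent
#' variables are directions of maximal covariance between the (optionally
#' autoscaled) predictor block and the centred response. With
#' `nLV = min(n - 1, p)` on full-column-rank data the coefficients
#' coincide with ordinary least squares; with fewer components the model
#' regularises, which is what makes it usable when predictors outnumber
#' subjects or are strongly collinear, as in multiplex biomarker panels.
#'
#' Preprocessing defaults to autoscaling (per-column mean-centring and
#' unit-variance scaling), the chemometric standard when predictors live
#' on heterogeneous scales (pg/mL cytokines next to ng/mL adhesion
#' molecules). Parameters are estimated from the training data handed to
#' this call and stored in the model, so validation data are always
#' projected with frozen parameters.
#'
#' @param X numeric n-by-p predictor matrix, no missing values.
#' @param y numeric response vector of length n.
#' @param nLV number of latent variables requested; at most
#'   `min(n - 1, p)`. If a weight vector collapses (rank exhausted) the
#'   extraction stops early with a warning and the model keeps the
#'   achieved count.
#' @param center,scale preprocessing flags (defaults: autoscaling).
#' @return a [PLSModel-class].
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -1, 0.5) + rnorm(20, sd = 0.1)
#' m <- fitPLS(X, y, nLV = 2)
#' m
#' @export
fitPLS <- function(X, y, nLV, center = TRUE, scale = TRUE) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    if (length(y) != n) stop("'y' must have one entry per row of 'X'")
    if (anyNA(X) || anyNA(y)) stop("missing values in 'X' or 'y'")
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("non-finite values in 'X' or 'y'")
    if (n < 3L) stop("at least 3 observations are required")
    bound <- min(n - 1L, p)
    nLV <- as.integer(nLV)
    if (nLV < 1L || nLV > bound)
        stop("'nLV' must lie in [1, ", bound, "] (= min(n - 1, p))")
    mk <- colnames(X)
    if (is.null(mk)) mk <- paste0("X", seq_len(p))
    st <- columnStats(X, scale, context = "X")
    Xc <- applyPreprocessing(X, center, scale, st$center, st$scale)
    ym <- if (center) mean(y) else 0
    yc <- y - ym
    fit <- .plsCore(Xc, yc, nLV)
    if (fit$truncated)
        warning("latent-variable extraction stopped early at ", fit$nLV,
                " component(s): remaining X-y covariance is numerically zero")
    ssx <- sum(Xc * Xc)
    ssy <- sum(yc * yc)
    tt <- colSums(fit$T^2)
    evx <- if (ssx > 0) tt * colSums(fit$P^2) / ssx else rep(0, fit$nLV)
    evy <- if (ssy > 0) fit$q^2 * tt / ssy else rep(0, fit$nLV)
    B <- if (fit$nLV > 0L) fit$B[, fit$nLV] else rep(0, p)
    names(B) <- mk
    new("PLSModel",
        weights = fit$W, xLoadings = fit$P, projection = fit$R,
        yLoadings = fit$q, coefficients = B, scores = fit$T,
        nLV = fit$nLV, center = center, scale = scale,
        xCenter = if (center) st$center else rep(0, p),
        xScale = if (scale) st$scale else rep(1, p),
        yCenter = ym,
        explainedVarX = as.numeric(evx), explainedVarY = as.numeric(evy),
        markerNames = mk)
}

#' @describeIn fitPLS number of latent variables in a fitted model.
#' @param model a [PLSModel-class].
#' @export
nLatent <- function(model) {
    stopifnot(is(model, "PLSModel"))
    model@nLV
}

#' Predict from a fitted PLS model
#'
#' Applies the training-set preprocessing parameters to `newdata`,
#' projects through the stored coefficients and back-transforms to the
#' original response scale. Predicting on the training matrix reproduces
#' the fitted values exactly.
#'
#' @param object a [PLSModel-class].
#' @param newdata m-by-p numeric matrix with the training column layout.
#' @param ... ignored.
#' @return numeric vector of m predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object@coefficients))
        stop("'newdata' has ", ncol(newdata), " columns but the model was ",
             "fitted with ", length(object@coefficients))
    if (anyNA(newdata) || !all(is.finite(newdata)))
        stop("missing or non-finite values in 'newdata'")
    Xs <- applyPreprocessing(newdata, object@center, object@scale,
                             object@xCenter, object@xScale)
    as.numeric(object@yCenter + Xs %*% object@coefficients)
})

#' Project new observations onto the latent-variable space
#'
#' Computes scores `T_new = X_new R` after applying the frozen training
#' preprocessing, e.g. for a scores plot of external subjects.
#'
#' @param model a [PLSModel-class].
#' @param newdata m-by-p matrix.
#' @return m-by-nLV score matrix.
#' @export
projectScores <- function(model, newdata) {
    stopifnot(is(model, "PLSModel"))
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(model@coefficients))
        stop("column-count mismatch")
    Xs <- applyPreprocessing(newdata, model@center, model@scale,
                             model@xCenter, model@xScale)
    Xs %*% model@projection
}

#' Per-component explained variance
#'
#' Fractions of the preprocessed X-block and centred-y variance captured
#' by each latent variable, with cumulative totals. Over all
#' `min(n - 1, p)` components the cumulative X fraction reaches 1.
#'
#' @param model a [PLSModel-class].
#' @return data frame with columns `lv`, `x`, `xCumulative`, `y`,
#'   `yCumulative`.
#' @export
explainedVariance <- function(model) {
    stopifnot(is(model, "PLSModel"))
    data.frame(lv = seq_len(model@nLV),
               x = model@explainedVarX,
               xCumulative = cumsum(model@explainedVarX),
               y = model@explainedVarY,
               yCumulative = cumsum(model@explainedVarY))
}

#' @describeIn fitPLS regression coefficients on the preprocessed scale.
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@coefficients)

#' @describeIn fitPLS training score matrix T (orthogonal columns).
#' @export
plsScores <- function(model) {
    stopifnot(is(model, "PLSModel"))
    model@scores
}

setMethod("show", "PLSModel", function(object) {
    cat("PLSModel (NIPALS PLS1):", object@nLV, "latent variable(s),",
        length(object@coefficients), "predictors\n")
    cat(sprintf("  preprocessing: center=%s, scale=%s\n",
                object@center, object@scale))
    cat(sprintf("  cumulative explained variance: X %.1f%%, y %.1f%%\n",
                100 * sum(object@explainedVarX),
                100 * sum(object@explainedVarY)))
})

#' Serialise / restore a PLS model as structured text
#'
#' Writes every slot needed for exact re-prediction (matrices, y-loadings,
#' preprocessing parameters, LV count) to a YAML file; `readPLSModel`
#' restores an equivalent model whose predictions match to full double
#' precision.
#'
#' @param model a [PLSModel-class].
#' @param path file path.
#' @return `writePLSModel` returns `path` invisibly; `readPLSModel`
#'   returns a [PLSModel-class].
#' @export
writePLSModel <- function(model, path) {
    stopifnot(is(model, "PLSModel"))
    num <- function(x) {
        if (is.matrix(x)) lapply(seq_len(ncol(x)),
                                 function(j) format(x[, j], digits = 17))
        else format(x, digits = 17)
    }
    obj <- list(
        nLV = model@nLV, markerNames = model@markerNames,
        center = model@center, scale = model@scale,
        xCenter = num(model@xCenter), xScale = num(model@xScale),
        yCenter = num(model@yCenter),
        weights = num(model@weights), xLoadings = num(model@xLoadings),
        projection = num(model@projection), yLoadings = num(model@yLoadings),
        coefficients = num(model@coefficients), scores = num(model@scores),
        explainedVarX = num(model@explainedVarX),
        explainedVarY = num(model@explainedVarY))
    yaml::write_yaml(obj, path, precision = 17)
    invisible(path)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(path) {
    obj <- yaml::read_yaml(path)
    mat <- function(x, nrowHint) {
        cols <- lapply(x, as.numeric)
        if (!length(cols)) return(matrix(0, nrowHint, 0L))
        do.call(cbind, cols)
    }
    p <- length(obj$markerNames)
    a <- obj$nLV
    B <- as.numeric(obj$coefficients)
    names(B) <- obj$markerNames
    new("PLSModel",
        weights = mat(obj$weights, p), xLoadings = mat(obj$xLoadings, p),
        projection = mat(obj$projection, p),
        yLoadings = as.numeric(obj$yLoadings),
        coefficients = B,
        scores = mat(obj$scores, 0L),
        nLV = as.integer(a), center = obj$center, scale = obj$scale,
        xCenter = as.numeric(obj$xCenter), xScale = as.numeric(obj$xScale),
        yCenter = as.numeric(obj$yCenter),
        explainedVarX = as.numeric(obj$explainedVarX),
        explainedVarY = as.numeric(obj$explainedVarY),
        markerNames = obj$markerNames)
}
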