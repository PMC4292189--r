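# Internal helpers: seeded evaluation and stratified resampling.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is left untouched. seed = NULL uses the current
# stream (and therefore advances it).
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(eval.parent(substitute(expr)))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)  # initialise so we have a state to restore
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin over k folds, so per-class fold sizes differ by at most
# one. k = n is handled as deterministic leave-one-out (singleton folds in
# subject order).
stratifiedFolds <- function(labels, k) {
    n <- length(labels)
    if (k < 2L) stop("'k' must be at least 2")
    if (k > n) stop("'k' cannot exceed the number of subjects")
    if (k == n) return(seq_len(n))
    folds <- integer(n)
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
}

# Stratified holdout: returns indices of an external set containing
# round(fraction * n_class) (at least 1) subjects of each class.
stratifiedHoldout <- function(labels, fraction) {
    out <- integer(0)
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        m <- max(1L, round(fraction * length(idx)))
        if (m >= length(idx))
            stop("external set would empty class '", cl, "'")
        out <- c(out, idx[sample.int(length(idx), m)])
    }
    sort(out)
}

# Column means / SDs with informative failure on zero-variance columns.
columnStats <- function(X, scale, context = "X") {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, sd)
    if (scale && any(sdv < .Machine$double.eps^0.5 * (abs(mu) + 1))) {
        bad <- colnames(X)[sdv < .Machine$double.eps^0.5 * (abs(mu) + 1)]
        if (is.null(bad)) bad <- which(sdv < .Machine$double.eps^0.5)
        stop("zero-variance column(s) in ", context,
             " cannot be autoscaled: ", paste(bad, collapse = ", "))
    }
    list(center = mu, scale = sdv)
}

applyPreprocessing <- function(X, center, scale, mu, sdv) {
    if (center) X <- sweep(X, 2L, mu, "-")
    if (scale) X <- sweep(X, 2L, sdv, "/")
    X
}

# Percent correct within each class plus weighted and balanced aggregates.
classificationRates <- function(truth, predicted, classes) {
    perClass <- vapply(classes, function(cl) {
        idx <- truth == cl
        100 * sum(predicted[idx] == cl) / sum(idx)
    }, numeric(1))
    c(perClass,
      overall = 100 * mean(predicted == truth),
      balanced = mean(perClass))
}
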