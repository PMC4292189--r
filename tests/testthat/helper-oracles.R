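# Independent oracles and fixture builders shared across the test files.

# Least-squares coefficients on the autoscaled/centred training scale,
# via the normal equations on a pseudoinverse. At full column rank an
# nLV = p PLS model must coincide with this.
olsOracle <- function(X, y, center = TRUE, scale = TRUE) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    Xc <- X
    if (center) Xc <- sweep(Xc, 2, mu, "-")
    if (scale) Xc <- sweep(Xc, 2, sdv, "/")
    yc <- if (center) y - mean(y) else y
    b <- qr.solve(crossprod(Xc), crossprod(Xc, yc))
    list(coef = as.numeric(b),
         predict = function(newX) {
             Xs <- newX
             if (center) Xs <- sweep(Xs, 2, mu, "-")
             if (scale) Xs <- sweep(Xs, 2, sdv, "/")
             as.numeric((if (center) mean(y) else 0) + Xs %*% b)
         })
}

# AUROC by exhaustive positive-negative pair counting (ties = 1/2).
aurocBrute <- function(scores, truth) {
    pos <- scores[truth == 1]
    neg <- scores[truth == 0]
    total <- 0
    for (a in pos) for (b in neg)
        total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    total / (length(pos) * length(neg))
}

# Discriminant Q2 by direct truncated-PRESS arithmetic, written
# element-by-element (no vectorised shortcuts shared with the package).
dq2Direct <- function(yPred, truth) {
    tss <- sum((truth - mean(truth))^2)
    press <- 0
    for (i in seq_along(truth)) {
        r <- truth[i] - yPred[i]
        if (truth[i] == 1 && yPred[i] > 1) r <- 0
        if (truth[i] == 0 && yPred[i] < 0) r <- 0
        press <- press + r^2
    }
    1 - press / tss
}

# A two-group spec with identical per-group moments (labels carry no
# information): the pooled default panel moments for both groups.
nullPanelSpec <- function(groupSizes = c(NW = 27L, SW = 11L)) {
    def <- defaultSyntheticSpec()
    m <- (def@targetMeans[1, ] + def@targetMeans[2, ]) / 2
    s <- (def@targetSds[1, ] + def@targetSds[2, ]) / 2
    syntheticCohortSpec(groupSizes = groupSizes,
                        markerNames = defaultMarkerPanel(),
                        targetMeans = rbind(m, m), targetSds = rbind(s, s),
                        family = "lognormal")
}

# A cleanly separable cohort: group membership is essentially determined
# by marker 1 (an 8-sigma gap); the rest are lognormal noise.
separableCohort <- function(n1 = 27, n2 = 11, p = 14, gap = 4,
                            seed = 1) {
    set.seed(seed)
    n <- n1 + n2
    X <- matrix(rlnorm(n * p, meanlog = 2, sdlog = 0.25), n, p)
    X[, 1] <- 10 + gap * rep(c(1, 0), c(n1, n2)) + rnorm(n, sd = gap / 8)
    colnames(X) <- paste0("M", seq_len(p))
    BiomarkerCohort(X, rep(c("NW", "SW"), c(n1, n2)))
}
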