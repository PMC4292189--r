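# NIPALS PLS1 engine: exact small cases, least-squares equivalence at
# full rank, orthogonality, ill-conditioned robustness, explained
# variance, serialisation, and agreement with an independent
# implementation.

test_that("one noiseless predictor is recovered exactly", {
    X <- matrix(1:4, ncol = 1)
    y <- 2 * (1:4)
    m <- fitPLS(X, y, nLV = 1, center = TRUE, scale = FALSE)
    expect_equal(unname(coef(m)), 2, tolerance = 1e-12)
    expect_equal(predict(m, X), y, tolerance = 1e-12)
})

test_that("a constant response gives a zero-coefficient model", {
    X <- matrix(rnorm(30), 10, 3)
    expect_warning(m <- fitPLS(X, rep(5, 10), nLV = 2), "stopped early")
    expect_equal(unname(coef(m)), rep(0, 3))
    expect_equal(predict(m, X), rep(5, 10))
    expect_identical(nLatent(m), 0L)
})

test_that("full-rank PLS coincides with least squares on a fixed toy", {
    set.seed(42)
    X <- matrix(rnorm(18), 6, 3)
    y <- rnorm(6)
    m <- fitPLS(X, y, nLV = 3)
    ols <- olsOracle(X, y)
    expect_equal(unname(coef(m)), ols$coef, tolerance = 1e-8)
    new <- matrix(rnorm(3), 1, 3)
    expect_equal(predict(m, new), ols$predict(new), tolerance = 1e-8)
})

test_that("full-rank equivalence holds across random instances", {
    set.seed(7)
    for (i in 1:20) {
        n <- sample(8:20, 1); p <- sample(2:6, 1)
        X <- matrix(rnorm(n * p), n, p)
        y <- rnorm(n)
        m <- fitPLS(X, y, nLV = p)
        expect_equal(unname(coef(m)), olsOracle(X, y)$coef,
                     tolerance = 1e-8)
    }
})

test_that("score columns are mutually orthogonal", {
    set.seed(8)
    for (i in 1:10) {
        X <- matrix(rnorm(20 * 6), 20, 6)
        y <- rnorm(20)
        Tm <- plsScores(fitPLS(X, y, nLV = 5))
        G <- crossprod(Tm)
        nrm <- sqrt(diag(G))
        off <- abs(G) / outer(nrm, nrm)
        diag(off) <- 0
        expect_lt(max(off), 1e-8)
    }
})

test_that("fitting survives p > n and perfectly collinear columns", {
    set.seed(9)
    X <- matrix(rnorm(8 * 20), 8, 20)       # p > n
    y <- rnorm(8)
    m <- fitPLS(X, y, nLV = 5)
    expect_identical(nLatent(m), 5L)
    X2 <- cbind(X[, 1:5], X[, 1])           # duplicated column
    m2 <- fitPLS(X2, y, nLV = 3)
    expect_identical(nLatent(m2), 3L)
    expect_true(all(is.finite(coef(m2))))
})

test_that("a row at the training means predicts the training mean of y", {
    set.seed(10)
    X <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
    m <- fitPLS(X, y, nLV = 2)
    expect_equal(predict(m, matrix(colMeans(X), 1)), mean(y),
                 tolerance = 1e-12)
    expect_equal(predict(m, X),
                 as.numeric(mean(y) +
                     gaitPLSDA:::applyPreprocessing(X, TRUE, TRUE,
                         m@xCenter, m@xScale) %*% coef(m)),
                 tolerance = 1e-12)
})

test_that("explained variance matches the reconstruction oracle", {
    # rank-1 X: one LV captures everything
    set.seed(11)
    u <- rnorm(8); v <- rnorm(3)
    X1 <- tcrossprod(u, v)
    m1 <- fitPLS(X1, rnorm(8), nLV = 1, scale = FALSE)
    expect_equal(sum(m1@explainedVarX), 1, tolerance = 1e-10)
    # exact linear y: cumulative y fraction 1 at full complexity
    X <- matrix(rnorm(40), 10, 4)
    y <- as.numeric(X %*% c(1, -2, 0.5, 3))
    mf <- fitPLS(X, y, nLV = 4)
    ev <- explainedVariance(mf)
    expect_equal(ev$yCumulative[4], 1, tolerance = 1e-10)
    expect_true(all(diff(ev$xCumulative) >= -1e-12))
    expect_equal(ev$xCumulative[4], 1, tolerance = 1e-10)
    # random matrix: compare to variance of the rank-a reconstruction
    Xr <- matrix(rnorm(40), 10, 4)
    yr <- rnorm(10)
    mr <- fitPLS(Xr, yr, nLV = 4)
    Xc <- gaitPLSDA:::applyPreprocessing(Xr, TRUE, TRUE, mr@xCenter,
                                         mr@xScale)
    Tm <- plsScores(mr); P <- mr@xLoadings
    for (a in 1:4) {
        recon <- Tm[, 1:a, drop = FALSE] %*% t(P[, 1:a, drop = FALSE])
        frac <- 1 - sum((Xc - recon)^2) / sum(Xc^2)
        expect_equal(explainedVariance(mr)$xCumulative[a], frac,
                     tolerance = 1e-8)
    }
})

test_that("invalid fits fail with informative errors", {
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    expect_error(fitPLS(X, y, nLV = 4), "min\\(n - 1, p\\)")
    Xz <- X; Xz[, 2] <- 7; colnames(Xz) <- c("a", "flat", "c")
    expect_error(fitPLS(Xz, y, nLV = 2), "flat")
    Xn <- X; Xn[2, 2] <- NA
    expect_error(fitPLS(Xn, y, nLV = 2), "missing")
    m <- fitPLS(X, y, nLV = 2)
    expect_error(predict(m, matrix(1, 2, 5)), "columns")
})

test_that("B = R q' and serialisation round-trips predictions exactly", {
    set.seed(12)
    X <- matrix(rnorm(60), 15, 4)
    y <- rnorm(15)
    m <- fitPLS(X, y, nLV = 3)
    expect_equal(unname(coef(m)),
                 as.numeric(m@projection %*% m@yLoadings),
                 tolerance = 1e-12)
    path <- tempfile(fileext = ".yaml")
    writePLSModel(m, path)
    m2 <- readPLSModel(path)
    new <- matrix(rnorm(20), 5, 4)
    expect_identical(predict(m2, new), predict(m, new))
})

test_that("coefficients agree with an independent PLS implementation", {
    skip_if_not_installed("mixOmics")
    set.seed(13)
    for (i in 1:5) {
        n <- 20; p <- 6; a <- 3
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("V", 1:p)))
        y <- rnorm(n)
        mine <- fitPLS(X, y, nLV = a)
        ref <- mixOmics::pls(X, y, ncomp = a, mode = "regression",
                             scale = TRUE)
        new <- matrix(rnorm(3 * p), 3, p,
                      dimnames = list(NULL, paste0("V", 1:p)))
        refPred <- predict(ref, new)$predict[, 1, a]
        expect_equal(predict(mine, new), unname(refPred),
                     tolerance = 1e-6)
    }
})
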