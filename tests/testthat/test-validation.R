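# Figures of merit and the cross-validation machinery.

test_that("NMC counts disagreeing positions", {
    expect_identical(nmc(c("NW", "NW", "SW"), c("NW", "NW", "SW")), 0L)
    expect_identical(nmc(c("NW", "NW", "SW"), c("NW", "SW", "SW")), 1L)
    set.seed(40)
    a <- sample(c("NW", "SW"), 100, replace = TRUE)
    b <- sample(c("NW", "SW"), 100, replace = TRUE)
    brute <- 0L
    for (i in 1:100) if (a[i] != b[i]) brute <- brute + 1L
    expect_identical(nmc(a, b), brute)
    expect_error(nmc(a, b[1:99]), "equal length")
})

test_that("AUROC is the Mann-Whitney pair-ordering probability", {
    expect_equal(auroc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                       c(1, 1, 1, 0, 0, 0)), 1)
    expect_equal(auroc(rep(0.4, 8), rep(c(1, 0), 4)), 0.5)
    s <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
    expect_equal(auroc(s, y), aurocBrute(s, y))
    expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC equals exhaustive pair counting on small instances", {
    set.seed(41)
    for (i in 1:200) {
        n <- sample(4:12, 1)
        y <- c(0, 1, rbinom(n - 2, 1, 0.5))
        # coarse score grid forces plenty of ties
        s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
        expect_equal(auroc(s, y), aurocBrute(s, y), tolerance = 1e-12)
    }
})

test_that("AUROC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(45)
    for (i in 1:10) {
        y <- c(0, 1, rbinom(18, 1, 0.5))
        s <- rnorm(20)
        ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<")))
        expect_equal(auroc(s, y), ref, tolerance = 1e-12)
    }
})

test_that("DQ2 truncates only correct-direction overshoot", {
    expect_equal(dq2(c(1.3, 1.0, -0.2, 0.0), c(1, 1, 0, 0)), 1)
    # no overshoot: equals the plain cross-validated Q2
    set.seed(42)
    y <- rep(c(1, 0), 5)
    p <- runif(10)            # inside [0, 1], no truncation possible
    expect_equal(dq2(p, y), 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    # perfectly inverted predictions are negative for any balance
    y2 <- c(1, 1, 1, 0, 0)
    expect_lt(dq2(1 - y2, y2), 0)
    expect_error(dq2(runif(4), rep(1, 4)), "single-class")
})

test_that("DQ2 dominates the untruncated Q2 on random vectors", {
    set.seed(43)
    for (i in 1:50) {
        n <- sample(6:30, 1)
        y <- c(0, 1, rbinom(n - 2, 1, 0.5))
        p <- rnorm(n, mean = 0.5, sd = 0.8)   # overshoots both ways
        q2 <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
        d <- dq2(p, y)
        expect_gte(d, q2 - 1e-12)
        expect_equal(d, dq2Direct(p, y), tolerance = 1e-12)
    }
})

test_that("inner CV reaches zero misclassifications on separable data", {
    for (s in c(44, 1, 2)) {
        co <- separableCohort(seed = s)
        y <- encodeClasses(groupLabels(co))
        cv <- kfoldCV(cohortMatrix(co), y, nLVMax = 8, k = 6, seed = 1)
        expect_identical(cv$merits$nmc[cv$chosen], 0L)
        expect_equal(cv$merits$auroc[cv$chosen], 1)
    }
})

test_that("cross-validated Q2 stays near or below zero on pure noise", {
    worst <- -Inf
    for (s in 1:20) {
        set.seed(500 + s)
        X <- matrix(rlnorm(40 * 14), 40, 14)
        y <- rep(c(1, 0), each = 20)
        cv <- kfoldCV(X, y, nLVMax = 8, k = 6, seed = s)
        worst <- max(worst, max(cv$merits$q2))
    }
    expect_lt(worst, 0.2)
})

test_that("k = n reduces to a deterministic leave-one-out assignment", {
    y <- rep(c(1, 0), each = 5)
    cv <- kfoldCV(matrix(rnorm(40), 10, 4), y, nLVMax = 2, k = 10,
                  seed = 1)
    expect_identical(cv$folds, 1:10)
})

test_that("too many folds for the class sizes fails with advice", {
    X <- matrix(rnorm(16), 4, 4)
    y <- c(1, 1, 1, 0)
    expect_error(kfoldCV(X, y, nLVMax = 2, k = 2, seed = 1),
                 "fewer folds")
})

test_that("double CV separates a strongly shifted cohort", {
    spec <- nullPanelSpec()
    co <- injectEffects(generateCohort(spec, seed = 45),
                        gaitPLSDA:::.defaultEffectDirections(), 2.0)
    res <- doubleCV(co, iterations = 50, seed = 46)
    s <- cvSummary(res)
    expect_gt(s$overall[s$level == "external"], 85)
})

test_that("double CV is seed-deterministic and covers every subject", {
    co <- generateCohort(defaultSyntheticSpec(), seed = 47)
    r1 <- doubleCV(co, iterations = 25, seed = 48)
    r2 <- doubleCV(co, iterations = 25, seed = 48)
    expect_identical(cvIterations(r1), cvIterations(r2))
    expect_identical(r1@externalPredictions, r2@externalPredictions)
    expect_true(all(r1@externalCounts >= 1L))
})

test_that("rate bookkeeping: overall is the class-size-weighted mean", {
    co <- generateCohort(defaultSyntheticSpec(), seed = 49)
    res <- doubleCV(co, iterations = 10, seed = 50)
    it <- cvIterations(res)
    n1 <- 27 - 5; n2 <- 11 - 2   # remainder class sizes at 20% holdout
    expect_equal(it$cal_overall,
                 (n1 * it$cal_pos + n2 * it$cal_neg) / (n1 + n2),
                 tolerance = 1e-10)
    expect_equal(it$cal_balanced, (it$cal_pos + it$cal_neg) / 2,
                 tolerance = 1e-10)
    s <- cvSummary(res)
    expect_equal(s$overall[1], mean(it$cal_overall), tolerance = 1e-12)
})

test_that("calibration dominates external rates on null data", {
    cal <- ext <- numeric(20)
    for (s in 1:20) {
        spec <- nullPanelSpec()
        co <- generateCohort(spec, seed = 600 + s)
        r <- doubleCV(co, iterations = 10, seed = 700 + s)
        sm <- cvSummary(r)
        cal[s] <- sm$balanced[sm$level == "calibration"]
        ext[s] <- sm$balanced[sm$level == "external"]
    }
    expect_gt(mean(cal), mean(ext))
})

test_that("permuted labels give chance-level balanced external rates", {
    co <- generateCohort(defaultSyntheticSpec(), seed = 51)
    set.seed(52)
    labs <- sample(groupLabels(co))
    r <- doubleCV(cohortMatrix(co), labs, iterations = 50, seed = 53)
    s <- cvSummary(r)
    bal <- s$balanced[s$level == "external"]
    expect_gt(bal, 40); expect_lt(bal, 60)
})

test_that("degenerate designs are rejected", {
    X <- matrix(rnorm(20 * 14), 20, 14)
    labs <- rep(c("NW", "SW"), c(19, 1))
    expect_error(doubleCV(X, labs, iterations = 2, seed = 1),
                 "at least 2 subjects")
    expect_error(gaitPLSDA:::stratifiedHoldout(labs, 0.9),
                 "empty class")
    expect_error(doubleCV(X, rep(c("NW", "SW"), 10), outerFraction = 0.7,
                          iterations = 2, seed = 1),
                 "outerFraction")
})
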