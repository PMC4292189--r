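# Synthetic-cohort generator: moment matching, copula correlation,
# determinism, effect injection.

test_that("lognormal parameterisation is exactly moment-matched", {
    spec <- defaultSyntheticSpec()
    for (g in 1:2) for (j in seq_along(spec@markerNames)) {
        m <- spec@targetMeans[g, j]; s <- spec@targetSds[g, j]
        par <- gaitPLSDA:::.lognormalParams(m, s)
        expect_equal(exp(par$mu + par$sigma^2 / 2), m, tolerance = 1e-12)
        expect_equal((exp(par$sigma^2) - 1) * exp(2 * par$mu + par$sigma^2),
                     s^2, tolerance = 1e-10)
    }
})

test_that("generated moments converge to the published IL8 targets", {
    spec <- defaultSyntheticSpec()
    big <- generateCohort(spec, seed = 101,
                          groupSizes = c(100000L, 1000L))
    x <- cohortMatrix(big)[groupLabels(big) == "NW", "IL8"]
    expect_lt(abs(mean(x) - 3.70) / 3.70, 0.01)
    expect_lt(abs(sd(x) - 1.67) / 1.67, 0.02)
})

test_that("per-group sample means converge to targets for every marker", {
    spec <- defaultSyntheticSpec()
    big <- generateCohort(spec, seed = 7,
                          groupSizes = c(100000L, 100000L))
    X <- cohortMatrix(big)
    g <- groupLabels(big)
    for (gi in 1:2) {
        rows <- g == rownames(spec@targetMeans)[gi]
        mns <- colMeans(X[rows, ])
        expect_true(all(abs(mns - spec@targetMeans[gi, ]) /
                            spec@targetMeans[gi, ] < 0.02))
    }
    # SD convergence at 2% is only checkable where the tails are tame:
    # for heavy-tailed markers (SD > mean) the sampling error of the
    # sample SD itself exceeds 2% at this n, so restrict to CV < 1.
    tame <- spec@targetSds[1, ] < spec@targetMeans[1, ]
    sds <- apply(X[g == "NW", tame], 2, sd)
    expect_true(all(abs(sds - spec@targetSds[1, tame]) /
                        spec@targetSds[1, tame] < 0.02))
})

test_that("identity copula yields near-zero inter-marker correlation", {
    spec <- defaultSyntheticSpec()
    big <- generateCohort(spec, seed = 3, groupSizes = c(10000L, 100L))
    X <- cohortMatrix(big)[groupLabels(big) == "NW", ]
    r <- cor(X)
    expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("a latent correlation propagates through the copula", {
    p <- length(defaultMarkerPanel())
    C <- diag(p); C[1, 2] <- C[2, 1] <- 0.8
    spec <- defaultSyntheticSpec()
    spec2 <- syntheticCohortSpec(markerNames = defaultMarkerPanel(),
                                 targetMeans = spec@targetMeans,
                                 targetSds = spec@targetSds,
                                 correlation = C)
    big <- generateCohort(spec2, seed = 3, groupSizes = c(5000L, 100L))
    X <- cohortMatrix(big)[groupLabels(big) == "NW", ]
    expect_gt(cor(X[, 1], X[, 2]), 0.4)
})

test_that("generation is seed-deterministic and strictly positive", {
    spec <- defaultSyntheticSpec()
    a <- generateCohort(spec, seed = 11)
    b <- generateCohort(spec, seed = 11)
    c <- generateCohort(spec, seed = 12)
    expect_identical(cohortMatrix(a), cohortMatrix(b))
    expect_false(identical(cohortMatrix(a), cohortMatrix(c)))
    expect_true(all(cohortMatrix(a) > 0))
    expect_identical(as.integer(table(groupLabels(a))[c("NW", "SW")]),
                     c(27L, 11L))
})

test_that("truncated-normal family moment-matches where feasible", {
    par <- gaitPLSDA:::.truncnormParams(10, 4)  # CV = 0.4 < 1
    alpha <- -par$mu / par$sigma
    lam <- dnorm(alpha) / pnorm(alpha, lower.tail = FALSE)
    expect_equal(par$mu + par$sigma * lam, 10, tolerance = 1e-8)
    expect_equal(par$sigma * sqrt(1 + alpha * lam - lam^2), 4,
                 tolerance = 1e-8)
    spec <- syntheticCohortSpec(markerNames = c("A", "B"),
                                targetMeans = rbind(c(10, 5), c(10, 5)),
                                targetSds = rbind(c(4, 2), c(4, 2)),
                                family = "truncated-normal")
    co <- generateCohort(spec, seed = 5, groupSizes = c(20000L, 100L))
    x <- cohortMatrix(co)[groupLabels(co) == "NW", "A"]
    expect_true(all(x >= 0))
    expect_lt(abs(mean(x) - 10) / 10, 0.02)
    expect_lt(abs(sd(x) - 4) / 4, 0.03)
    expect_error(gaitPLSDA:::.truncnormParams(5, 6), "cannot match")
})

test_that("invalid specifications are rejected with informative errors", {
    C <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
    expect_error(
        syntheticCohortSpec(markerNames = c("A", "B", "C"),
                            targetMeans = matrix(1, 2, 3),
                            targetSds = matrix(1, 2, 3),
                            correlation = C),
        "positive semi-definite")
    expect_error(
        syntheticCohortSpec(markerNames = "A",
                            targetMeans = matrix(1, 2, 1),
                            targetSds = matrix(c(0, 1), 2, 1)),
        "SDs must be positive")
})

test_that("injectEffects shifts flagged group means and nothing else", {
    spec <- nullPanelSpec(groupSizes = c(NW = 1000L, SW = 1000L))
    co <- generateCohort(spec, seed = 21)
    expect_identical(injectEffects(co, c("IL8" = -1), 0), co)
    up <- injectEffects(co, c("P-selectin" = 1), 1.5)
    g <- groupLabels(up)
    Xup <- cohortMatrix(up)
    expect_gt(mean(Xup[g == "NW", "P-selectin"]),
              mean(Xup[g == "SW", "P-selectin"]))
    down <- injectEffects(co, c("IL8" = -1), 1.5)
    Xd <- cohortMatrix(down)
    expect_gt(mean(Xd[g == "SW", "IL8"]), mean(Xd[g == "NW", "IL8"]))
    # unflagged markers untouched
    expect_identical(Xd[, "IL6"], cohortMatrix(co)[, "IL6"])
    expect_error(injectEffects(co, c("nope" = 1), 1), "unknown marker")
})
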