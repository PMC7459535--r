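test_that("group-means OLS equals the normal-equations oracle", {
    set.seed(21)
    groups <- c("a", "a", "b", "b", "b", "c")
    X <- groupDesign(setNames(groups, paste0("s", 1:6)))
    m <- matrix(rnorm(5 * 6), 5, 6,
                dimnames = list(paste0("cg", 1:5), paste0("s", 1:6)))
    fit <- fitLinearModel(m, X)
    for (i in 1:5) {
        o <- olsOracle(m[i, ], X)
        expect_equal(unname(fit@coefficients[i, ]), unname(o$coef),
                     tolerance = 1e-10)
        expect_equal(fit@sigma2[i], o$sigma2, tolerance = 1e-10)
    }
    expect_equal(fit@df, 3)
    expect_equal(unname(fit@covUnscaled), unname(solve(crossprod(X))),
                 tolerance = 1e-12)
    # group-means design: coefficients are group means, singleton group =
    # that sample's value
    expect_equal(fit@coefficients[, "a"], rowMeans(m[, 1:2]),
                 ignore_attr = TRUE)
    expect_equal(fit@coefficients[, "c"], m[, 6], ignore_attr = TRUE)
})

test_that("the 12-sample cell-culture design has 6 residual df", {
    groups <- rep(paste0(rep(c("b", "p", "k"), each = 2),
                         c("_cancer", "_primary")), times = c(3, 1, 3, 1, 3, 1))
    X <- groupDesign(groups)
    m <- matrix(rnorm(2 * 12), 2, 12, dimnames = list(c("cg1", "cg2"), NULL))
    expect_equal(fitLinearModel(m, X)@df, 6)
})

test_that("rank-deficient designs are rejected naming the aliased column", {
    X <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), c = c(1, 1, 1, 1))
    m <- matrix(rnorm(4), 1, 4, dimnames = list("cg1", NULL))
    expect_error(fitLinearModel(m, X), "rank deficient.*c")
})

test_that("sites with missing values are dropped with a warning", {
    X <- groupDesign(c("a", "a", "b", "b"))
    m <- matrix(rnorm(8), 2, 4, dimnames = list(c("cg1", "cg2"), NULL))
    m[2, 1] <- NA
    expect_warning(fit <- fitLinearModel(m, X), "1 site")
    expect_identical(rownames(fit@coefficients), "cg1")
    expect_identical(attr(fit, "droppedSites"), "cg2")
})

test_that("contrast estimates and variances propagate correctly", {
    set.seed(22)
    X <- groupDesign(c("a", "a", "b", "b", "c", "c", "c"))
    m <- matrix(rnorm(4 * 7), 4, 7, dimnames = list(paste0("cg", 1:4), NULL))
    fit <- fitLinearModel(m, X)
    # identity contrast leaves the fit unchanged
    id <- diag(3); dimnames(id) <- list(colnames(X), colnames(X))
    fid <- applyContrasts(fit, id)
    expect_equal(fid@coefficients, fit@coefficients)
    expect_equal(fid@covUnscaled, fit@covUnscaled)
    # difference contrast equals difference of group means
    cb <- makeContrasts2(X, aVsB = c("a", "b"))
    fab <- applyContrasts(fit, cb)
    expect_equal(unname(fab@coefficients[, 1]),
                 unname(fit@coefficients[, "a"] - fit@coefficients[, "b"]))
    # contrast variance equals c' (X'X)^-1 c
    XtXi <- solve(crossprod(X))
    expect_equal(unname(fab@covUnscaled[1, 1]),
                 unname(drop(t(cb) %*% XtXi %*% cb)), tolerance = 1e-10)
    expect_error(applyContrasts(fit, matrix(1, 5, 1)), "must match")
})

test_that("constant variances collapse the prior onto the common value", {
    X <- groupDesign(c("a", "a", "a", "b", "b", "b"))
    base <- c(1, -1, 0, 2, 0, -2) * 0.5   # same residual pattern per site
    m <- rbind(cg1 = base + rep(c(0, 3), each = 3),
               cg2 = base + rep(c(1, 5), each = 3),
               cg3 = base)
    fit <- applyContrasts(fitLinearModel(m, X),
                          makeContrasts2(X, ab = c("a", "b")))
    mod <- eBayesModerate(fit)
    expect_equal(mod@s02, fit@sigma2[1], tolerance = 1e-6)
    expect_equal(mod@s2Post, fit@sigma2, tolerance = 1e-6)
})

test_that("zero prior df reproduces the ordinary t-statistic", {
    set.seed(23)
    X <- groupDesign(rep(c("a", "b"), each = 4))
    m <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(paste0("cg", 1:50), NULL))
    fit <- applyContrasts(fitLinearModel(m, X),
                          makeContrasts2(X, ab = c("a", "b")))
    mod <- eBayesModerate(fit, priorDf = 0)
    ordT <- fit@coefficients[, 1] /
        (sqrt(fit@covUnscaled[1, 1]) * sqrt(fit@sigma2))
    expect_equal(unname(mod@tStat[, 1]), unname(ordT), tolerance = 1e-12)
    expect_equal(mod@dfTotal, fit@df)
})

test_that("posterior variance is a convex combination, monotone in d0", {
    set.seed(24)
    X <- groupDesign(rep(c("a", "b"), each = 3))
    m <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(paste0("cg", 1:200), NULL))
    fit <- applyContrasts(fitLinearModel(m, X),
                          makeContrasts2(X, ab = c("a", "b")))
    mod <- eBayesModerate(fit)
    expect_true(all(mod@s2Post >= pmin(fit@sigma2, mod@s02) - 1e-12))
    expect_true(all(mod@s2Post <= pmax(fit@sigma2, mod@s02) + 1e-12))
    # larger prior df pulls the posterior closer to s0^2 (same s02 under
    # fixed priorDf: the geometric mean of the observed variances)
    lo <- eBayesModerate(fit, priorDf = 1)
    hi <- eBayesModerate(fit, priorDf = 100)
    expect_equal(lo@s02, hi@s02)
    expect_true(mean(abs(hi@s2Post - hi@s02)) <
                mean(abs(lo@s2Post - lo@s02)))
})

test_that("moderated statistics agree with the limma reference", {
    skip_if_not_installed("limma")
    set.seed(25)
    X <- groupDesign(rep(c("a", "b", "c"), each = 3))
    m <- matrix(rnorm(500 * 9, sd = 0.7), 500, 9,
                dimnames = list(paste0("cg", 1:500), paste0("s", 1:9)))
    cb <- makeContrasts2(X, ab = c("a", "b"), ac = c("a", "c"))
    mod <- eBayesModerate(applyContrasts(fitLinearModel(m, X), cb))
    lf <- limma::lmFit(m, X)
    lf <- limma::contrasts.fit(lf, cb)
    lf <- limma::eBayes(lf)
    expect_equal(mod@d0, lf$df.prior, tolerance = 1e-6)
    expect_equal(mod@s02, lf$s2.prior, tolerance = 1e-6)
    expect_equal(unname(mod@tStat), unname(lf$t), tolerance = 1e-8)
    expect_equal(unname(mod@pValue), unname(lf$p.value), tolerance = 1e-8)
})

test_that("moderated F reduces to t^2 and matches the quadratic form", {
    set.seed(26)
    X <- groupDesign(rep(c("a", "b", "c"), each = 3))
    cb <- makeContrasts2(X, ab = c("a", "b"), ac = c("a", "c"))
    m <- matrix(rnorm(20 * 9), 20, 9,
                dimnames = list(paste0("cg", 1:20), NULL))
    mod <- eBayesModerate(applyContrasts(fitLinearModel(m, X), cb))
    f1 <- moderatedF(mod, "ab")
    expect_equal(f1$F, unname(mod@tStat[, "ab"]^2), tolerance = 1e-12)
    expect_equal(f1$pValue, unname(mod@pValue[, "ab"]), tolerance = 1e-12)
    # two contrasts: brute-force quadratic form
    f2 <- moderatedF(mod)
    V <- mod@covUnscaled
    for (i in c(1, 7, 20)) {
        b <- mod@coefficients[i, ]
        expect_equal(f2$F[i],
                     drop(t(b) %*% solve(V) %*% b) / (2 * mod@s2Post[i]),
                     tolerance = 1e-10)
    }
    expect_error(moderatedF(mod, character(0)), "empty")
})

test_that("null moderated p-values are approximately uniform", {
    set.seed(27)
    X <- groupDesign(rep(c("a", "b"), each = 6))
    m <- matrix(rnorm(20000 * 12), 20000, 12,
                dimnames = list(paste0("cg", 1:20000), NULL))
    mod <- eBayesModerate(applyContrasts(fitLinearModel(m, X),
                                         makeContrasts2(X, ab = c("a", "b"))))
    p <- sort(mod@pValue[, 1])
    ks <- max(abs(p - seq_along(p) / length(p)))
    expect_lt(ks, 0.02)
})

test_that("BH adjustment equals the naive step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.04, 5)), rep(0.04, 5))
    set.seed(28)
    for (i in 1:5) {
        p <- runif(37)
        expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
        expect_true(all(diff(bhAdjust(sort(p))) >= -1e-15))  # order-preserving
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("decision matrix signs follow q-threshold and estimate sign", {
    mod <- new("ModeratedFit",
               new("MethylFit",
                   coefficients = cbind(ct = c(2, 1.5, -1, 0.5)),
                   covUnscaled = matrix(1, 1, 1,
                                        dimnames = list("ct", "ct")),
                   sigma2 = rep(1, 4), df = 4,
                   design = matrix(1, 5, 1)),
               d0 = 1, s02 = 1, s2Post = rep(1, 4), dfTotal = 5,
               tStat = cbind(ct = c(5, 4, -3, 1)),
               pValue = cbind(ct = c(0.01, 0.2, 0.04, 0.5)),
               qValue = cbind(ct = c(0.01, 0.2, 0.04, 0.5)))
    expect_identical(unname(decisionMatrix(mod, 0.05)[, 1]),
                     c(1L, 0L, -1L, 0L))
})

test_that("delta beta averages cancer lines and subtracts the primary", {
    b <- rbind(cg1 = c(0.9, 0.9, 0.9, 0.2),
               cg2 = c(0.4, 0.4, 0.4, 0.4),
               cg3 = c(0.1, 0.2, 0.3, 0.6))
    colnames(b) <- c("l1", "l2", "l3", "prim")
    d <- deltaBeta(b, c("l1", "l2", "l3"), "prim")
    expect_equal(unname(d), c(0.7, 0, -0.4))
    b[1, 2] <- NA
    expect_true(is.na(deltaBeta(b, c("l1", "l2", "l3"), "prim")["cg1"]))
    expect_error(deltaBeta(b, c("l1", "nope"), "prim"), "not present")
})
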