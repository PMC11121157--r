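test_that("a view is perfectly canonically correlated with itself", {
    v <- makeViews(20, 5, 5, seed = 21)$x
    fit <- fitSCCA(v, v, SCCAConfig(nComponents = 1))
    expect_equal(canonicalCorrelations(fit), 1, tolerance = 1e-8)
})

test_that("classical CCA recovers exact structure and its invariances", {
    set.seed(22)
    sids <- sprintf("S%03d", 1:50)
    X <- matrix(rnorm(100), 50, 2, dimnames = list(sids, c("a", "b")))
    Y <- cbind(dup = X[, 1])
    cc <- classicalCCA(OmicsView(X), OmicsView(Y), k = 1)
    expect_equal(cc$correlations, 1, tolerance = 1e-10)

    ## independent views: correlations near zero at n = 1000
    set.seed(23)
    sids <- sprintf("S%04d", 1:1000)
    A <- matrix(rnorm(2000), 1000, 2, dimnames = list(sids, c("a", "b")))
    B <- matrix(rnorm(2000), 1000, 2, dimnames = list(sids, c("c", "d")))
    cc0 <- classicalCCA(OmicsView(A), OmicsView(B), k = 2)
    expect_lt(max(cc0$correlations), 0.15)

    ## invariance to invertible re-mixing of X's columns
    vw <- makeViews(30, 4, 3, seed = 24)
    cc1 <- classicalCCA(vw$x, vw$y, k = 3)
    set.seed(25)
    Mix <- matrix(rnorm(16), 4, 4)
    mixed <- omicsValues(vw$x) %*% Mix
    colnames(mixed) <- featureNames(vw$x)
    cc2 <- classicalCCA(OmicsView(mixed), vw$y, k = 3)
    expect_equal(cc1$correlations, cc2$correlations, tolerance = 1e-8)

    ## agreement with the QR-based reference implementation
    ref <- cancor(omicsValues(vw$x), omicsValues(vw$y))
    expect_equal(cc1$correlations, ref$cor[1:3], tolerance = 1e-8)

    ## collinear features produce a singular covariance
    Xs <- cbind(omicsValues(vw$x), dup2 = omicsValues(vw$x)[, 1])
    expect_error(classicalCCA(OmicsView(Xs), vw$y, 1), "ridge")
})

test_that("unpenalized sCCA equals classical CCA across components", {
    for (seed in c(31, 32, 33, 34, 35)) {
        vw <- makeViews(20, 5, 4, seed = seed)
        cc <- classicalCCA(vw$x, vw$y, k = 3)
        fit <- fitSCCA(vw$x, vw$y,
                       SCCAConfig(nComponents = 3, tol = 1e-12,
                                  maxIter = 5000))
        expect_equal(canonicalCorrelations(fit), cc$correlations,
                     tolerance = 1e-6, label = sprintf("seed %d", seed))
    }
})

test_that("score variances are unit, correlation ascends, and the sign convention holds", {
    vw <- makeViews(40, 8, 6, seed = 41)
    fit <- fitSCCA(vw$x, vw$y, SCCAConfig(nComponents = 2, tol = 1e-10))
    for (cc in fit@components) {
        expect_equal(var(cc@u), 1, tolerance = 1e-6)
        expect_equal(var(cc@v), 1, tolerance = 1e-6)
        expect_equal(cc@correlation, cor(cc@u, cc@v), tolerance = 1e-12)
        expect_lte(abs(cc@correlation), 1)
        ## monotone ascent of the correlation with tau = 0
        expect_true(all(diff(cc@corrTrace) > -1e-9))
        ## largest-|w1| entry is positive
        expect_gt(cc@w1[which.max(abs(cc@w1))], 0)
    }
    ## bit-for-bit reproducibility
    fit2 <- fitSCCA(vw$x, vw$y, SCCAConfig(nComponents = 2, tol = 1e-10))
    expect_identical(canonicalWeights(fit, "x"), canonicalWeights(fit2, "x"))
})

test_that("penalties that zero a view raise the view-specific error", {
    vw <- makeViews(30, 5, 4, seed = 51)
    expect_error(fitSCCA(vw$x, vw$y, SCCAConfig(tau1 = 50, tau2 = 0)),
                 "view 1")
    expect_error(fitSCCA(vw$x, vw$y, SCCAConfig(tau1 = 0, tau2 = 50)),
                 "view 2")
})

test_that("w1 support shrinks as tau1 grows on a fixed dataset", {
    sim <- genPairedOmics(n = 80, p = 60, q = 50, kLatent = 1,
                          nClusters = 1, nNonzeroPerView = 8,
                          clusterSeparation = 0, seed = 52)
    xs <- standardizeColumns(sim$x); ys <- standardizeColumns(sim$y)
    sizes <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.35), function(tau) {
        f <- fitSCCA(xs, ys, SCCAConfig(tau1 = tau, tau2 = 0.1,
                                        ridge1 = 1e-3, ridge2 = 1e-3))
        sum(f@components[[1]]@w1 != 0)
    }, 0L)
    expect_true(all(diff(sizes) <= 0))
})

test_that("deflation residualizes, preserves orthogonal columns, and is idempotent", {
    set.seed(61)
    n <- 30
    sids <- sprintf("S%03d", 1:n)
    score <- rnorm(n)
    sc <- score - mean(score)
    orth <- rnorm(n)
    orth <- orth - mean(orth)
    orth <- orth - sc * sum(orth * sc) / sum(sc^2)   # exactly orthogonal
    M <- cbind(prop = 2.5 * score, orth = orth, mix = rnorm(n))
    rownames(M) <- sids
    v <- OmicsView(M)
    d <- deflate(v, score)
    ## proportional column vanishes
    expect_false("prop" %in% featureNames(d))
    ## every remaining column orthogonal to the centered score
    expect_lt(max(abs(crossprod(omicsValues(d), sc))), 1e-8)
    ## orthogonal column survives as its standardized self
    expect_equal(omicsValues(d)[, "orth"],
                 drop(scale(orth))[seq_len(n)] * sign(1),
                 tolerance = 1e-10, ignore_attr = TRUE)
    ## idempotence
    d2 <- deflate(d, score)
    expect_equal(omicsValues(d2), omicsValues(d), tolerance = 1e-10)
})

test_that("score aggregation shapes, z-scoring and mode symmetry", {
    vw <- makeViews(25, 6, 5, seed = 71)
    fit <- fitSCCA(vw$x, vw$y, SCCAConfig(nComponents = 2))
    both <- aggregateScores(fit, "both_views")
    expect_equal(dim(both), c(25, 4))
    expect_equal(unname(colMeans(both)), rep(0, 4), tolerance = 1e-12)
    expect_equal(unname(apply(both, 2, sd)), rep(1, 4), tolerance = 1e-12)
    expect_identical(rownames(both), sampleNames(vw$x))

    xonly <- aggregateScores(fit, "x_only")
    expect_equal(dim(xonly), c(25, 2))
    expect_equal(unname(xonly[, 1]),
                 drop(scale(fit@components[[1]]@u)), tolerance = 1e-12,
                 ignore_attr = TRUE)

    ## mean_of_views with u = v collapses to x_only: self-paired fit
    self <- fitSCCA(vw$x, vw$x, SCCAConfig(nComponents = 1))
    expect_equal(aggregateScores(self, "mean_of_views"),
                 aggregateScores(self, "x_only"), tolerance = 1e-6)
})
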