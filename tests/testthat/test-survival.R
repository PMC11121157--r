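test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
    time <- 1:6
    event <- c(1, 0, 1, 1, 0, 1)
    km <- kmCurve(time, event)
    expect_equal(km@eventTimes, c(1, 3, 4, 6))
    expect_equal(km@survival, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
                 tolerance = 1e-10)
    ## against the generic hand oracle
    oracle <- kmHand(time, event)
    expect_equal(km@survival, oracle$surv, tolerance = 1e-12)
    expect_equal(km@atRisk, c(6L, 4L, 3L, 1L))
    ## Greenwood SE at the first event time: S * sqrt(d/(n(n-d)))
    expect_equal(km@greenwoodSE[1], 5 / 6 * sqrt(1 / (6 * 5)),
                 tolerance = 1e-10)
})

test_that("Kaplan-Meier degenerate cases", {
    allCens <- kmCurve(c(2, 4, 8), c(0, 0, 0))
    expect_length(allCens@eventTimes, 0)          # survival stays at 1
    one <- kmCurve(5, 1)
    expect_equal(one@eventTimes, 5)
    expect_equal(one@survival, 0)
    expect_error(kmCurve(numeric(0), integer(0)), "empty")
})

test_that("log-rank test: null balance, separation, and relabeling invariance", {
    ## identical (time, event) multisets in both groups
    time <- rep(c(1, 2, 3, 4), 2)
    event <- rep(c(1, 1, 0, 1), 2)
    grp <- rep(1:2, each = 4)
    lr <- logrankTest(time, event, grp)
    expect_equal(lr$chi2, 0, tolerance = 1e-10)
    expect_equal(lr$p, 1, tolerance = 1e-10)

    ## clearly separated groups, checked against the hand statistic
    t2 <- c(1, 2, 3, 10, 20, 30)
    e2 <- rep(1, 6)
    g2 <- rep(1:2, each = 3)
    lr2 <- logrankTest(t2, e2, g2)
    expect_lt(lr2$p, 0.05)
    expect_equal(lr2$chi2, logrankHand(t2, e2, g2), tolerance = 1e-8)

    ## permutation-null oracle (3 vs 3 admits only choose(6,3) = 20
    ## relabelings, so the permutation check uses 8 vs 8)
    t3 <- c(1:8, 101:108)
    e3 <- rep(1, 16)
    g3 <- rep(1:2, each = 8)
    lr3 <- logrankTest(t3, e3, g3)
    set.seed(101)
    permStats <- replicate(2000, logrankHand(t3, e3, sample(g3)))
    permP <- mean(permStats >= lr3$chi2 - 1e-12)
    expect_lt(permP, 0.05)
    expect_lt(lr3$p, 0.05)

    ## 3-group statistic invariant to relabeling
    set.seed(102)
    t3 <- rexp(60) + 0.1
    e3 <- rbinom(60, 1, 0.8)
    g3 <- rep(1:3, 20)
    lrA <- logrankTest(t3, e3, g3)
    lrB <- logrankTest(t3, e3, c(3, 1, 2)[g3])
    expect_equal(lrA$chi2, lrB$chi2, tolerance = 1e-10)
    expect_error(logrankTest(t3, e3, rep(1, 60)), "two groups")
})

test_that("grouped Cox fit recovers a known hazard ratio and centers coefficients", {
    lab <- rep(1:2, each = 500)
    sv <- genSubtypeSurvival(lab, c(0, log(2)), baselineRate = 0.2,
                             censoringRate = 0, seed = 111)
    fit <- coxFitSubtypes(survivalTime(sv), survivalEvent(sv), lab)
    hr <- fit@hrMatrix[2, 1]
    expect_gt(hr, 1.7); expect_lt(hr, 2.4)
    expect_equal(sum(fit@groupSizes * fit@beta), 0, tolerance = 1e-10)
    ## antisymmetry of the ratio matrix
    expect_equal(fit@hrMatrix * t(fit@hrMatrix),
                 matrix(1, 2, 2), tolerance = 1e-10, ignore_attr = TRUE)

    ## identical groups: coefficients near zero
    set.seed(112)
    t0 <- rexp(100) + 0.01
    e0 <- rbinom(100, 1, 0.9)
    fit0 <- coxFitSubtypes(rep(t0, 2), rep(e0, 2), rep(1:2, each = 100))
    expect_equal(fit0@beta, c(0, 0), tolerance = 1e-8)
    expect_equal(fit0@hrMin, 1, tolerance = 1e-8)
})

test_that("six-sample Cox coefficient matches the Efron partial-likelihood oracle", {
    time <- c(1, 2, 4, 5, 7, 9)
    event <- c(1, 1, 0, 1, 1, 1)
    lab <- c(1, 2, 1, 2, 1, 2)
    fit <- coxFitSubtypes(time, event, lab, ties = "efron")
    betaHat <- fit@beta[2] - fit@beta[1]    # group-2 effect vs group 1
    x <- as.numeric(lab == 2)
    grid <- seq(-5, 5, by = 0.001)
    ll <- vapply(grid, efronLogLik, numeric(1), time = time,
                 event = event, x = x)
    betaGrid <- grid[which.max(ll)]
    betaOracle <- optimize(efronLogLik, c(betaGrid - 0.01, betaGrid + 0.01),
                           time = time, event = event, x = x,
                           maximum = TRUE)$maximum
    expect_equal(betaHat, betaOracle, tolerance = 1e-4)
})

test_that("HRmin follows its definition and SEP both conventions", {
    ## pre-centering beta (0, ln 2, ln 8): pairwise max ratios 2, 8, 4
    expect_equal(hrMin(c(0, log(2), log(8))), 2, tolerance = 1e-12)
    expect_equal(hrMin(c(0, 0)), 1)
    ## invariant to permuting groups
    expect_equal(hrMin(c(log(8), 0, log(2))), 2, tolerance = 1e-12)

    ## SEP by direct formula on an equal-size two-group fit:
    ## force beta = (0.5, -0.5) through a synthetic fit object
    lab <- rep(1:2, each = 10)
    sv <- genSubtypeSurvival(lab, c(0.5, -0.5), baselineRate = 0.2,
                             censoringRate = 0, seed = 113)
    fit <- coxFitSubtypes(survivalTime(sv), survivalEvent(sv), lab)
    ## conventions are exact reciprocals and bounded as documented
    expect_equal(sepStatistic(fit, "printed") * sepStatistic(fit, "reciprocal"),
                 1, tolerance = 1e-10)
    expect_lte(sepStatistic(fit, "printed"), 1)
    expect_gte(sepStatistic(fit, "reciprocal"), 1)
    ## analytic check of the formula at beta = (0.5, -0.5), equal sizes
    betaFixed <- c(0.5, -0.5)
    sizes <- c(10, 10)
    sepPrinted <- exp(-sum(sizes / sum(sizes) * abs(betaFixed)))
    expect_equal(sepPrinted, exp(-0.5), tolerance = 1e-12)
    expect_equal(1 / sepPrinted, exp(0.5), tolerance = 1e-12)
})

test_that("HRmin is at least 1 and SEP bounded on arbitrary fits", {
    for (s in 1:5) {
        set.seed(s)
        n <- 90
        lab <- sample(1:3, n, replace = TRUE)
        t0 <- rexp(n, rate = 0.1 * exp(0.3 * lab)) + 0.01
        e0 <- rbinom(n, 1, 0.85)
        if (sum(e0) < 5) next
        fit <- suppressWarnings(coxFitSubtypes(t0, e0, lab))
        expect_gte(fit@hrMin, 1)
        expect_lte(fit@sepPrinted, 1)
        expect_gte(fit@sepReciprocal, 1)
        expect_equal(sum(fit@groupSizes * fit@beta), 0, tolerance = 1e-8)
        lg <- log(fit@hrMatrix)
        expect_equal(lg, -t(lg), tolerance = 1e-10, ignore_attr = TRUE)
    }
})

test_that("global Schoenfeld test equals the single-covariate test at df = 1", {
    lab <- rep(1:2, each = 150)
    sv <- genSubtypeSurvival(lab, c(0, log(2)), baselineRate = 0.1,
                             censoringRate = 0.1, seed = 121)
    g <- schoenfeldGST(time = survivalTime(sv), event = survivalEvent(sv),
                       labels = lab)
    expect_identical(g$df, 1L)
    zph <- survival::cox.zph(
        survival::coxph(survival::Surv(survivalTime(sv),
                                       survivalEvent(sv)) ~ factor(lab)),
        transform = "rank")
    expect_equal(g$chi2, zph$table[1, "chisq"], tolerance = 1e-8)

    ## fewer events than degrees of freedom
    expect_error(schoenfeldGST(time = c(1, 2, 3, 4),
                               event = c(1, 0, 0, 0),
                               labels = c(1, 1, 2, 2)),
                 "fewer events")
})

test_that("monotone likelihood is capped rather than divergent", {
    ## group 1 all events before any group-2 event
    time <- c(1, 2, 3, 10, 11, 12)
    event <- rep(1, 6)
    lab <- rep(1:2, each = 3)
    expect_warning(fit <- coxFitSubtypes(time, event, lab), "capped")
    expect_true(all(abs(fit@beta) <= 15))
    expect_gte(fit@hrMin, 1)
})
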