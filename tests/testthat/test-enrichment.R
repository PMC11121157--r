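## helper: expression view with n samples and given gene count
exprView <- function(n, nGenes, seed) {
    set.seed(seed)
    OmicsView(matrix(rnorm(n * nGenes), n, nGenes,
                     dimnames = list(sprintf("S%03d", seq_len(n)),
                                     sprintf("g%03d", seq_len(nGenes)))))
}

test_that("differential expression is calibrated under the null", {
    falsePositives <- vapply(1:10, function(s) {
        v <- exprView(40, 200, seed = 200 + s)
        de <- subtypeDE(v, rep(1:2, each = 20), subtype = 1)
        sum(de$q_value <= 0.05)
    }, numeric(1))
    expect_lte(sum(falsePositives), 2)
})

test_that("shifted genes are detected as up-regulated with direction antisymmetry", {
    set.seed(211)
    v <- exprView(40, 200, seed = 211)
    m <- omicsValues(v)
    labels <- rep(1:2, each = 20)
    m[labels == 1, 1:20] <- m[labels == 1, 1:20] + 3   # 3 sd shift
    v <- OmicsView(m)
    de <- subtypeDE(v, labels, subtype = 1)
    expect_gte(sum(de$direction[1:20] == "up"), 18)
    expect_equal(sum(de$direction[-(1:20)] != "ns"), 0)

    ## flipping the contrast swaps directions and negates statistics
    deFlip <- subtypeDE(v, labels, subtype = 2)
    expect_equal(deFlip$mean_diff, -de$mean_diff, tolerance = 1e-12)
    expect_equal(deFlip$t_stat, -de$t_stat, tolerance = 1e-12)
    expect_identical(deFlip$direction[de$direction == "up"] ,
                     rep("down", sum(de$direction == "up")))
    expect_error(subtypeDE(v, labels, subtype = 3), "3 samples")
})

test_that("hypergeometric ORA is exact on the complete-overlap toy", {
    db <- GeneSetDB(list(s1 = paste0("g", 1:5)),
                    universe = paste0("g", 1:20))
    res <- oraTest(paste0("g", 1:5), db)
    expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
    expect_equal(res$overlap, 5L)
    expect_equal(res$gene_ratio, 1)
})

test_that("ORA p-values agree with a without-replacement sampling oracle", {
    universe <- paste0("g", 1:40)
    members <- paste0("g", 1:8)          # M = 8, N = 40
    db <- GeneSetDB(list(s = members), universe = universe)
    drawn <- paste0("g", c(1:3, 20:26))  # k = 3 of n_drawn = 10
    res <- oraTest(drawn, db)
    set.seed(221)
    B <- 1e5
    hits <- replicate(B, {
        sum(sample(universe, 10) %in% members) >= 3
    })
    pMC <- mean(hits)
    se <- sqrt(pMC * (1 - pMC) / B)
    expect_lt(abs(res$p_value - pMC), 3 * se)
})

test_that("ORA input handling: universe restriction, empty draws, errors", {
    db <- GeneSetDB(list(s1 = paste0("g", 1:5)),
                    universe = paste0("g", 1:20))
    expect_warning(res <- oraTest(c("g1", "zzz"), db), "outside")
    expect_equal(res$list_size, 1L)
    expect_error(suppressWarnings(oraTest("zzz", db)), "empty gene list")
    tiny <- GeneSetDB(list(s1 = "g1"), universe = paste0("g", 1:5))
    expect_error(oraTest("g1", tiny), "at least 10")
})

test_that("ORA is calibrated on random gene lists", {
    ## sizes chosen so the discrete hypergeometric null is fine-grained:
    ## at N = 500, M = 50, n = 50 the exact exceedance
    ## P(p <= 0.05) = 0.0483
    set.seed(231)
    universe <- paste0("g", 1:500)
    sets <- lapply(1:20, function(i) sample(universe, 50))
    names(sets) <- paste0("s", 1:20)
    db <- GeneSetDB(sets, universe = universe)
    hits <- 0; total <- 0
    for (r in 1:2000) {
        genes <- sample(universe, 50)
        res <- oraTest(genes, db)
        hits <- hits + sum(res$p_value <= 0.05)
        total <- total + nrow(res)
    }
    expect_lt(abs(hits / total - 0.05), 0.02)
})

test_that("BH adjustment in the ORA table matches the step-up definition", {
    set.seed(241)
    universe <- paste0("g", 1:100)
    sets <- lapply(1:12, function(i) sample(universe, 10 + i))
    names(sets) <- paste0("s", 1:12)
    db <- GeneSetDB(sets, universe = universe)
    res <- oraTest(sample(universe, 20), db)
    expect_equal(res$q_value, bhStepUp(res$p_value), tolerance = 1e-12)
    ## q is monotone non-decreasing in p after sorting by p
    expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))
})

test_that("a planted gene set is top-ranked with small q", {
    set.seed(251)
    universe <- sprintf("g%03d", 1:300)
    planted <- sample(universe, 25)
    db <- genGeneSets(universe, nSets = 40, plantedGenes = planted,
                      seed = 5)
    res <- oraTest(planted, db)
    expect_identical(res$set_name[1L], "planted")
    expect_lt(res$q_value[1L], 0.05)
})

test_that("component gene lists and weight rankings follow their definitions", {
    cc1 <- new("CanonicalComponent", w1 = c(0, 0.3, 0, -0.2),
               w2 = c(0.5, 0.1), u = rnorm(8), v = rnorm(8),
               correlation = 0.9, nIter = 3L, converged = TRUE,
               corrTrace = c(0.8, 0.9))
    cc2 <- new("CanonicalComponent", w1 = c(0.5, 0.1, 0, 0),
               w2 = c(0.2, 0.6), u = rnorm(8), v = rnorm(8),
               correlation = 0.8, nIter = 3L, converged = TRUE,
               corrTrace = c(0.7, 0.8))
    res <- new("SCCAResult", components = list(cc1, cc2),
               config = SCCAConfig(nComponents = 2),
               sampleIds = sprintf("S%d", 1:8),
               featureIdsX = c("a", "b", "c", "d"),
               featureIdsY = c("ga", "gb"))
    gl <- componentGeneLists(res, "x")
    expect_equal(gl$CC1, c(b = 0.3, d = -0.2))
    expect_equal(gl$CC2, c(a = 0.5, b = 0.1))
    ## union across components contains each component's genes
    expect_true(all(names(gl$CC1) %in%
                    unique(unlist(lapply(gl, names)))))

    ## ranking by average absolute weight on view y:
    ## ga: mean(0.5, 0.2) = 0.35; gb: mean(0.1, 0.6) = 0.35 -> ID order
    rk <- rankGenesByAvgAbsWeight(res, "y")
    expect_identical(rk$gene_id, c("ga", "gb"))
    ## view x: a 0.25, b 0.2, c 0, d 0.1
    rkx <- rankGenesByAvgAbsWeight(res, "x")
    expect_identical(rkx$gene_id, c("a", "b", "d", "c"))
    ## invariant to global sign flips of a component
    cc2flip <- cc2
    cc2flip@w1 <- -cc2@w1; cc2flip@w2 <- -cc2@w2
    resFlip <- res
    resFlip@components <- list(cc1, cc2flip)
    expect_identical(rankGenesByAvgAbsWeight(resFlip, "x"), rkx)
})
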