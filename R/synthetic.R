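## Seeded generators for paired omics matrices with a shared sparse
## latent structure, cluster-dependent survival data, and gene-set
## databases with a planted enriched set. These define the study
## conditions under which every pipeline stage is validated.

#' Generate paired omics views with shared sparse latent structure
#'
#' Draws per-sample latent factors `Z` (n x K) with cluster-specific
#' means, sparse loading matrices `A` (p x K) and `B` (q x K) whose
#' non-zero entries are uniform on +/-[0.5, 1], and returns
#' `X = Z A' + E_x`, `Y = Z B' + E_y` with i.i.d. Gaussian noise.
#' Each cluster's mean is displaced by `clusterSeparation` within-cluster
#' standard deviations along its own latent axis (each subtype activates
#' its own latent program), so clusters on distinct axes sit at pairwise
#' mean distance `clusterSeparation * sqrt(2)`. Cluster sizes are
#' balanced exactly. Deterministic per seed.
#'
#' The default noise sd of 0.76 makes the signal fraction of a loaded
#' feature about one half (E[a^2] ~ 0.583 for |a| ~ U[0.5, 1] at unit
#' within-cluster latent variance).
#'
#' @param n samples (default 200).
#' @param p,q features in views X and Y (defaults 300, 400).
#' @param kLatent latent factors K (default 2).
#' @param nClusters planted clusters (default 3).
#' @param nNonzeroPerView non-zero loadings per factor per view
#'   (default 10).
#' @param clusterSeparation distance between cluster means in latent sd
#'   units (default 4).
#' @param noiseSd Gaussian noise sd (default 0.76).
#' @param seed integer seed.
#' @return list with `x`, `y` ([OmicsView-class]) and `truth`
#'   ([SynthTruth-class]).
#' @export
genPairedOmics <- function(n = 200L, p = 300L, q = 400L, kLatent = 2L,
                           nClusters = 3L, nNonzeroPerView = 10L,
                           clusterSeparation = 4, noiseSd = 0.76,
                           seed = 1L) {
    stopifnot(kLatent >= 1L, n >= nClusters, nClusters >= 1L)
    if (nNonzeroPerView > min(p, q))
        stop("infeasible sparsity: nNonzeroPerView exceeds min(p, q)")
    old <- .saveSeed(); on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))

    ## balanced cluster labels in a fixed random order
    labels <- sample(rep(seq_len(nClusters), length.out = n))
    ## each cluster displaced clusterSeparation sd along its own latent
    ## axis (cycling with growing, sign-alternating magnitude if
    ## nClusters > kLatent); distinct-axis pairs sit at mean distance
    ## clusterSeparation * sqrt(2)
    mu <- matrix(0, nClusters, kLatent)
    for (c in seq_len(nClusters)) {
        wrap <- (c - 1L) %/% kLatent
        mu[c, ((c - 1L) %% kLatent) + 1L] <-
            clusterSeparation * (1 + wrap) * (-1)^wrap
    }
    Z <- mu[labels, , drop = FALSE] +
        matrix(rnorm(n * kLatent), n, kLatent)

    drawLoadings <- function(nFeat) {
        L <- matrix(0, nFeat, kLatent)
        for (k in seq_len(kLatent)) {
            idx <- sample.int(nFeat, nNonzeroPerView)
            L[idx, k] <- sample(c(-1, 1), nNonzeroPerView, replace = TRUE) *
                runif(nNonzeroPerView, 0.5, 1)
        }
        L
    }
    A <- drawLoadings(p)
    B <- drawLoadings(q)
    X <- Z %*% t(A) + matrix(rnorm(n * p, sd = noiseSd), n, p)
    Y <- Z %*% t(B) + matrix(rnorm(n * q, sd = noiseSd), n, q)
    sids <- sprintf("S%04d", seq_len(n))
    dimnames(X) <- list(sids, sprintf("gene%04d", seq_len(p)))
    dimnames(Y) <- list(sids, sprintf("cpg%04d", seq_len(q)))
    rownames(A) <- colnames(X); rownames(B) <- colnames(Y)

    truth <- new("SynthTruth", latentFactors = Z, loadingsX = A,
                 loadingsY = B, trueLabels = as.integer(labels),
                 trueLogHazards = numeric(0),
                 enrichedSets = character(0), seed = as.integer(seed))
    list(x = OmicsView(X), y = OmicsView(Y), truth = truth)
}

#' Generate cluster-dependent survival data
#'
#' Event times are exponential with rate
#' `baselineRate * exp(logHazards[label])`; censoring times are
#' independent exponential with the rate tuned so the expected censored
#' fraction equals `censoringRate`. With `crossing = TRUE` the non-
#' reference log-hazards reverse sign at the median event time
#' (piecewise-exponential), deliberately violating proportional
#' hazards for power studies of the Schoenfeld test.
#'
#' @param trueLabels integer cluster per sample.
#' @param logHazards one log-hazard offset per cluster.
#' @param baselineRate baseline exponential event rate (default 0.1).
#' @param censoringRate expected censored fraction in [0, 1)
#'   (default 0.2).
#' @param seed integer seed.
#' @param crossing reverse group effects at the median time
#'   (default FALSE).
#' @return A [SurvivalTable-class] with sample identifiers
#'   `S0001, ...` matching [genPairedOmics()].
#' @export
genSubtypeSurvival <- function(trueLabels, logHazards, baselineRate = 0.1,
                               censoringRate = 0.2, seed = 1L,
                               crossing = FALSE) {
    trueLabels <- as.integer(trueLabels)
    nClusters <- max(trueLabels)
    if (length(logHazards) != nClusters)
        stop("one log-hazard per cluster is required")
    stopifnot(baselineRate > 0, censoringRate >= 0, censoringRate < 1)
    old <- .saveSeed(); on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))
    n <- length(trueLabels)
    rate <- baselineRate * exp(logHazards[trueLabels])

    if (!crossing) {
        eventTime <- rexp(n, rate = rate)
    } else {
        ## piecewise hazard: group offset flips sign at the crossing
        ## time t0 (median of the constant-hazard regime)
        t0 <- log(2) / (baselineRate * mean(exp(logHazards[trueLabels])))
        rate2 <- baselineRate * exp(-logHazards[trueLabels])
        e <- rexp(n)
        eventTime <- ifelse(e < rate * t0,
                            e / rate,
                            t0 + (e - rate * t0) / rate2)
    }

    if (censoringRate == 0) {
        censTime <- rep(Inf, n)
    } else {
        sizes <- tabulate(trueLabels, nClusters) / n
        ## P(C < T) averaged over groups = censoringRate (exponential C)
        f <- function(rc)
            sum(sizes * rc / (rc + baselineRate * exp(logHazards))) -
                censoringRate
        rc <- uniroot(f, c(1e-12, 1e6 * baselineRate))$root
        censTime <- rexp(n, rate = rc)
    }
    time <- pmin(eventTime, censTime)
    event <- as.integer(eventTime <= censTime)
    time <- pmax(time, 1e-8)    # strictly positive follow-up
    SurvivalTable(sprintf("S%04d", seq_len(n)), time, event)
}

#' Generate a gene-set database with one planted set
#'
#' `nSets` random sets (sizes uniform in `setSizeRange`) drawn from the
#' universe, plus one set named `"planted"` equal to `plantedGenes`.
#'
#' @param universe background gene universe.
#' @param nSets number of random sets (default 50).
#' @param setSizeRange length-2 integer range of random set sizes
#'   (default c(10, 30)).
#' @param plantedGenes genes of the planted (truly enriched) set; must
#'   lie inside the universe.
#' @param seed integer seed.
#' @return A [GeneSetDB-class]; the planted set is named `"planted"`.
#' @export
genGeneSets <- function(universe, nSets = 50L, setSizeRange = c(10L, 30L),
                        plantedGenes, seed = 1L) {
    universe <- as.character(universe)
    if (!all(plantedGenes %in% universe))
        stop("plantedGenes must be a subset of the universe")
    if (max(setSizeRange) > length(universe))
        stop("set size exceeds universe size")
    old <- .saveSeed(); on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))
    sets <- list(planted = unique(as.character(plantedGenes)))
    for (i in seq_len(nSets)) {
        sz <- sample(seq(setSizeRange[1L], setSizeRange[2L]), 1L)
        sets[[sprintf("random%03d", i)]] <- sample(universe, sz)
    }
    GeneSetDB(sets, universe = universe)
}

#' Simulate a complete synthetic study
#'
#' Bundles the generators into the named presets used throughout the
#' package: `"recovery"` (3 separated clusters, one latent factor per
#' cluster, true hazard ratios 1/2/4, planted gene set = the X-features
#' loaded on the latent factors), `"null"` (no cluster separation,
#' equal hazards) and
#' `"crossing"` (recovery structure with hazards crossing at the median
#' time).
#'
#' @param preset "recovery", "null" or "crossing".
#' @param seed integer seed.
#' @param n,p,q problem size (defaults 200, 300, 400).
#' @return list with `x`, `y`, `surv`, `db` and `truth`; `truth` carries
#'   the true labels, log-hazards and the planted set name.
#' @export
simulateStudy <- function(preset = c("recovery", "null", "crossing"),
                          seed = 1L, n = 200L, p = 300L, q = 400L) {
    preset <- match.arg(preset)
    sep <- if (preset == "null") 0 else 4
    logHaz <- if (preset == "null") c(0, 0, 0) else log(c(1, 2, 4))
    omics <- genPairedOmics(n = n, p = p, q = q, kLatent = 3L,
                            nClusters = 3L, nNonzeroPerView = 10L,
                            clusterSeparation = sep, seed = seed)
    surv <- genSubtypeSurvival(omics$truth@trueLabels, logHaz,
                               baselineRate = 0.1, censoringRate = 0.2,
                               seed = seed + 1000L,
                               crossing = preset == "crossing")
    planted <- rownames(omics$truth@loadingsX)[
        rowSums(abs(omics$truth@loadingsX)) > 0]
    db <- genGeneSets(featureNames(omics$x), nSets = 50L,
                      plantedGenes = planted, seed = seed + 2000L)
    truth <- omics$truth
    truth@trueLogHazards <- logHaz
    truth@enrichedSets <- "planted"
    list(x = omics$x, y = omics$y, surv = surv, db = db, truth = truth)
}
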