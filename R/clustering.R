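## K-means subtyping of the aggregated canonical scores, with the
## cluster-count diagnostics (elbow/WSS curve, silhouette, BSS/WSS).

## k-means++ seeding: first center uniform, subsequent centers with
## probability proportional to the squared distance to the nearest
## chosen center.
.kmeansPlusPlusCenters <- function(X, k) {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- X[idx, ]
    d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
    for (j in seq_len(k - 1L) + 1L) {
        if (all(d2 <= 0)) idx <- sample.int(n, 1L)
        else idx <- sample.int(n, 1L, prob = d2)
        centers[j, ] <- X[idx, ]
        d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
    }
    centers
}

## Canonical label order: decreasing cluster size, ties broken by the
## smallest sample index contained in the cluster.
.canonicalizeLabels <- function(labels, k) {
    size <- tabulate(labels, k)
    firstIdx <- vapply(seq_len(k), function(c) min(which(labels == c)), 0L)
    ord <- order(-size, firstIdx)
    relab <- integer(k)
    relab[ord] <- seq_len(k)
    relab[labels]
}

#' Cluster latent scores with k-means
#'
#' Runs k-means (k-means++ seeding, `nRestarts` independent starts,
#' Euclidean distance) on an n x m score matrix and keeps the solution
#' with minimal total within-cluster sum of squares. Labels are
#' canonicalised by decreasing cluster size (ties by smallest sample
#' index) so that repeated runs with one seed are identical.
#'
#' @param scores numeric n x m matrix (rows = samples); z-scored columns
#'   as produced by [aggregateScores()] are the intended input.
#' @param k number of clusters, 2 <= k < n.
#' @param seed integer RNG seed.
#' @param nRestarts independent k-means++ restarts (default 25).
#' @return A [SubtypeAssignment-class].
#' @export
kmeansCluster <- function(scores, k, seed = 1L, nRestarts = 25L) {
    scores <- as.matrix(scores)
    n <- nrow(scores)
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2")
    if (k >= n) stop("k must be smaller than the number of samples")
    if (!all(is.finite(scores))) stop("scores must be finite")
    sids <- rownames(scores)
    if (is.null(sids)) sids <- sprintf("sample%03d", seq_len(n))

    tss <- sum(sweep(scores, 2L, colMeans(scores), "-")^2)
    old <- .saveSeed()
    on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))

    best <- NULL
    for (r in seq_len(nRestarts)) {
        km <- NULL
        for (try in 1:10) {          # re-seed within the restart on failure
            centers <- .kmeansPlusPlusCenters(scores, k)
            km <- tryCatch(
                suppressWarnings(stats::kmeans(scores, centers = centers,
                                               iter.max = 100L)),
                error = function(e) NULL)
            if (!is.null(km) && length(unique(km$cluster)) == k) break
            km <- NULL
        }
        if (is.null(km)) next
        if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
            best <- km
    }
    if (is.null(best))
        stop("k-means failed to produce ", k, " non-empty clusters")

    labels <- .canonicalizeLabels(best$cluster, k)
    wss <- best$tot.withinss
    bss <- tss - wss
    sil <- if (tss <= 1e-12) NA_real_
           else mean(cluster::silhouette(labels, stats::dist(scores))[, 3L])
    new("SubtypeAssignment", sampleIds = sids, labels = as.integer(labels),
        k = k, wss = wss, bss = bss, silhouette = sil,
        seed = as.integer(seed), nRestarts = as.integer(nRestarts))
}

.saveSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Within-cluster sum-of-squares (elbow) curve
#'
#' WSS per candidate k, the quantity inspected on an elbow plot. The
#' curve is forced non-increasing in k: if sampling noise produces an
#' increase, that k is re-run with additional restarts.
#'
#' @param scores numeric n x m matrix.
#' @param kRange integer vector of candidate cluster counts.
#' @param seed integer RNG seed.
#' @param nRestarts restarts per k (default 25).
#' @return data.frame with columns `k` and `wss`, in `kRange` order.
#' @export
wssCurve <- function(scores, kRange, seed = 1L, nRestarts = 25L) {
    kRange <- as.integer(kRange)
    if (max(kRange) >= nrow(as.matrix(scores)))
        stop("max(kRange) must be smaller than the number of samples")
    wss <- vapply(kRange, function(k)
        kmeansCluster(scores, k, seed = seed, nRestarts = nRestarts)@wss,
        numeric(1))
    ord <- order(kRange)
    for (i in seq_along(ord)[-1L]) {     # enforce monotone non-increase
        ki <- ord[i]; kprev <- ord[i - 1L]
        tries <- 0L
        while (wss[ki] > wss[kprev] + 1e-9 && tries < 5L) {
            tries <- tries + 1L
            wss[ki] <- kmeansCluster(scores, kRange[ki],
                                     seed = seed + tries,
                                     nRestarts = 4L * nRestarts)@wss
        }
        wss[ki] <- min(wss[ki], wss[kprev])
    }
    data.frame(k = kRange, wss = wss)
}

#' Between/within sum-of-squares ratio
#'
#' @param assignment a [SubtypeAssignment-class] with wss > 0.
#' @return bss / wss, larger for better-separated clusters.
#' @export
bssWssRatio <- function(assignment) {
    stopifnot(is(assignment, "SubtypeAssignment"))
    if (assignment@wss <= 0)
        stop("degenerate perfect clustering: wss is zero")
    assignment@bss / assignment@wss
}

#' Choose the number of clusters
#'
#' Runs [kmeansCluster()] over `kRange` and returns the k maximising the
#' mean silhouette width (ties broken toward smaller k), alongside the
#' full diagnostics table (k, wss, silhouette, bss/wss) so the choice
#' can be overridden by inspection (elbow plot, prior subtype
#' knowledge).
#'
#' @param scores numeric n x m matrix.
#' @param kRange integer candidate cluster counts, within [2, n - 1].
#' @param seed integer RNG seed.
#' @param nRestarts restarts per k (default 25).
#' @return A list with `kBest` (integer) and `diagnostics` (data.frame
#'   with one row per k).
#' @export
selectK <- function(scores, kRange, seed = 1L, nRestarts = 25L) {
    kRange <- sort(as.integer(kRange))
    fits <- lapply(kRange, function(k)
        kmeansCluster(scores, k, seed = seed, nRestarts = nRestarts))
    diag <- data.frame(
        k = kRange,
        wss = vapply(fits, function(f) f@wss, numeric(1)),
        silhouette = vapply(fits, function(f) f@silhouette, numeric(1)),
        bss_wss = vapply(fits, function(f)
            if (f@wss > 0) f@bss / f@wss else Inf, numeric(1)))
    kBest <- kRange[which.max(diag$silhouette)]   # ties -> smaller k
    list(kBest = kBest, diagnostics = diag)
}

#' Plot the WSS elbow curve
#' @param curve data.frame from [wssCurve()].
#' @param ... passed to [graphics::plot()].
#' @return `curve`, invisibly.
#' @export
plotWSSCurve <- function(curve, ...) {
    graphics::plot(curve$k, curve$wss, type = "b", pch = 19,
                   xlab = "number of clusters k",
                   ylab = "within-cluster sum of squares", ...)
    invisible(curve)
}
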