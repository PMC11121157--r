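## Independent oracles used by the tests. These are deliberately naive
## re-derivations (hand formulas, enumeration, lattice search, Monte
## Carlo) kept free of any package internals.

## --- small fixtures -------------------------------------------------

## random standardized views with matching samples
makeViews <- function(n, p, q, seed = 1) {
    set.seed(seed)
    sids <- sprintf("S%03d", seq_len(n))
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sids, paste0("x", seq_len(p))))
    Y <- matrix(rnorm(n * q), n, q,
                dimnames = list(sids, paste0("y", seq_len(q))))
    list(x = standardizeColumns(OmicsView(X)),
         y = standardizeColumns(OmicsView(Y)))
}

writeTempMatrix <- function(df, ext = ".tsv", sep = "\t") {
    tf <- tempfile(fileext = ext)
    write.table(df, tf, sep = sep, quote = FALSE, row.names = FALSE)
    tf
}

## --- elastic net ----------------------------------------------------

## the elastic-net objective, restated independently
enetObjectiveOracle <- function(X, t, w, tau, ridge) {
    sum((t - X %*% w)^2) / (2 * (nrow(X) - 1)) +
        ridge * sum(w^2) + tau * sum(abs(w))
}

## coarse-to-fine lattice minimisation of the elastic-net objective
## over w in R^p (p small); vectorised evaluation over the lattice
latticeENet <- function(X, t, tau, ridge, lim = 2, steps = c(0.05, 0.005, 5e-4)) {
    p <- ncol(X)
    center <- rep(0, p)
    halfwidth <- lim
    for (st in steps) {
        grids <- lapply(seq_len(p), function(j)
            seq(center[j] - halfwidth, center[j] + halfwidth, by = st))
        W <- as.matrix(expand.grid(grids))
        R <- matrix(t, nrow(X), nrow(W)) - X %*% t(W)
        obj <- colSums(R^2) / (2 * (nrow(X) - 1)) +
            ridge * rowSums(W^2) + tau * rowSums(abs(W))
        center <- W[which.min(obj), ]
        halfwidth <- 1.5 * st
    }
    center
}

## --- survival -------------------------------------------------------

## hand product-limit estimator (no ties handling beyond grouping)
kmHand <- function(time, event) {
    ut <- sort(unique(time[event == 1]))
    surv <- numeric(length(ut))
    s <- 1
    for (i in seq_along(ut)) {
        nRisk <- sum(time >= ut[i])
        d <- sum(time == ut[i] & event == 1)
        s <- s * (1 - d / nRisk)
        surv[i] <- s
    }
    data.frame(time = ut, surv = surv)
}

## two-group log-rank chi-square from the O-E / hypergeometric-variance
## definition
logrankHand <- function(time, event, grp) {
    ut <- sort(unique(time[event == 1]))
    U <- 0; V <- 0
    for (t0 in ut) {
        atRisk <- time >= t0
        n <- sum(atRisk)
        n1 <- sum(atRisk & grp == 1)
        d <- sum(time == t0 & event == 1)
        d1 <- sum(time == t0 & event == 1 & grp == 1)
        U <- U + d1 - d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    U^2 / V
}

## Efron partial log-likelihood for a single binary covariate
## (indicator of group 2), evaluated at log-hazard beta
efronLogLik <- function(beta, time, event, x) {
    eta <- x * beta
    ll <- 0
    for (t0 in sort(unique(time[event == 1]))) {
        D <- which(time == t0 & event == 1)
        R <- which(time >= t0)
        d <- length(D)
        sumR <- sum(exp(eta[R]))
        sumD <- sum(exp(eta[D]))
        ll <- ll + sum(eta[D])
        for (l in seq_len(d) - 1)
            ll <- ll - log(sumR - (l / d) * sumD)
    }
    ll
}

## --- clustering -----------------------------------------------------

## exhaustive minimum within-cluster sum of squares over all k-label
## assignments of small 1-D data
enumerateMinWSS <- function(x, k) {
    n <- length(x)
    best <- Inf
    bestLab <- NULL
    labs <- rep(1L, n)
    repeat {
        if (length(unique(labs)) == k) {
            wss <- sum(unlist(lapply(split(x, labs),
                                     function(g) sum((g - mean(g))^2))))
            if (wss < best) {
                best <- wss
                bestLab <- labs
            }
        }
        j <- n
        while (j >= 1 && labs[j] == k) {
            labs[j] <- 1L
            j <- j - 1L
        }
        if (j == 0L) break
        labs[j] <- labs[j] + 1L
    }
    list(wss = best, labels = bestLab)
}

## --- multiple testing -----------------------------------------------

## Benjamini-Hochberg step-up, restated from the definition
bhStepUp <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- p[ord] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[ord] <- q
    out
}
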