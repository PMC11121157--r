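## Sparse canonical correlation analysis by alternating elastic-net
## regression, classical CCA (used as the zero-penalty reference),
## PLS-style deflation and score aggregation.

## Leading right singular vector of the cross-covariance X'Y/(n-1),
## computed by power iteration on the implicit operator so the p x q
## cross-covariance never needs to be formed for large views.
.leadingCrossCovSingular <- function(X, Y, seed, maxIter = 500L,
                                     tol = 1e-12) {
    n <- nrow(X); q <- ncol(Y)
    v <- rep(1 / sqrt(q), q)
    nrmPrev <- 0
    for (it in seq_len(maxIter)) {
        a <- crossprod(X, Y %*% v) / (n - 1)    # C v        (length p)
        b <- crossprod(Y, X %*% a) / (n - 1)    # C' C v     (length q)
        nrm <- sqrt(sum(b^2))
        if (!is.finite(nrm) || nrm < 1e-14) {
            ## degenerate start direction: seeded random restart
            set.seed(seed)
            v <- rnorm(q); v <- v / sqrt(sum(v^2))
            nrmPrev <- 0
            next
        }
        v <- drop(b) / nrm
        if (abs(nrm - nrmPrev) < tol * max(1, nrm)) break
        nrmPrev <- nrm
    }
    v
}

#' Fit sparse canonical correlation analysis
#'
#' Finds sparse weight vectors `w1`, `w2` maximising the correlation of
#' the canonical scores `u = X w1` and `v = Y w2` under unit-variance
#' constraints `Var(u) = Var(v) = 1`, with separate l1 (and optional l2)
#' penalties per data view. The solution alternates elastic-net
#' regressions: `w1` is regressed on the current `v`, rescaled to unit
#' score variance, then `w2` on the current `u`, until the canonical
#' correlation changes by less than `tol`. `w2` is initialised from the
#' leading right singular vector of the cross-covariance `X'Y/(n-1)`
#' (seeded random fallback for degenerate inputs). Subsequent components
#' are extracted after [deflate()]-ing both views on their own score
#' vectors. The sign of each component is fixed so that the
#' largest-magnitude entry of `w1` is positive.
#'
#' @param x,y sample-aligned, standardized [OmicsView-class] objects
#'   (see [standardizeColumns()]); n >= 4.
#' @param config an [SCCAConfig-class].
#' @return An [SCCAResult-class]. Weight vectors are aligned to the full
#'   feature lists of `x` and `y`; features removed by deflation carry
#'   zero weight in later components.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(80), 20, 4,
#'             dimnames = list(sprintf("S%02d", 1:20), paste0("f", 1:4)))
#' v <- OmicsView(m)
#' fit <- fitSCCA(v, v, SCCAConfig(nComponents = 1))
#' canonicalCorrelations(fit)  # 1: a view is perfectly correlated with itself
#' @export
fitSCCA <- function(x, y, config = SCCAConfig()) {
    validObject(config)
    stopifnot(is(x, "OmicsView"), is(y, "OmicsView"))
    if (!identical(sampleNames(x), sampleNames(y)))
        stop("x and y must be sample-aligned; see alignSamples()")
    n <- nrow(omicsValues(x))
    if (n < 4L)
        stop("fitSCCA requires at least 4 samples")
    K <- config@nComponents
    if (K > min(n - 1L, ncol(omicsValues(x)), ncol(omicsValues(y))))
        stop("nComponents exceeds min(n - 1, p, q)")
    idsX <- featureNames(x); idsY <- featureNames(y)
    Xd <- omicsValues(x); Yd <- omicsValues(y)
    components <- vector("list", K)
    for (k in seq_len(K)) {
        cc <- .fitOneComponent(Xd, Yd, config)
        w1full <- setNames(numeric(length(idsX)), idsX)
        w2full <- setNames(numeric(length(idsY)), idsY)
        w1full[colnames(Xd)] <- cc$w1
        w2full[colnames(Yd)] <- cc$w2
        components[[k]] <- new("CanonicalComponent",
                               w1 = unname(w1full), w2 = unname(w2full),
                               u = cc$u, v = cc$v,
                               correlation = cc$correlation,
                               nIter = cc$nIter, converged = cc$converged,
                               corrTrace = cc$corrTrace)
        if (!cc$converged)
            warning(sprintf("component %d did not converge in %d iterations",
                            k, config@maxIter))
        if (k < K) {
            Xd <- .deflateMatrix(Xd, cc$u)
            Yd <- .deflateMatrix(Yd, cc$v)
            if (ncol(Xd) == 0L || ncol(Yd) == 0L)
                stop("deflation exhausted a view before reaching ",
                     K, " components")
        }
    }
    new("SCCAResult", components = components, config = config,
        sampleIds = sampleNames(x), featureIdsX = idsX, featureIdsY = idsY)
}

## One canonical component on (already deflated) matrices.
.fitOneComponent <- function(X, Y, config) {
    n <- nrow(X)
    w2 <- .leadingCrossCovSingular(X, Y, config@seed)
    v <- drop(Y %*% w2)
    sdv <- sd(v)
    if (sdv < 1e-12) {
        set.seed(config@seed)
        w2 <- rnorm(ncol(Y)); v <- drop(Y %*% w2); sdv <- sd(v)
        if (sdv < 1e-12)
            stop("view 2 admits no direction with positive score variance")
    }
    w2 <- w2 / sdv; v <- v / sdv
    w1 <- NULL
    corrPrev <- -Inf
    corrTrace <- numeric(0)
    converged <- FALSE
    it <- 0L
    while (it < config@maxIter) {
        it <- it + 1L
        w1 <- penalizedRegressionStep(X, v, config@tau1, config@ridge1,
                                      w0 = w1)
        if (all(w1 == 0))
            stop("penalty too large for view 1: all weights soft-thresholded to zero")
        u <- drop(X %*% w1)
        sdu <- sd(u)
        w1 <- w1 / sdu; u <- u / sdu
        w2 <- penalizedRegressionStep(Y, u, config@tau2, config@ridge2,
                                      w0 = w2)
        if (all(w2 == 0))
            stop("penalty too large for view 2: all weights soft-thresholded to zero")
        v <- drop(Y %*% w2)
        sdv <- sd(v)
        w2 <- w2 / sdv; v <- v / sdv
        corr <- cor(u, v)
        corrTrace <- c(corrTrace, corr)
        if (is.finite(corrPrev) && abs(corr - corrPrev) < config@tol) {
            converged <- TRUE
            break
        }
        corrPrev <- corr
    }
    ## sign convention: largest-|w1| entry positive (flip both views)
    imax <- which.max(abs(w1))
    if (w1[imax] < 0) {
        w1 <- -w1; u <- -u
        w2 <- -w2; v <- -v
    }
    list(w1 = unname(w1), w2 = unname(w2), u = u, v = v,
         correlation = cor(u, v), nIter = it, converged = converged,
         corrTrace = corrTrace)
}

## Residualize every column on the (centered) score, drop columns that
## become constant, re-standardize. Internal matrix version of deflate().
.deflateMatrix <- function(M, score, dropTol = 1e-8) {
    s <- score - mean(score)
    ss <- sum(s^2)
    if (ss <= 0)
        stop("deflation score has zero variance")
    proj <- drop(crossprod(M, s)) / ss
    R <- M - outer(s, proj)
    R <- sweep(R, 2L, colMeans(R), "-")
    sdev <- apply(R, 2L, sd)
    keep <- sdev > dropTol
    R <- sweep(R[, keep, drop = FALSE], 2L, sdev[keep], "/")
    R
}

#' Deflate a view on a score vector
#'
#' Replaces every column by its residual after least-squares projection
#' onto the (centered) score, then re-standardizes. Columns that become
#' (numerically) constant — e.g. columns exactly proportional to the
#' score — are dropped. The resulting columns are orthogonal to the
#' centered score.
#'
#' @param view an [OmicsView-class].
#' @param score numeric score vector of length n with positive variance.
#' @return The deflated [OmicsView-class].
#' @export
deflate <- function(view, score) {
    M <- omicsValues(view)
    stopifnot(length(score) == nrow(M))
    OmicsView(.deflateMatrix(M, score))
}

#' Classical canonical correlation analysis
#'
#' Standard CCA from the generalized eigenproblem on the covariance
#' blocks (Sxx, Sxy, Syy), applicable only when both views have fewer
#' features than samples and non-singular covariance. Serves as the
#' exact zero-penalty reference for [fitSCCA()].
#'
#' @param x,y sample-aligned [OmicsView-class] objects with p < n and
#'   q < n.
#' @param k number of canonical pairs to return.
#' @return A list with `correlations` (length k), and weight matrices
#'   `w1` (p x k), `w2` (q x k) scaled so each canonical score has unit
#'   sample variance.
#' @export
classicalCCA <- function(x, y, k = 1L) {
    stopifnot(is(x, "OmicsView"), is(y, "OmicsView"))
    X <- omicsValues(x); Y <- omicsValues(y)
    n <- nrow(X)
    if (ncol(X) >= n || ncol(Y) >= n)
        stop("classical CCA requires p < n and q < n; use fitSCCA with penalties")
    k <- as.integer(k)
    stopifnot(k >= 1L, k <= min(ncol(X), ncol(Y)))
    Sxx <- cov(X); Syy <- cov(Y); Sxy <- cov(X, Y)
    isqrt <- function(S, label) {
        e <- eigen(S, symmetric = TRUE)
        if (min(e$values) < 1e-10 * max(e$values))
            stop("singular covariance in view ", label,
                 "; remove collinear features or use fitSCCA with ridge > 0")
        e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
            t(e$vectors)
    }
    Ax <- isqrt(Sxx, "x"); Ay <- isqrt(Syy, "y")
    M <- Ax %*% Sxy %*% Ay
    sv <- svd(M, nu = k, nv = k)
    w1 <- Ax %*% sv$u
    w2 <- Ay %*% sv$v
    rownames(w1) <- colnames(X); rownames(w2) <- colnames(Y)
    list(correlations = pmin(sv$d[seq_len(k)], 1), w1 = w1, w2 = w2)
}

#' Aggregate canonical scores into a clustering input matrix
#'
#' Combines the per-component canonical scores into one n x m matrix and
#' z-scores every column (mean 0, sd 1), the scaling applied before
#' k-means clustering.
#'
#' @param result an [SCCAResult-class].
#' @param mode `"both_views"` concatenates (u_k, v_k) for all components
#'   (m = 2K, default); `"x_only"` uses the X-view scores u_k (m = K);
#'   `"mean_of_views"` uses (u_k + v_k)/2 (m = K).
#' @return n x m numeric matrix with sample-ID rownames (when the fit
#'   carries them) and z-scored columns.
#' @export
aggregateScores <- function(result,
                            mode = c("both_views", "x_only",
                                     "mean_of_views")) {
    mode <- match.arg(mode)
    stopifnot(is(result, "SCCAResult"))
    K <- length(result@components)
    U <- vapply(result@components, function(cc) cc@u,
                numeric(length(result@components[[1]]@u)))
    V <- vapply(result@components, function(cc) cc@v,
                numeric(length(result@components[[1]]@v)))
    U <- matrix(U, ncol = K); V <- matrix(V, ncol = K)
    S <- switch(mode,
                both_views = {
                    M <- matrix(NA_real_, nrow(U), 2L * K)
                    M[, seq(1L, 2L * K, by = 2L)] <- U
                    M[, seq(2L, 2L * K, by = 2L)] <- V
                    colnames(M) <- as.vector(rbind(paste0("CC", 1:K, "_x"),
                                                   paste0("CC", 1:K, "_y")))
                    M
                },
                x_only = {
                    colnames(U) <- paste0("CC", 1:K)
                    U
                },
                mean_of_views = {
                    M <- (U + V) / 2
                    colnames(M) <- paste0("CC", 1:K)
                    M
                })
    rownames(S) <- result@sampleIds
    sdev <- apply(S, 2L, sd)
    if (any(sdev < 1e-12))
        stop("zero-variance score column(s): ",
             paste(colnames(S)[sdev < 1e-12], collapse = ", "))
    scale(S)[, , drop = FALSE]
}
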