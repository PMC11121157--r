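#' One penalized (elastic-net) regression step
#'
#' Solves the elastic-net problem at the heart of the alternating sCCA
#' scheme,
#' \deqn{\hat w = \arg\min_w \frac{\|t - Xw\|_2^2}{2(n-1)}
#'   + \mathrm{ridge}\,\|w\|_2^2 + \tau\,\|w\|_1,}
#' by cyclical coordinate descent with soft-thresholding. With `tau = 0`
#' the exact closed-form ridge (or ordinary least-squares) solution is
#' returned instead, since the objective is then smooth and the solve is
#' exact. Columns of `design` must be standardized (mean 0, unit sd with
#' denominator n - 1), so that for a single standardized column the
#' solution has the closed form
#' `sign(c) * max(|c| - tau, 0) / (1 + 2 ridge)` with
#' `c = cor(x, t) * sd(t)`.
#'
#' A weight vector of all zeros is a legitimate return (when `tau`
#' exceeds every absolute column-target covariance), not an error;
#' callers that require a non-trivial direction must detect it.
#'
#' @param design standardized n x p design matrix.
#' @param target numeric response of length n with positive variance.
#' @param tau non-negative l1 penalty.
#' @param ridge non-negative l2 penalty.
#' @param w0 optional warm-start weights (default zeros).
#' @param maxSweeps maximum coordinate-descent sweeps (default 1000).
#' @param tol convergence tolerance on the relative coordinate change
#'   (default 1e-9).
#' @return Weight vector of length p. Attribute `"objective"` holds the
#'   objective value after every coordinate-descent sweep (monotone
#'   non-increasing); for the `tau = 0` closed-form path it has length 1.
#' @export
penalizedRegressionStep <- function(design, target, tau, ridge = 0,
                                    w0 = NULL, maxSweeps = 1000L,
                                    tol = 1e-9) {
    design <- as.matrix(design)
    n <- nrow(design); p <- ncol(design)
    if (!all(is.finite(design)) || !all(is.finite(target)))
        stop("non-finite values in design or target")
    if (length(target) != n)
        stop("target length must match the number of design rows")
    if (var(target) <= 0)
        stop("target has zero variance")
    if (tau < 0 || ridge < 0)
        stop("penalties must be non-negative")
    if (is.null(w0)) w0 <- numeric(p)

    if (tau == 0) {
        ## smooth objective: exact solve of (X'X/(n-1) + 2 ridge I) w = X't/(n-1)
        G <- crossprod(design) / (n - 1)
        diag(G) <- diag(G) + 2 * ridge
        b <- crossprod(design, target) / (n - 1)
        w <- tryCatch(drop(solve(G, b)),
                      error = function(e)
                          drop(solve(G + diag(1e-10, p), b)))
        r <- target - design %*% w
        attr(w, "objective") <- drop(crossprod(r)) / (2 * (n - 1)) +
            ridge * sum(w^2)
        return(w)
    }
    w <- .enetCD(design, as.numeric(target), tau, ridge, as.numeric(w0),
                 as.integer(maxSweeps), tol)
    names(w) <- colnames(design)
    w
}

## Elastic-net objective used throughout this package (and by the test
## oracles): ||t - Xw||^2 / (2(n-1)) + ridge ||w||^2 + tau ||w||_1.
enetObjective <- function(design, target, w, tau, ridge) {
    r <- target - design %*% w
    drop(crossprod(r)) / (2 * (nrow(design) - 1)) +
        ridge * sum(w^2) + tau * sum(abs(w))
}
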