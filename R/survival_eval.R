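## Survival-based evaluation of subtype assignments: Kaplan-Meier
## curves, K-sample log-rank test, grouped Cox proportional-hazards fit
## with pairwise hazard ratios, HRmin, the SEP separation statistic and
## the global Schoenfeld test of proportional hazards. The estimators
## themselves come from the survival package; the separation statistics
## and the size-weighted coefficient centering are computed here.

#' @importFrom survival Surv survfit survdiff coxph cox.zph
NULL

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (1 = event observed).
#' @return A [KMCurve-class]: one row per distinct event time with the
#'   survival estimate, risk-set size, event count and Greenwood
#'   standard error. Censored observations shrink the risk set but do
#'   not produce steps.
#' @examples
#' kmCurve(time = 1:6, event = c(1, 0, 1, 1, 0, 1))
#' @export
kmCurve <- function(time, event) {
    if (length(time) == 0L)
        stop("empty survival input")
    stopifnot(length(time) == length(event), all(time > 0),
              all(event %in% c(0, 1)))
    sf <- survfit(Surv(time, event) ~ 1, conf.type = "log")
    sm <- summary(sf, censored = FALSE)
    hasEvent <- sm$n.event > 0
    new("KMCurve",
        eventTimes = as.numeric(sm$time[hasEvent]),
        survival = as.numeric(sm$surv[hasEvent]),
        atRisk = as.integer(sm$n.risk[hasEvent]),
        nEvents = as.integer(sm$n.event[hasEvent]),
        greenwoodSE = as.numeric(sm$std.err[hasEvent]))
}

#' Tabulate a KMCurve
#' @param curve a [KMCurve-class].
#' @return data.frame with columns time, survival, at_risk, n_events, se.
#' @export
kmCurveTable <- function(curve) {
    data.frame(time = curve@eventTimes, survival = curve@survival,
               at_risk = curve@atRisk, n_events = curve@nEvents,
               se = curve@greenwoodSE)
}

#' K-sample log-rank test
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param labels group (subtype) label per subject; at least two groups.
#' @return list with `chi2`, `df` (= number of groups - 1) and `p`.
#' @export
logrankTest <- function(time, event, labels) {
    labels <- as.factor(labels)
    if (nlevels(labels) < 2L)
        stop("log-rank test requires at least two groups")
    stopifnot(length(time) == length(event),
              length(labels) == length(time))
    sd <- survdiff(Surv(time, event) ~ labels)
    df <- nlevels(labels) - 1L
    list(chi2 = as.numeric(sd$chisq), df = df,
         p = pchisq(as.numeric(sd$chisq), df, lower.tail = FALSE))
}

#' Grouped Cox proportional-hazards fit with separation statistics
#'
#' Fits a Cox proportional-hazards model with the subtype label as the
#' only covariate (reference-coded indicators), converts the estimates
#' to per-group log-hazard coefficients and centers them by the
#' size-weighted mean so that `sum(ni * beta_i) = 0` (pairwise
#' differences are unchanged by this reparameterisation). From the
#' centered coefficients it derives the pairwise hazard-ratio matrix,
#' HRmin, and the SEP statistic in both conventions, and attaches the
#' K-sample log-rank test and the global Schoenfeld test (GST) of
#' proportional hazards.
#'
#' Monotone partial likelihoods (a group whose events all precede every
#' other group's) yield numerically diverging coefficients; these are
#' capped at |beta| <= 15 with a warning.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator; at least one event overall.
#' @param labels subtype label per subject; every group non-empty.
#' @param ties tie handling in the partial likelihood: "efron" (default)
#'   or "breslow".
#' @param gstTransform event-time transform for the Schoenfeld test:
#'   "rank" (default) or "identity".
#' @return A [CoxGroupFit-class].
#' @seealso [hrMin()], [sepStatistic()], [schoenfeldGST()]
#' @export
coxFitSubtypes <- function(time, event, labels,
                           ties = c("efron", "breslow"),
                           gstTransform = c("rank", "identity")) {
    ties <- match.arg(ties)
    gstTransform <- match.arg(gstTransform)
    labels <- as.factor(labels)
    stopifnot(length(time) == length(event),
              length(labels) == length(time), all(time > 0))
    if (nlevels(labels) < 2L)
        stop("at least two subtype groups are required")
    if (any(table(labels) == 0L))
        stop("every subtype group must be non-empty")
    if (sum(event) < 1L)
        stop("no events observed; Cox model cannot be fitted")

    df <- data.frame(time = time, event = event, grp = labels)
    fit <- withCallingHandlers(
        coxph(Surv(time, event) ~ grp, data = df, ties = ties),
        warning = function(w) {
            if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    rawCoef <- fit$coefficients
    if (any(!is.finite(rawCoef)) || any(abs(rawCoef) > 15)) {
        warning("monotone partial likelihood: coefficient(s) capped at |beta| = 15")
        rawCoef[is.nan(rawCoef)] <- 0
        rawCoef[is.infinite(rawCoef)] <- sign(rawCoef[is.infinite(rawCoef)]) * 15
        rawCoef <- pmin(pmax(rawCoef, -15), 15)
    }
    sizes <- as.integer(table(labels))
    names(sizes) <- levels(labels)
    n <- sum(sizes)
    betaRaw <- c(0, rawCoef)                       # reference group first
    beta <- betaRaw - sum(sizes * betaRaw) / n     # size-weighted centering
    names(beta) <- levels(labels)

    hrMat <- exp(outer(beta, beta, "-"))
    dimnames(hrMat) <- list(levels(labels), levels(labels))
    dAbs <- abs(outer(beta, beta, "-"))
    hrmin <- exp(min(dAbs[upper.tri(dAbs)]))
    sepP <- exp(-sum((sizes / n) * abs(beta)))
    lr <- logrankTest(time, event, labels)
    gst <- tryCatch(
        schoenfeldGST(time = time, event = event, labels = labels,
                      ties = ties, timeTransform = gstTransform),
        error = function(e) {
            warning("global Schoenfeld test unavailable: ",
                    conditionMessage(e))
            list(chi2 = NA_real_, df = nlevels(labels) - 1L, p = NA_real_)
        })

    new("CoxGroupFit", groupSizes = sizes, beta = unname(beta),
        covBeta = fit$var, loglik = fit$loglik[2L],
        hrMatrix = hrMat, hrMin = hrmin,
        sepPrinted = sepP, sepReciprocal = 1 / sepP,
        logrankStat = lr$chi2, logrankP = lr$p,
        gstStat = gst$chi2, gstP = gst$p, ties = ties, coxph = fit)
}

#' Global Schoenfeld test of proportional hazards
#'
#' Computes scaled Schoenfeld residuals at each event time
#' (Grambsch-Therneau scaling by the inverse average information),
#' regresses them on the transformed event times, and returns the global
#' chi-square statistic with `df = C - 1`. A small statistic (p above
#' the significance level) supports retaining the proportional-hazards
#' assumption; callers compare `p` to 0.05.
#'
#' @param fit optional [CoxGroupFit-class]; when supplied its tie
#'   handling is reused and `time`/`event`/`labels` describe the same
#'   data.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator; more events than `C - 1` required.
#' @param labels subtype label per subject.
#' @param timeTransform "rank" (default) or "identity".
#' @param ties tie handling when `fit` is not supplied.
#' @return list with `chi2`, `df` and `p` for the global test.
#' @export
schoenfeldGST <- function(fit = NULL, time, event, labels,
                          timeTransform = c("rank", "identity"),
                          ties = c("efron", "breslow")) {
    timeTransform <- match.arg(timeTransform)
    ties <- if (!is.null(fit)) fit@ties else match.arg(ties)
    labels <- as.factor(labels)
    dfree <- nlevels(labels) - 1L
    if (sum(event) <= dfree)
        stop("fewer events (", sum(event), ") than degrees of freedom (",
             dfree, ") for the Schoenfeld test")
    dat <- data.frame(time = time, event = event, grp = labels)
    cox <- withCallingHandlers(
        coxph(Surv(time, event) ~ grp, data = dat, ties = ties),
        warning = function(w) {
            if (grepl("infinite|did not converge|beta may be",
                      conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    zph <- cox.zph(cox, transform = timeTransform, global = TRUE)
    glob <- zph$table["GLOBAL", , drop = TRUE]
    list(chi2 = as.numeric(glob[["chisq"]]),
         df = as.integer(glob[["df"]]),
         p = as.numeric(glob[["p"]]))
}

#' Kaplan-Meier plot per subtype
#'
#' Step curves per subtype with shaded pointwise confidence bands and a
#' log-rank p-value annotation.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param labels subtype label per subject.
#' @param col colours, one per subtype.
#' @param main plot title.
#' @return the [survival::survfit()] object, invisibly.
#' @export
plotKM <- function(time, event, labels, col = NULL, main = "") {
    labels <- as.factor(labels)
    sf <- survfit(Surv(time, event) ~ labels)
    k <- nlevels(labels)
    if (is.null(col))
        col <- grDevices::hcl.colors(max(k, 2L), "Dark 3")[seq_len(k)]
    graphics::plot(sf, col = col, lwd = 2, conf.int = TRUE,
                   xlab = "time", ylab = "survival probability",
                   main = main)
    lr <- logrankTest(time, event, labels)
    graphics::legend("topright",
                     legend = c(paste("subtype", levels(labels)),
                                sprintf("log-rank p = %.3g", lr$p)),
                     col = c(col, NA), lwd = c(rep(2, k), NA), bty = "n")
    invisible(sf)
}
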