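#' @describeIn OmicsView sample identifiers (row names).
#' @param object an `OmicsView`.
#' @export
setMethod("sampleNames", "OmicsView", function(object) rownames(object@values))

#' @describeIn OmicsView feature identifiers (column names).
#' @export
setMethod("featureNames", "OmicsView", function(object) colnames(object@values))

#' @describeIn OmicsView the samples x features numeric matrix.
#' @export
setMethod("omicsValues", "OmicsView", function(object) object@values)

#' @describeIn OmicsView number of samples.
#' @param x an `OmicsView`.
#' @export
setMethod("nrow", "OmicsView", function(x) nrow(x@values))

#' @describeIn OmicsView number of features.
#' @export
setMethod("ncol", "OmicsView", function(x) ncol(x@values))

setMethod("show", "OmicsView", function(object) {
    v <- object@values
    cat(sprintf("OmicsView: %d samples x %d features\n", nrow(v), ncol(v)))
    nm <- sum(is.na(v))
    if (nm > 0)
        cat(sprintf("  missing entries: %d (%.2f%%)\n", nm,
                    100 * nm / length(v)))
    cat("  samples: ", paste(head(rownames(v), 4L), collapse = ", "),
        if (nrow(v) > 4L) ", ..." else "", "\n", sep = "")
    cat("  features: ", paste(head(colnames(v), 4L), collapse = ", "),
        if (ncol(v) > 4L) ", ..." else "", "\n", sep = "")
})

#' @describeIn SurvivalTable sample identifiers.
#' @param object a `SurvivalTable`.
#' @export
setMethod("sampleNames", "SurvivalTable", function(object) object@sampleIds)

#' Follow-up times of a SurvivalTable
#' @param table a [SurvivalTable-class].
#' @return numeric vector of follow-up times.
#' @export
survivalTime <- function(table) table@time

#' Event indicators of a SurvivalTable
#' @param table a [SurvivalTable-class].
#' @return integer 0/1 event indicators.
#' @export
survivalEvent <- function(table) table@event

setMethod("show", "SurvivalTable", function(object) {
    cat(sprintf("SurvivalTable: %d subjects, %d events (%.1f%%)\n",
                length(object@sampleIds), sum(object@event),
                100 * mean(object@event)))
})

#' Gene sets of a GeneSetDB
#' @param db a [GeneSetDB-class].
#' @return named list of character vectors.
#' @export
geneSets <- function(db) db@sets

#' Background universe of a GeneSetDB
#' @param db a [GeneSetDB-class].
#' @return character vector of universe gene identifiers.
#' @export
geneUniverse <- function(db) db@universe

setMethod("show", "GeneSetDB", function(object) {
    sz <- lengths(object@sets)
    cat(sprintf("GeneSetDB: %d sets (sizes %d-%d), universe of %d genes\n",
                length(object@sets), min(sz), max(sz),
                length(object@universe)))
})

setMethod("show", "SCCAConfig", function(object) {
    cat(sprintf(paste0("SCCAConfig: K=%d, tau=(%.4g, %.4g), ",
                       "ridge=(%.4g, %.4g), maxIter=%d, tol=%.1e\n"),
                object@nComponents, object@tau1, object@tau2,
                object@ridge1, object@ridge2, object@maxIter, object@tol))
})

#' Canonical correlations of a fitted sCCA
#' @param result an [SCCAResult-class].
#' @return numeric vector of per-component canonical correlations.
#' @export
canonicalCorrelations <- function(result)
    vapply(result@components, function(cc) cc@correlation, numeric(1))

#' Canonical weight matrix of one view
#' @param result an [SCCAResult-class].
#' @param view "x" or "y".
#' @return features x components weight matrix with feature-ID rownames.
#' @export
canonicalWeights <- function(result, view = c("x", "y")) {
    view <- match.arg(view)
    ids <- if (view == "x") result@featureIdsX else result@featureIdsY
    w <- vapply(result@components,
                function(cc) if (view == "x") cc@w1 else cc@w2,
                numeric(length(ids)))
    w <- matrix(w, nrow = length(ids),
                dimnames = list(ids, paste0("CC", seq_along(result@components))))
    w
}

setMethod("show", "SCCAResult", function(object) {
    cors <- canonicalCorrelations(object)
    nz1 <- vapply(object@components, function(cc) sum(cc@w1 != 0), 0L)
    nz2 <- vapply(object@components, function(cc) sum(cc@w2 != 0), 0L)
    cat(sprintf("SCCAResult: %d component(s), n=%d samples\n",
                length(object@components), length(object@components[[1]]@u)))
    for (k in seq_along(cors))
        cat(sprintf("  CC%d: correlation %.4f, support |w1|=%d/%d, |w2|=%d/%d%s\n",
                    k, cors[k], nz1[k], length(object@featureIdsX),
                    nz2[k], length(object@featureIdsY),
                    if (object@components[[k]]@converged) ""
                    else " (not converged)"))
})

#' @describeIn SubtypeAssignment per-sample cluster labels, named by
#'   sample identifier.
#' @param object a `SubtypeAssignment`.
#' @export
setMethod("clusterLabels", "SubtypeAssignment",
          function(object) setNames(object@labels, object@sampleIds))

#' @describeIn SubtypeAssignment sample identifiers.
#' @export
setMethod("sampleNames", "SubtypeAssignment",
          function(object) object@sampleIds)

setMethod("show", "SubtypeAssignment", function(object) {
    cat(sprintf("SubtypeAssignment: %d samples in k=%d clusters (sizes %s)\n",
                length(object@labels), object@k,
                paste(tabulate(object@labels, object@k), collapse = "/")))
    cat(sprintf("  wss=%.4g, bss=%.4g, mean silhouette=%.3f\n",
                object@wss, object@bss, object@silhouette))
})

setMethod("show", "KMCurve", function(object) {
    cat(sprintf("KMCurve: %d event times, final S(t)=%.4f\n",
                length(object@eventTimes),
                if (length(object@survival)) tail2(object@survival) else 1))
})

tail2 <- function(x) x[length(x)]

#' @describeIn CoxGroupFit HRmin of the fit.
#' @param object a `CoxGroupFit`.
#' @export
setMethod("hrMin", "CoxGroupFit", function(object) object@hrMin)

#' @describeIn hrMin compute HRmin directly from per-group log-hazard
#'   coefficients.
#' @export
setMethod("hrMin", "numeric", function(object) {
    stopifnot(length(object) >= 2L)
    d <- abs(outer(object, object, "-"))
    exp(min(d[upper.tri(d)]))
})

#' @describeIn CoxGroupFit SEP statistic of the fit under either
#'   convention.
#' @param convention "reciprocal" (default) or "printed".
#' @export
setMethod("sepStatistic", "CoxGroupFit", function(object, convention) {
    convention <- match.arg(convention, c("reciprocal", "printed"))
    if (convention == "printed") object@sepPrinted else object@sepReciprocal
})

setMethod("show", "CoxGroupFit", function(object) {
    cat(sprintf("CoxGroupFit (%s ties): %d groups (sizes %s)\n",
                object@ties, length(object@beta),
                paste(object@groupSizes, collapse = "/")))
    cat(sprintf("  centered beta: %s\n",
                paste(sprintf("%.4f", object@beta), collapse = ", ")))
    cat(sprintf("  HRmin=%.4f, SEP(reciprocal)=%.4f, SEP(printed)=%.4f\n",
                object@hrMin, object@sepReciprocal, object@sepPrinted))
    cat(sprintf("  log-rank: chi2=%.3f, p=%.3g; GST: chi2=%.3f, p=%.3g\n",
                object@logrankStat, object@logrankP,
                object@gstStat, object@gstP))
})

setMethod("show", "SynthTruth", function(object) {
    cat(sprintf(paste0("SynthTruth: n=%d, K=%d latent factor(s), ",
                       "%d clusters, seed=%d\n"),
                nrow(object@latentFactors), ncol(object@latentFactors),
                length(unique(object@trueLabels)), object@seed))
})
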