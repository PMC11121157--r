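#' @import methods
#' @importFrom stats sd cor var cov pchisq phyper p.adjust rnorm rexp runif
#'   setNames uniroot
#' @importFrom utils read.delim write.table head packageVersion
#' @useDynLib sCClust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' OmicsView: one omics data matrix with sample and feature identifiers
#'
#' A thin S4 container for a single omics data view (e.g. gene expression
#' levels or DNA-methylation beta/M-values), stored samples x features.
#' Sample and feature identifiers are kept as the matrix dimnames and must
#' be unique and non-missing.
#'
#' @slot values numeric matrix, n samples x p features, with complete
#'   dimnames. Missing entries are allowed (NA) until
#'   [filterMissingFeatures()] has been applied.
#'
#' @seealso [readOmicsMatrix()], [standardizeColumns()], [alignSamples()]
#' @export
setClass("OmicsView", representation(values = "matrix"))

setValidity("OmicsView", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    dn <- dimnames(v)
    if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
        return("'values' must carry sample (row) and feature (column) names")
    sid <- dn[[1L]]; fid <- dn[[2L]]
    if (anyNA(sid) || any(sid == ""))
        return("sample identifiers must be non-missing and non-empty")
    if (anyNA(fid) || any(fid == ""))
        return("feature identifiers must be non-missing and non-empty")
    if (anyDuplicated(sid))
        return(sprintf("duplicate sample identifiers: %s",
                       paste(unique(sid[duplicated(sid)]), collapse = ", ")))
    if (anyDuplicated(fid))
        return(sprintf("duplicate feature identifiers: %s",
                       paste(unique(fid[duplicated(fid)]), collapse = ", ")))
    TRUE
})

#' Construct an OmicsView
#'
#' @param values numeric matrix, samples in rows, features in columns;
#'   must have complete, unique dimnames.
#' @return An [OmicsView-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("S1", "S2", "S3"), c("g1", "g2")))
#' OmicsView(m)
#' @export
OmicsView <- function(values) {
    storage.mode(values) <- "double"
    new("OmicsView", values = values)
}

#' SurvivalTable: right-censored survival data
#'
#' @slot sampleIds character, unique sample identifiers.
#' @slot time numeric, positive follow-up times (one unit throughout).
#' @slot event integer, 1 = event (death) observed, 0 = right-censored.
#' @export
setClass("SurvivalTable",
         representation(sampleIds = "character", time = "numeric",
                        event = "integer"))

setValidity("SurvivalTable", function(object) {
    n <- length(object@sampleIds)
    if (length(object@time) != n || length(object@event) != n)
        return("sampleIds, time and event must have equal length")
    if (anyDuplicated(object@sampleIds))
        return("duplicate sample identifiers in survival table")
    if (anyNA(object@time) || any(object@time <= 0))
        return("all survival times must be positive")
    if (anyNA(object@event) || !all(object@event %in% c(0L, 1L)))
        return("event must be 0 (censored) or 1 (event)")
    TRUE
})

#' Construct a SurvivalTable
#'
#' @param sampleIds character vector of unique sample identifiers.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (1 = event observed).
#' @return A [SurvivalTable-class] object.
#' @export
SurvivalTable <- function(sampleIds, time, event) {
    new("SurvivalTable", sampleIds = as.character(sampleIds),
        time = as.numeric(time), event = as.integer(event))
}

#' GeneSetDB: named gene sets over a background universe
#'
#' @slot sets named list of character vectors (gene identifiers); every
#'   set is non-empty and deduplicated.
#' @slot universe character, the background gene universe.
#' @export
setClass("GeneSetDB",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetDB", function(object) {
    if (length(object@sets) == 0L)
        return("no gene sets")
    if (is.null(names(object@sets)) || any(names(object@sets) == ""))
        return("every gene set must be named")
    if (anyDuplicated(names(object@sets)))
        return("duplicate gene-set names")
    for (nm in names(object@sets)) {
        s <- object@sets[[nm]]
        if (length(s) == 0L)
            return(sprintf("gene set '%s' is empty", nm))
        if (anyDuplicated(s))
            return(sprintf("gene set '%s' contains duplicates", nm))
    }
    if (anyDuplicated(object@universe))
        return("universe contains duplicates")
    TRUE
})

#' Construct a GeneSetDB
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param universe background universe; defaults to the union of all sets.
#' @return A [GeneSetDB-class] object.
#' @export
GeneSetDB <- function(sets, universe = NULL) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (is.null(universe))
        universe <- sort(unique(unlist(sets, use.names = FALSE)))
    new("GeneSetDB", sets = sets, universe = as.character(universe))
}

#' SCCAConfig: sparse-CCA fitting parameters
#'
#' Penalties are per data view: `tau1`/`ridge1` apply to the first view
#' (X, e.g. expression), `tau2`/`ridge2` to the second (Y, e.g.
#' methylation). `tau` is the l1 (lasso) penalty controlling sparsity of
#' the canonical weights; `ridge` is the l2 (elastic-net) term
#' stabilising correlated features.
#'
#' @slot tau1,tau2 non-negative l1 penalties for views X and Y.
#' @slot ridge1,ridge2 non-negative l2 penalties.
#' @slot nComponents number of canonical components K.
#' @slot maxIter maximum alternating iterations per component.
#' @slot tol convergence threshold on the change in canonical correlation.
#' @slot seed integer seed for the (rarely used) random initialisation
#'   fallback.
#' @export
setClass("SCCAConfig",
         representation(tau1 = "numeric", tau2 = "numeric",
                        ridge1 = "numeric", ridge2 = "numeric",
                        nComponents = "integer", maxIter = "integer",
                        tol = "numeric", seed = "integer"))

setValidity("SCCAConfig", function(object) {
    if (object@tau1 < 0 || object@tau2 < 0)
        return("tau1 and tau2 must be non-negative")
    if (object@ridge1 < 0 || object@ridge2 < 0)
        return("ridge1 and ridge2 must be non-negative")
    if (object@nComponents < 1L)
        return("nComponents must be a positive integer")
    if (object@maxIter < 1L)
        return("maxIter must be a positive integer")
    if (object@tol <= 0)
        return("tol must be positive")
    TRUE
})

#' Construct an SCCAConfig
#'
#' @param tau1,tau2 non-negative l1 penalties for views X and Y.
#' @param ridge1,ridge2 non-negative l2 penalties (default 0).
#' @param nComponents number of canonical components K (default 1).
#' @param maxIter maximum alternating iterations (default 200).
#' @param tol convergence threshold on the canonical-correlation change
#'   (default 1e-6).
#' @param seed integer seed (default 1).
#' @return An [SCCAConfig-class] object.
#' @export
SCCAConfig <- function(tau1 = 0, tau2 = 0, ridge1 = 0, ridge2 = 0,
                       nComponents = 1L, maxIter = 200L, tol = 1e-6,
                       seed = 1L) {
    new("SCCAConfig", tau1 = tau1, tau2 = tau2, ridge1 = ridge1,
        ridge2 = ridge2, nComponents = as.integer(nComponents),
        maxIter = as.integer(maxIter), tol = tol, seed = as.integer(seed))
}

#' CanonicalComponent: one canonical weight/score pair
#'
#' @slot w1,w2 canonical weight vectors for views X and Y, aligned to the
#'   full (undeflated) feature lists; features removed by deflation carry
#'   zero weight.
#' @slot u,v per-sample canonical scores (X w1 and Y w2 on the possibly
#'   deflated views), unit sample variance.
#' @slot correlation Pearson correlation of (u, v).
#' @slot nIter alternating iterations used.
#' @slot converged logical, whether |delta correlation| < tol was reached.
#' @slot corrTrace correlation after each alternating iteration.
#' @export
setClass("CanonicalComponent",
         representation(w1 = "numeric", w2 = "numeric",
                        u = "numeric", v = "numeric",
                        correlation = "numeric", nIter = "integer",
                        converged = "logical", corrTrace = "numeric"))

setValidity("CanonicalComponent", function(object) {
    if (length(object@u) != length(object@v))
        return("score vectors u and v must have equal length")
    if (all(object@w1 == 0) || all(object@w2 == 0))
        return("canonical weight vectors must have a non-zero entry")
    if (abs(object@correlation) > 1 + 1e-8)
        return("correlation must lie in [-1, 1]")
    TRUE
})

#' SCCAResult: a fitted sparse canonical correlation analysis
#'
#' @slot components list of [CanonicalComponent-class], in fitting order.
#' @slot config the [SCCAConfig-class] used.
#' @slot sampleIds sample identifiers aligning the score vectors.
#' @slot featureIdsX,featureIdsY feature identifiers aligning the weight
#'   vectors to the two views.
#' @seealso [fitSCCA()], [aggregateScores()]
#' @export
setClass("SCCAResult",
         representation(components = "list", config = "SCCAConfig",
                        sampleIds = "character",
                        featureIdsX = "character",
                        featureIdsY = "character"))

setValidity("SCCAResult", function(object) {
    if (length(object@components) == 0L)
        return("result must contain at least one component")
    for (cc in object@components) {
        if (!is(cc, "CanonicalComponent"))
            return("components must be CanonicalComponent objects")
        if (length(cc@w1) != length(object@featureIdsX))
            return("w1 length must match featureIdsX")
        if (length(cc@w2) != length(object@featureIdsY))
            return("w2 length must match featureIdsY")
        if (length(cc@u) != length(object@sampleIds))
            return("score length must match sampleIds")
    }
    TRUE
})

#' SubtypeAssignment: k-means subtype labels with diagnostics
#'
#' @slot sampleIds character sample identifiers.
#' @slot labels integer cluster label per sample, 1..k, canonicalised by
#'   decreasing cluster size.
#' @slot k number of clusters.
#' @slot wss total within-cluster sum of squares.
#' @slot bss between-cluster sum of squares.
#' @slot silhouette mean silhouette width.
#' @slot seed,nRestarts RNG seed and number of independent k-means++
#'   restarts used.
#' @seealso [kmeansCluster()], [selectK()]
#' @export
setClass("SubtypeAssignment",
         representation(sampleIds = "character", labels = "integer",
                        k = "integer", wss = "numeric", bss = "numeric",
                        silhouette = "numeric", seed = "integer",
                        nRestarts = "integer"))

setValidity("SubtypeAssignment", function(object) {
    if (length(object@labels) != length(object@sampleIds))
        return("labels and sampleIds must have equal length")
    if (!all(seq_len(object@k) %in% object@labels))
        return("every cluster 1..k must be non-empty")
    if (object@wss < -1e-8 || object@bss < -1e-8)
        return("wss and bss must be non-negative")
    if (is.finite(object@silhouette) &&
        (object@silhouette < -1 - 1e-8 || object@silhouette > 1 + 1e-8))
        return("mean silhouette width must lie in [-1, 1]")
    TRUE
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot eventTimes increasing distinct event times.
#' @slot survival estimated survival after each event time.
#' @slot atRisk number at risk just before each event time.
#' @slot nEvents events at each event time.
#' @slot greenwoodSE Greenwood standard error of the survival estimate.
#' @seealso [kmCurve()]
#' @export
setClass("KMCurve",
         representation(eventTimes = "numeric", survival = "numeric",
                        atRisk = "integer", nEvents = "integer",
                        greenwoodSE = "numeric"))

setValidity("KMCurve", function(object) {
    k <- length(object@eventTimes)
    if (length(object@survival) != k || length(object@atRisk) != k ||
        length(object@nEvents) != k || length(object@greenwoodSE) != k)
        return("all slots must have one entry per event time")
    if (k > 1 && any(diff(object@eventTimes) <= 0))
        return("event times must be strictly increasing")
    if (any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
        return("survival must lie in [0, 1]")
    if (k > 1 && any(diff(object@survival) > 1e-12))
        return("survival must be non-increasing")
    TRUE
})

#' CoxGroupFit: grouped Cox proportional-hazards fit with separation
#' statistics
#'
#' Holds the per-subtype log-hazard coefficients (size-weighted centered
#' so that sum(ni * beta_i) = 0), the pairwise hazard-ratio matrix, the
#' minimum pairwise hazard ratio HRmin, the SEP separation statistic in
#' both conventions, the K-sample log-rank test, and the global Schoenfeld
#' test (GST) of proportional hazards.
#'
#' @slot groupSizes named integer, samples per subtype.
#' @slot beta centered per-group log-hazard coefficients.
#' @slot covBeta covariance of the reference-coded coefficients (groups
#'   2..C vs group 1).
#' @slot loglik partial log-likelihood at the optimum.
#' @slot hrMatrix C x C pairwise hazard ratios exp(beta_i - beta_j).
#' @slot hrMin minimum over pairs of the max-oriented hazard ratio (>= 1).
#' @slot sepPrinted exp(-sum(ni/n |beta_i|)), in (0, 1].
#' @slot sepReciprocal exp(+sum(ni/n |beta_i|)), >= 1.
#' @slot logrankStat,logrankP K-sample log-rank chi-square and p-value.
#' @slot gstStat,gstP global Schoenfeld test chi-square and p-value.
#' @slot ties tie-handling used ("efron" or "breslow").
#' @slot coxph the underlying [survival::coxph()] fit (for diagnostics).
#' @seealso [coxFitSubtypes()], [hrMin()], [sepStatistic()]
#' @export
setClass("CoxGroupFit",
         representation(groupSizes = "integer", beta = "numeric",
                        covBeta = "matrix", loglik = "numeric",
                        hrMatrix = "matrix", hrMin = "numeric",
                        sepPrinted = "numeric", sepReciprocal = "numeric",
                        logrankStat = "numeric", logrankP = "numeric",
                        gstStat = "numeric", gstP = "numeric",
                        ties = "character", coxph = "ANY"))

setValidity("CoxGroupFit", function(object) {
    C <- length(object@beta)
    if (length(object@groupSizes) != C)
        return("one coefficient per group is required")
    if (abs(sum(object@groupSizes * object@beta)) > 1e-8)
        return("coefficients must satisfy sum(ni * beta_i) = 0")
    if (object@hrMin < 1 - 1e-10)
        return("hrMin must be >= 1")
    if (object@sepPrinted > 1 + 1e-10 || object@sepPrinted <= 0)
        return("sepPrinted must lie in (0, 1]")
    if (object@sepReciprocal < 1 - 1e-10)
        return("sepReciprocal must be >= 1")
    if (abs(object@sepPrinted * object@sepReciprocal - 1) > 1e-8)
        return("SEP conventions must be reciprocal")
    TRUE
})

#' SynthTruth: ground truth of a synthetic paired-omics study
#'
#' @slot latentFactors n x K latent factor matrix.
#' @slot loadingsX,loadingsY sparse p x K and q x K loading matrices.
#' @slot trueLabels integer cluster per sample.
#' @slot trueLogHazards per-cluster log-hazard offsets (may be empty
#'   before survival generation).
#' @slot enrichedSets names of planted enriched gene sets (may be empty).
#' @slot seed integer seed used.
#' @export
setClass("SynthTruth",
         representation(latentFactors = "matrix", loadingsX = "matrix",
                        loadingsY = "matrix", trueLabels = "integer",
                        trueLogHazards = "numeric",
                        enrichedSets = "character", seed = "integer"))
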