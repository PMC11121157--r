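#' Sample identifiers
#' @param object an object with samples.
#' @return character vector of sample identifiers.
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' Feature identifiers
#' @param object an object with features.
#' @return character vector of feature identifiers.
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' Underlying numeric values
#' @param object an object wrapping a numeric matrix.
#' @return the numeric matrix (samples x features).
#' @export
setGeneric("omicsValues", function(object) standardGeneric("omicsValues"))

#' Cluster labels
#' @param object a clustering result.
#' @return named integer vector of cluster labels.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' Minimum pairwise hazard ratio (HRmin)
#'
#' Over all unordered pairs of subtypes, the smallest of the
#' max-oriented pairwise hazard ratios:
#' `min over i<j of max(exp(beta_i - beta_j), exp(beta_j - beta_i))`,
#' equivalently `exp(min |beta_i - beta_j|)`. Always >= 1; HRmin = 1 iff
#' two subtypes share the same hazard.
#'
#' @param object a [CoxGroupFit-class] or a numeric vector of per-group
#'   log-hazard coefficients.
#' @return HRmin, a scalar >= 1.
#' @examples
#' hrMin(c(0, log(2), log(8)))  # pairwise max ratios 2, 8, 4 -> 2
#' @export
setGeneric("hrMin", function(object) standardGeneric("hrMin"))

#' SEP hazard-separation statistic
#'
#' Summarises the average hazard separation across C subtypes from the
#' size-weighted centered Cox coefficients beta_i (sum(ni beta_i) = 0).
#' The `printed` convention is `exp(-sum((ni/n) |beta_i|))`, bounded in
#' (0, 1]; the `reciprocal` convention is its inverse
#' `exp(+sum((ni/n) |beta_i|))`, >= 1, growing with separation. Both are
#' available because the two appear in the literature with opposite
#' orientation; the default is `reciprocal` so larger values mean more
#' separation.
#'
#' @param object a [CoxGroupFit-class].
#' @param convention "reciprocal" (default) or "printed".
#' @return the SEP statistic under the requested convention.
#' @export
setGeneric("sepStatistic",
           function(object, convention = c("reciprocal", "printed"))
               standardGeneric("sepStatistic"))
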