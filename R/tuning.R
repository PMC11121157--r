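## HRmin-driven hyperparameter search: every (tau1, tau2, K) grid point
## runs the full fit -> aggregate -> cluster -> Cox chain; selection
## maximises HRmin among grid points where the proportional-hazards
## assumption is retained (GST p > 0.05).

#' Define a tuning grid
#'
#' @param tau1Values,tau2Values non-negative l1 penalty candidates for
#'   views X and Y.
#' @param nComponentsValues candidate numbers of canonical components.
#' @param k fixed cluster count used at every grid point (subtype counts
#'   are conventionally fixed to the established number for the cancer
#'   under study while penalties are tuned).
#' @param ridge1,ridge2 l2 penalties held fixed across the grid.
#' @param seed integer seed propagated to every stochastic stage.
#' @return A `tuningGrid` list.
#' @export
tuningGrid <- function(tau1Values, tau2Values, nComponentsValues = 1L,
                       k = 3L, ridge1 = 0, ridge2 = 0, seed = 1L) {
    stopifnot(length(tau1Values) > 0, length(tau2Values) > 0,
              length(nComponentsValues) > 0, all(tau1Values >= 0),
              all(tau2Values >= 0), k >= 2L)
    structure(list(tau1Values = as.numeric(tau1Values),
                   tau2Values = as.numeric(tau2Values),
                   nComponentsValues = as.integer(nComponentsValues),
                   k = as.integer(k), ridge1 = ridge1, ridge2 = ridge2,
                   seed = as.integer(seed)),
              class = "tuningGrid")
}

#' Select the best grid row
#'
#' Among rows with `status == "ok"` and (optionally) `gst_p > gstAlpha`,
#' picks the row with maximal `hr_min`; ties are broken by larger `sep`,
#' then smaller `K`, then lexicographically smaller `(tau1, tau2)`.
#'
#' @param table the grid-search result table.
#' @param gstFilter require the proportional-hazards assumption to be
#'   retained (default TRUE).
#' @param gstAlpha significance level of the GST gate (default 0.05).
#' @return the index (row number in `table`) of the selected row.
#' @export
selectBestGridRow <- function(table, gstFilter = TRUE, gstAlpha = 0.05) {
    ok <- table$status == "ok"
    if (gstFilter)
        ok <- ok & !is.na(table$gst_p) & table$gst_p > gstAlpha
    if (!any(ok))
        stop("no grid point satisfies proportional hazards",
             " (GST p > ", gstAlpha, ")")
    cand <- which(ok)
    ord <- order(-table$hr_min[cand], -table$sep[cand], table$K[cand],
                 table$tau1[cand], table$tau2[cand])
    cand[ord[1L]]
}

#' Grid search over sparsity parameters and component counts
#'
#' For every combination of (tau1, tau2, K) the pipeline
#' [fitSCCA()] -> [aggregateScores()] -> [kmeansCluster()] ->
#' [coxFitSubtypes()] is executed and its evaluation statistics
#' recorded. Grid points where a penalty zeroes out an entire view are
#' recorded with status `"degenerate"` and excluded from selection.
#' Selection maximises HRmin among points where the GST retains
#' proportional hazards (see [selectBestGridRow()]). Deterministic given
#' the grid seed.
#'
#' @param x,y sample-aligned, standardized [OmicsView-class] objects.
#' @param surv a [SurvivalTable-class] aligned to the same samples.
#' @param grid a [tuningGrid()].
#' @param aggregation score aggregation mode (see [aggregateScores()]).
#' @param gstFilter apply the GST validity gate during selection
#'   (default TRUE).
#' @return list with `table` (one row per grid point), `best` (selected
#'   row as a one-row data.frame) and `criterion` (description of the
#'   selection rule).
#' @export
gridSearch <- function(x, y, surv, grid,
                       aggregation = c("both_views", "x_only",
                                       "mean_of_views"),
                       gstFilter = TRUE) {
    aggregation <- match.arg(aggregation)
    stopifnot(inherits(grid, "tuningGrid"))
    if (!identical(sampleNames(x), sampleNames(surv)))
        stop("inputs must be sample-aligned; see alignSamples()")
    pts <- expand.grid(tau1 = grid$tau1Values, tau2 = grid$tau2Values,
                       K = grid$nComponentsValues,
                       KEEP.OUT.ATTRS = FALSE)
    rows <- vector("list", nrow(pts))
    for (i in seq_len(nrow(pts))) {
        row <- list(tau1 = pts$tau1[i], tau2 = pts$tau2[i], K = pts$K[i],
                    hr_min = NA_real_, sep = NA_real_,
                    logrank_p = NA_real_, gst_p = NA_real_,
                    silhouette = NA_real_, status = "ok")
        res <- tryCatch({
            cfg <- SCCAConfig(tau1 = pts$tau1[i], tau2 = pts$tau2[i],
                              ridge1 = grid$ridge1, ridge2 = grid$ridge2,
                              nComponents = pts$K[i], seed = grid$seed)
            fit <- suppressWarnings(fitSCCA(x, y, cfg))
            scores <- aggregateScores(fit, mode = aggregation)
            cl <- kmeansCluster(scores, grid$k, seed = grid$seed)
            cx <- suppressWarnings(
                coxFitSubtypes(surv@time, surv@event, cl@labels))
            list(cl = cl, cx = cx)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            row$status <- "degenerate"
        } else {
            row$hr_min <- res$cx@hrMin
            row$sep <- res$cx@sepReciprocal
            row$logrank_p <- res$cx@logrankP
            row$gst_p <- res$cx@gstP
            row$silhouette <- res$cl@silhouette
        }
        rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    table <- do.call(rbind, rows)
    best <- selectBestGridRow(table, gstFilter = gstFilter)
    list(table = table, best = table[best, , drop = FALSE],
         criterion = paste0("max HRmin",
                            if (gstFilter) " subject to GST p > 0.05"))
}
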