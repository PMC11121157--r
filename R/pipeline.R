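## End-to-end driver: read -> filter -> align -> standardize ->
## (tune | fit) -> aggregate -> cluster -> survival evaluation ->
## enrichment, writing every intermediate artifact plus a
## machine-readable summary. All randomness flows from config$seed.

.configDefaults <- list(
    preset = NULL, xPath = NULL, yPath = NULL, survPath = NULL,
    gmtPath = NULL, orientation = "samples_in_rows",
    maxMissingRate = 0.05,
    tau1 = 0.1, tau2 = 0.1, ridge1 = 0.001, ridge2 = 0.001,
    nComponents = 3L,
    tuning = NULL,             # list(tau1Values, tau2Values, nComponentsValues)
    k = 3L, kRange = NULL,
    aggregation = "both_views", sepConvention = "reciprocal",
    deAlpha = 0.05, ties = "efron", gstTransform = "rank",
    outDir = NULL, seed = 1L, logLevel = "info")

#' Assemble a pipeline configuration
#'
#' Unspecified fields take the package defaults (2 canonical components,
#' tau = 0.1 and ridge = 0.001 per view, k = 3, both-view score
#' aggregation, reciprocal SEP convention, seed 1).
#'
#' @param ... configuration fields; see Details.
#' @details Recognised fields: `preset` ("recovery"/"null"/"crossing",
#'   generates synthetic inputs) or `xPath`/`yPath`/`survPath` (+
#'   optional `gmtPath`); `orientation`; `maxMissingRate`;
#'   `tau1`/`tau2`/`ridge1`/`ridge2`/`nComponents`; `tuning` (a list
#'   with `tau1Values`, `tau2Values`, `nComponentsValues` enabling
#'   HRmin grid search); `k` or `kRange`; `aggregation`;
#'   `sepConvention`; `deAlpha`; `ties`; `gstTransform`; `outDir`;
#'   `seed`.
#' @return A validated config list of class `"scclustConfig"`.
#' @export
pipelineConfig <- function(...) {
    user <- list(...)
    unknown <- setdiff(names(user), names(.configDefaults))
    if (length(unknown) > 0L)
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg <- .configDefaults
    cfg[names(user)] <- user
    if (is.null(cfg$preset) &&
        (is.null(cfg$xPath) || is.null(cfg$yPath) || is.null(cfg$survPath)))
        stop("config must provide either a preset or xPath, yPath and survPath")
    cfg$seed <- as.integer(cfg$seed)
    structure(cfg, class = "scclustConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipelineConfig()].
#' @return A config list of class `"scclustConfig"`.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    do.call(pipelineConfig, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full subtyping pipeline
#'
#' Executes the three-stage workflow — sparse CCA integration of the two
#' omics views, k-means clustering of the aggregated canonical scores,
#' and survival-based validation with per-subtype enrichment — and
#' writes every intermediate artifact plus `summary.json` into the run
#' directory. Outputs are reproducible from the config + seed alone.
#'
#' @param config a config from [pipelineConfig()] or
#'   [readPipelineConfig()], or a plain list of its fields.
#' @return the run directory path, invisibly; the summary is available
#'   as `jsonlite::read_json(file.path(dir, "summary.json"))`.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "scclustConfig"))
        config <- do.call(pipelineConfig, as.list(config))
    outDir <- config$outDir
    if (is.null(outDir))
        outDir <- tempfile("scclust_run_")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logLines <- c(sprintf("sCClust %s", as.character(packageVersion("sCClust"))),
                  sprintf("R %s.%s", R.version$major, R.version$minor),
                  sprintf("seed %d", config$seed))
    truth <- NULL
    db <- NULL

    if (!is.null(config$preset)) {
        sim <- .stage("simulate",
                      simulateStudy(config$preset, seed = config$seed))
        x <- sim$x; y <- sim$y; surv <- sim$surv
        db <- sim$db; truth <- sim$truth
        inDir <- file.path(outDir, "inputs")
        dir.create(inDir, showWarnings = FALSE)
        writeOmicsMatrix(x, file.path(inDir, "X.tsv"))
        writeOmicsMatrix(y, file.path(inDir, "Y.tsv"))
        writeSurvivalTable(surv, file.path(inDir, "survival.tsv"))
        writeGMT(db, file.path(inDir, "sets.gmt"))
        logLines <- c(logLines, sprintf("preset %s", config$preset))
    } else {
        x <- .stage("read_x", readOmicsMatrix(config$xPath,
                                              config$orientation))
        y <- .stage("read_y", readOmicsMatrix(config$yPath,
                                              config$orientation))
        surv <- .stage("read_survival", readSurvivalTable(config$survPath))
        if (!is.null(config$gmtPath))
            db <- .stage("read_gmt", readGMT(config$gmtPath))
    }

    x <- .stage("filter_missing",
                filterMissingFeatures(x, config$maxMissingRate))
    y <- .stage("filter_missing",
                filterMissingFeatures(y, config$maxMissingRate))
    al <- .stage("align_samples", alignSamples(x, y, surv))
    x <- .stage("standardize", suppressWarnings(standardizeColumns(al$x)))
    y <- .stage("standardize", suppressWarnings(standardizeColumns(al$y)))
    surv <- al$surv
    n <- length(sampleNames(surv))

    if (!is.null(config$tuning)) {
        grid <- .stage("tune", do.call(tuningGrid, c(
            config$tuning,
            list(k = config$k, ridge1 = config$ridge1,
                 ridge2 = config$ridge2, seed = config$seed))))
        tuned <- .stage("tune", gridSearch(x, y, surv, grid,
                                           aggregation = config$aggregation))
        .writeTSV(tuned$table, file.path(outDir, "tuning.tsv"))
        config$tau1 <- tuned$best$tau1
        config$tau2 <- tuned$best$tau2
        config$nComponents <- tuned$best$K
        yaml::write_yaml(list(tau1 = config$tau1, tau2 = config$tau2,
                              nComponents = config$nComponents,
                              ridge1 = config$ridge1,
                              ridge2 = config$ridge2, k = config$k,
                              seed = config$seed),
                         file.path(outDir, "best_config.yaml"))
        logLines <- c(logLines,
                      sprintf("tuning selected tau1=%g tau2=%g K=%d",
                              config$tau1, config$tau2, config$nComponents))
    }

    scca <- .stage("fit_scca", {
        cfg <- SCCAConfig(tau1 = config$tau1, tau2 = config$tau2,
                          ridge1 = config$ridge1, ridge2 = config$ridge2,
                          nComponents = config$nComponents,
                          seed = config$seed)
        suppressWarnings(fitSCCA(x, y, cfg))
    })
    wx <- canonicalWeights(scca, "x"); wy <- canonicalWeights(scca, "y")
    .writeTSV(data.frame(feature_id = rownames(wx), wx, check.names = FALSE),
              file.path(outDir, "weights_x.tsv"))
    .writeTSV(data.frame(feature_id = rownames(wy), wy, check.names = FALSE),
              file.path(outDir, "weights_y.tsv"))

    scores <- .stage("aggregate",
                     aggregateScores(scca, mode = config$aggregation))
    .writeTSV(data.frame(sample_id = rownames(scores), scores,
                         check.names = FALSE),
              file.path(outDir, "scores.tsv"))

    k <- config$k
    if (!is.null(config$kRange)) {
        sel <- .stage("select_k", selectK(scores, config$kRange,
                                          seed = config$seed))
        .writeTSV(sel$diagnostics, file.path(outDir, "k_diagnostics.tsv"))
        k <- sel$kBest
        logLines <- c(logLines, sprintf("selectK chose k=%d", k))
    }
    cl <- .stage("cluster", kmeansCluster(scores, k, seed = config$seed))
    .writeTSV(data.frame(sample_id = cl@sampleIds, subtype = cl@labels),
              file.path(outDir, "labels.tsv"))
    .writeTSV(data.frame(k = cl@k, wss = cl@wss, bss = cl@bss,
                         silhouette = cl@silhouette),
              file.path(outDir, "cluster_diagnostics.tsv"))

    cx <- .stage("survival_eval",
                 suppressWarnings(coxFitSubtypes(surv@time, surv@event,
                                                 cl@labels,
                                                 ties = config$ties,
                                                 gstTransform =
                                                     config$gstTransform)))
    for (g in seq_len(k)) {
        sel <- cl@labels == g
        km <- kmCurve(surv@time[sel], surv@event[sel])
        .writeTSV(kmCurveTable(km),
                  file.path(outDir, sprintf("km_subtype%d.tsv", g)))
    }
    sepValue <- sepStatistic(cx, config$sepConvention)
    .writeTSV(data.frame(p_value = cx@logrankP, hr_min = cx@hrMin,
                         sep = sepValue,
                         sep_convention = config$sepConvention,
                         gst_p = cx@gstP),
              file.path(outDir, "evaluation.tsv"))

    oraTop <- NULL
    plantedRank <- NULL; plantedQ <- NULL
    .stage("enrichment", {
        for (g in seq_len(k)) {
            de <- tryCatch(subtypeDE(x, cl@labels, g, alpha = config$deAlpha),
                           error = function(e) NULL)
            if (is.null(de)) next
            .writeTSV(de, file.path(outDir, sprintf("de_subtype%d.tsv", g)))
            if (is.null(db)) next
            for (dir in c("up", "down")) {
                genes <- de$gene_id[de$direction == dir]
                if (length(genes) == 0L) next
                ora <- tryCatch(suppressWarnings(oraTest(genes, db)),
                                error = function(e) NULL)
                if (is.null(ora)) next
                .writeTSV(ora, file.path(outDir,
                                         sprintf("ora_subtype%d_%s.tsv",
                                                 g, dir)))
                if (!is.null(truth) &&
                    length(truth@enrichedSets) > 0L) {
                    r <- match(truth@enrichedSets[1L], ora$set_name)
                    if (!is.na(r) &&
                        (is.null(plantedRank) || r < plantedRank)) {
                        plantedRank <- r
                        plantedQ <- ora$q_value[r]
                    }
                }
                if (is.null(oraTop)) oraTop <- ora$set_name[1L]
            }
        }
    })

    summary <- list(
        n = n, k = k, seed = config$seed,
        tau1 = config$tau1, tau2 = config$tau2,
        n_components = length(scca@components),
        canonical_correlations = canonicalCorrelations(scca),
        silhouette = cl@silhouette,
        logrank_p = cx@logrankP, hr_min = cx@hrMin,
        sep = sepValue, sep_convention = config$sepConvention,
        gst_p = cx@gstP)
    if (!is.null(truth)) {
        summary$ari <- mclust::adjustedRandIndex(cl@labels,
                                                 truth@trueLabels)
        if (!is.null(plantedRank)) {
            summary$planted_set_rank <- plantedRank
            summary$planted_set_q <- plantedQ
        }
    }
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logLines, file.path(outDir, "run_log.txt"))
    invisible(outDir)
}
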