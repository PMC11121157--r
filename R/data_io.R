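## Reading, writing and preprocessing of omics matrices, survival tables
## and GMT gene-set collections. Delimiter is auto-detected from the file
## extension (.csv -> comma, otherwise tab); missing tokens are "", "NA",
## "NaN".

.delimFor <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.missingTokens <- c("", "NA", "NaN")

#' Read an omics matrix from delimited text
#'
#' Reads a TSV/CSV matrix with one header row and one leading ID column
#' and returns it oriented samples x features regardless of the file
#' orientation. Empty cells, "NA" and "NaN" become missing values; any
#' other non-numeric cell is an error reporting its position.
#'
#' @param path file path (.csv is comma-delimited, anything else tab).
#' @param orientation "samples_in_rows" (default) or "features_in_rows".
#' @return An [OmicsView-class], samples x features.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(id = c("S1", "S2"), g1 = c(1, 2), g2 = c(3, 4)),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' readOmicsMatrix(tf)
#' @export
readOmicsMatrix <- function(path,
                            orientation = c("samples_in_rows",
                                            "features_in_rows")) {
    orientation <- match.arg(orientation)
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- read.delim(path, sep = .delimFor(path), header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     na.strings = NULL, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("expected an ID column plus at least one data column in ", path)
    rowIds <- as.character(df[[1L]])
    colIds <- colnames(df)[-1L]
    if (anyDuplicated(rowIds))
        stop("duplicate row identifiers in ", path, ": ",
             paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
    if (anyDuplicated(colIds))
        stop("duplicate column identifiers in ", path, ": ",
             paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    body <- as.matrix(df[, -1L, drop = FALSE])
    isMissing <- matrix(trimws(body) %in% .missingTokens, nrow = nrow(body))
    num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
    bad <- which(is.na(num) & !isMissing, arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("non-numeric cell '%s' at row %d ('%s'), column %d ('%s') in %s",
                     body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                     rowIds[bad[1L, 1L]], bad[1L, 2L], colIds[bad[1L, 2L]],
                     path))
    num[isMissing] <- NA_real_
    dimnames(num) <- list(rowIds, colIds)
    if (orientation == "features_in_rows")
        num <- t(num)
    OmicsView(num)
}

#' Write an OmicsView to tab-delimited text
#'
#' @param view an [OmicsView-class].
#' @param path output path; written samples x features with an
#'   `sample_id` header for the ID column.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(view, path) {
    v <- omicsValues(view)
    df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a survival table
#'
#' Expects delimited text with columns `sample_id`, `time`, `event`
#' (1 = event observed, 0 = censored).
#'
#' @param path file path (.csv comma-delimited, otherwise tab).
#' @return A [SurvivalTable-class].
#' @export
readSurvivalTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- read.delim(path, sep = .delimFor(path), header = TRUE,
                     stringsAsFactors = FALSE)
    need <- c("sample_id", "time", "event")
    if (!all(need %in% colnames(df)))
        stop("survival table ", path, " must have columns: ",
             paste(need, collapse = ", "))
    SurvivalTable(df$sample_id, df$time, df$event)
}

#' Write a SurvivalTable to tab-delimited text
#' @param table a [SurvivalTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSurvivalTable <- function(table, path) {
    df <- data.frame(sample_id = table@sampleIds, time = table@time,
                     event = table@event)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Drop high-missingness features and impute the rest
#'
#' Features whose fraction of missing entries is strictly greater than
#' `maxMissingRate` are discarded; missing entries in retained features
#' are imputed (default: by the feature mean across observed samples).
#' The dropped feature identifiers are attached as attribute
#' `"dropped"`.
#'
#' @param view an [OmicsView-class].
#' @param maxMissingRate maximum tolerated missing fraction per feature
#'   (default 0.05, i.e. 5%).
#' @param impute "mean", "median", or "fail" (error if anything is left
#'   to impute).
#' @return The filtered, fully observed [OmicsView-class].
#' @export
filterMissingFeatures <- function(view, maxMissingRate = 0.05,
                                  impute = c("mean", "median", "fail")) {
    impute <- match.arg(impute)
    stopifnot(maxMissingRate >= 0, maxMissingRate <= 1)
    v <- omicsValues(view)
    missRate <- colMeans(is.na(v))
    keep <- missRate <= maxMissingRate
    if (!any(keep))
        stop("no features survive missing filter (max missing rate ",
             maxMissingRate, ")")
    dropped <- colnames(v)[!keep]
    v <- v[, keep, drop = FALSE]
    if (anyNA(v)) {
        if (impute == "fail")
            stop("missing values remain after filtering and impute='fail'")
        fun <- if (impute == "mean") mean else stats::median
        for (j in which(colSums(is.na(v)) > 0L)) {
            obs <- !is.na(v[, j])
            if (!any(obs))
                stop("feature '", colnames(v)[j],
                     "' has no observed values at the given threshold")
            v[!obs, j] <- fun(v[obs, j])
        }
    }
    out <- OmicsView(v)
    attr(out, "dropped") <- dropped
    out
}

#' Restrict two omics views and a survival table to their shared samples
#'
#' Subjects present in all three inputs are retained, in one common
#' order (the order of first appearance in `x`).
#'
#' @param x,y [OmicsView-class] objects for the two data views.
#' @param surv a [SurvivalTable-class].
#' @return A list with elements `x`, `y`, `surv`, all on the identical
#'   sample set and order.
#' @export
alignSamples <- function(x, y, surv) {
    sx <- sampleNames(x); sy <- sampleNames(y); ss <- sampleNames(surv)
    common <- sx[sx %in% sy & sx %in% ss]
    if (length(common) < 3L)
        stop(sprintf(paste0("fewer than 3 samples shared by all inputs ",
                            "(shared: %d; x: %d, y: %d, survival: %d)"),
                     length(common), length(sx), length(sy), length(ss)))
    idx <- match(common, ss)
    list(x = OmicsView(omicsValues(x)[common, , drop = FALSE]),
         y = OmicsView(omicsValues(y)[common, , drop = FALSE]),
         surv = SurvivalTable(common, surv@time[idx], surv@event[idx]))
}

#' Standardize features to zero mean and unit variance
#'
#' Columns are centered and scaled to unit sample standard deviation
#' (denominator n - 1). Constant columns carry no signal for a
#' correlation analysis and are dropped with a warning; their
#' identifiers are attached as attribute `"dropped"`.
#'
#' @param view an [OmicsView-class] with no missing values and n >= 2.
#' @return The standardized [OmicsView-class].
#' @export
standardizeColumns <- function(view) {
    v <- omicsValues(view)
    if (anyNA(v))
        stop("standardizeColumns requires a fully observed matrix; ",
             "run filterMissingFeatures first")
    if (nrow(v) < 2L)
        stop("standardizeColumns requires at least 2 samples")
    mu <- colMeans(v)
    sdev <- apply(v, 2L, sd)
    const <- sdev == 0 | !is.finite(sdev)
    dropped <- colnames(v)[const]
    if (any(const)) {
        warning("dropping ", sum(const), " constant feature(s): ",
                paste(head(dropped, 5L), collapse = ", "),
                if (sum(const) > 5L) ", ..." else "")
        if (all(const))
            stop("all features are constant")
    }
    v <- sweep(v[, !const, drop = FALSE], 2L, mu[!const], "-")
    v <- sweep(v, 2L, sdev[!const], "/")
    out <- OmicsView(v)
    attr(out, "dropped") <- dropped
    out
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated gene
#' identifiers. Duplicate genes within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @param universe optional background universe; defaults to the union
#'   of all set members.
#' @return A [GeneSetDB-class].
#' @export
readGMT <- function(path, universe = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("no gene sets in ", path)
    sets <- list()
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L)
            stop(sprintf("line %d of %s has %d field(s); expected set name, description and at least one gene",
                         i, path, length(fields)))
        genes <- fields[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes)) {
            warning(sprintf("duplicate genes in set '%s' (line %d); deduplicated",
                            fields[[1L]], i))
            genes <- unique(genes)
        }
        sets[[fields[[1L]]]] <- genes
    }
    GeneSetDB(sets, universe = universe)
}

#' Write a GeneSetDB in GMT format
#' @param db a [GeneSetDB-class].
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(db, path, descriptions = NULL) {
    nm <- names(geneSets(db))
    if (is.null(descriptions))
        descriptions <- rep("na", length(nm))
    lines <- vapply(seq_along(nm), function(i)
        paste(c(nm[i], descriptions[i], geneSets(db)[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}
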