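## Per-subtype differential expression (moderated t via limma) and
## hypergeometric pathway over-representation analysis, plus the
## canonical-weight gene rankings used to interpret fitted components.

#' Subtype-versus-rest differential expression
#'
#' Moderated two-sample comparison of one subtype against all remaining
#' samples, per gene, with empirical-Bayes variance shrinkage
#' (limma's lmFit/eBayes) and Benjamini-Hochberg adjustment across
#' genes. Direction is called at `q <= alpha`.
#'
#' @param expr an [OmicsView-class] expression matrix
#'   (samples x genes).
#' @param labels subtype label per sample, aligned to `expr`.
#' @param subtype the subtype to contrast against the rest.
#' @param alpha FDR level for direction calls (default 0.05).
#' @return data.frame with columns `gene_id`, `mean_diff` (subtype mean
#'   minus rest mean), `t_stat` (moderated t), `p_value`, `q_value`
#'   (BH), and `direction` in {"up", "down", "ns"}.
#' @export
subtypeDE <- function(expr, labels, subtype, alpha = 0.05) {
    stopifnot(is(expr, "OmicsView"))
    v <- omicsValues(expr)
    if (length(labels) != nrow(v))
        stop("labels must have one entry per sample")
    inGroup <- labels == subtype
    if (sum(inGroup) < 3L || sum(!inGroup) < 3L)
        stop("subtype-vs-rest comparison requires at least 3 samples per side (",
             sum(inGroup), " vs ", sum(!inGroup), ")")
    design <- cbind(Intercept = 1, subtype = as.numeric(inGroup))
    fit <- limma::lmFit(t(v), design)
    fit <- limma::eBayes(fit)
    p <- fit$p.value[, "subtype"]
    q <- p.adjust(p, method = "BH")
    diff <- fit$coefficients[, "subtype"]
    dir <- rep("ns", length(p))
    dir[q <= alpha & diff > 0] <- "up"
    dir[q <= alpha & diff < 0] <- "down"
    out <- data.frame(gene_id = colnames(v), mean_diff = unname(diff),
                      t_stat = unname(fit$t[, "subtype"]),
                      p_value = unname(p), q_value = unname(q),
                      direction = dir, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Hypergeometric over-representation analysis
#'
#' Tests every gene set for over-representation of the input gene list
#' against the background universe: the p-value is the hypergeometric
#' upper tail `P(K >= k)` with universe size N, in-universe set size M
#' and list size n_drawn, BH-adjusted across sets.
#'
#' @param genes character gene list (e.g. the up-regulated genes of one
#'   subtype); genes outside the universe are dropped with a warning.
#' @param db a [GeneSetDB-class]; universe size >= 10.
#' @return data.frame sorted by p-value with columns `set_name`,
#'   `overlap` (k), `set_size` (M), `list_size` (n_drawn),
#'   `universe_size` (N), `gene_ratio` (k/n_drawn), `p_value`,
#'   `q_value`.
#' @examples
#' db <- GeneSetDB(list(s1 = paste0("g", 1:5)),
#'                 universe = paste0("g", 1:20))
#' oraTest(paste0("g", 1:5), db)  # complete overlap: p = 1/choose(20,5)
#' @export
oraTest <- function(genes, db) {
    stopifnot(is(db, "GeneSetDB"))
    N <- length(geneUniverse(db))
    if (N < 10L)
        stop("universe must contain at least 10 genes")
    genes <- unique(as.character(genes))
    inUniv <- genes %in% geneUniverse(db)
    if (!all(inUniv)) {
        warning(sum(!inUniv), " gene(s) outside the universe dropped")
        genes <- genes[inUniv]
    }
    if (length(genes) == 0L)
        stop("empty gene list after intersection with the universe")
    nDrawn <- length(genes)
    sets <- geneSets(db)
    rows <- lapply(names(sets), function(nm) {
        members <- intersect(sets[[nm]], geneUniverse(db))
        M <- length(members)
        k <- length(intersect(genes, members))
        p <- if (nDrawn == 0L || M == 0L) 1
             else phyper(k - 1L, M, N - M, nDrawn, lower.tail = FALSE)
        data.frame(set_name = nm, overlap = k, set_size = M,
                   list_size = nDrawn, universe_size = N,
                   gene_ratio = if (nDrawn > 0L) k / nDrawn else 0,
                   p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out <- out[order(out$p_value, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Non-zero genes per canonical component
#'
#' @param result an [SCCAResult-class].
#' @param view "x" (default, e.g. expression) or "y".
#' @return named list, one entry per component, each a named numeric
#'   vector of the non-zero canonical weights (names = feature IDs).
#' @export
componentGeneLists <- function(result, view = c("x", "y")) {
    view <- match.arg(view)
    W <- canonicalWeights(result, view)
    out <- lapply(seq_len(ncol(W)), function(k) {
        w <- W[, k]
        w[w != 0]
    })
    names(out) <- colnames(W)
    out
}

#' Rank genes by average absolute canonical weight
#'
#' Orders features by the mean over components of the absolute canonical
#' weight, descending (ties broken by feature-ID order). This is the
#' ranking used to nominate the genes driving the latent subtype
#' structure.
#'
#' @param result an [SCCAResult-class].
#' @param view "x" (default) or "y".
#' @return data.frame with columns `gene_id` and `avg_abs_weight`, in
#'   decreasing weight order.
#' @export
rankGenesByAvgAbsWeight <- function(result, view = c("x", "y")) {
    view <- match.arg(view)
    W <- canonicalWeights(result, view)
    avg <- rowMeans(abs(W))
    ord <- order(-avg, rownames(W))
    data.frame(gene_id = rownames(W)[ord], avg_abs_weight = unname(avg[ord]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Dot plot of over-representation results
#'
#' Top sets by p-value, point size encoding the gene ratio and shading
#' the adjusted p-value.
#'
#' @param ora data.frame from [oraTest()].
#' @param topN number of sets to show (default 15).
#' @return `ora`, invisibly.
#' @export
plotORADot <- function(ora, topN = 15L) {
    d <- head(ora[order(ora$p_value), , drop = FALSE], topN)
    d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    shade <- grDevices::gray(pmin(0.8, pmax(0, log10(d$q_value) / -8)))
    graphics::dotchart(d$gene_ratio, labels = d$set_name, pch = 19,
                       pt.cex = 0.5 + 3 * d$gene_ratio, color = shade,
                       xlab = "gene ratio (overlap / list size)")
    invisible(ora)
}
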