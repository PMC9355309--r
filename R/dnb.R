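#' Select genes with high expression deviation in one group
#'
#' Per-gene replicate SD is computed within \code{group} and within
#' \code{reference}; a gene is selected when
#' \code{SD(group) >= sdFold * SD(reference)} and \code{SD(reference) > 0}.
#' Genes with zero reference SD are selected whenever their group SD is
#' positive and flagged (\code{zero_reference}). Genes that are zero in at
#' least \code{minExpressedFraction} of all samples (assessed on the counts
#' assay when present) are excluded before selection.
#'
#' @param x a \linkS4class{TimecourseExperiment}; SDs are taken on the
#'   active scale (log2-CPM after \code{\link{normalizeLogCpm}}).
#' @param group group whose deviation is assessed.
#' @param reference comparison group, default the reference group.
#' @param sdFold fold threshold, default 2.
#' @param minExpressedFraction zero-fraction above which a gene is treated
#'   as not expressed, default 0.5.
#' @return data.frame of selected genes: \code{gene_id}, \code{sd_group},
#'   \code{sd_reference}, \code{zero_reference}.
#' @export
selectHighSdGenes <- function(x, group, reference = referenceGroup(x),
                              sdFold = 2, minExpressedFraction = 0.5) {
    if (sdFold <= 0) stop("sdFold must be positive")
    a <- .groupValues(x, group, minReplicates = 2L)
    b <- .groupValues(x, reference, minReplicates = 2L)
    zeroSource <- if ("counts" %in% assayNames(x)) assay(x, "counts")
                  else .activeValues(x)
    expressed <- rowMeans(zeroSource == 0) < minExpressedFraction
    sdG <- .rowSds(a)
    sdR <- .rowSds(b)
    sel <- expressed & ((sdR > 0 & sdG >= sdFold * sdR) |
                        (sdR == 0 & sdG > 0))
    data.frame(gene_id = rownames(x)[sel],
               sd_group = unname(sdG[sel]),
               sd_reference = unname(sdR[sel]),
               zero_reference = unname(sdR[sel] == 0),
               row.names = NULL)
}

#' Pairwise Pearson correlation of genes within one group
#'
#' @param x a \linkS4class{TimecourseExperiment}.
#' @param group group whose replicates are correlated over.
#' @param genes gene ids (>= 2).
#' @return symmetric correlation matrix with unit diagonal; pairs involving
#'   a zero-variance gene are set to 0 with a warning. Two replicates give
#'   a degenerate (+/-1) estimate and also warn.
#' @export
pccMatrix <- function(x, group, genes) {
    if (length(genes) < 2L) stop("need >= 2 genes")
    v <- .groupValues(x, group, minReplicates = 2L)
    if (ncol(v) == 2L)
        warning("only 2 replicates: correlation estimates are degenerate")
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
        stop(sprintf("unknown gene '%s'", missing[1L]))
    r <- suppressWarnings(cor(t(v[genes, , drop = FALSE])))
    if (anyNA(r)) {
        warning("zero-variance gene(s): correlations set to 0")
        r[is.na(r)] <- 0
    }
    diag(r) <- 1
    r
}

#' Group genes by correlation at a fixed threshold
#'
#' Average-linkage hierarchical clustering on the distance
#' \code{1 - |PCC|}, cut at height \code{1 - threshold}; alternatively the
#' connected components of the graph with edges at \code{|PCC| >=
#' threshold}. Both agree on well-separated correlation blocks.
#'
#' @param pcc correlation matrix from \code{\link{pccMatrix}}.
#' @param threshold correlation threshold in (0, 1), default 0.9.
#' @param minClusterSize smallest reported cluster, default 5 (pairs and
#'   triplets give unstable mean correlations).
#' @param mode \code{"hclust"} (default) or \code{"components"}.
#' @return list: \code{clusters} (gene-id vectors, largest first) and
#'   \code{small} (members of undersized groups).
#' @export
clusterByCorrelation <- function(pcc, threshold = 0.9, minClusterSize = 5,
                                 mode = c("hclust", "components")) {
    mode <- match.arg(mode)
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must be in (0, 1)")
    genes <- rownames(pcc)
    if (mode == "hclust") {
        hc <- hclust(stats::as.dist(1 - abs(pcc)), method = "average")
        grp <- cutree(hc, h = 1 - threshold)
    } else {
        adj <- abs(pcc) >= threshold
        diag(adj) <- FALSE
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        grp <- igraph::components(g)$membership
    }
    parts <- split(genes, grp)
    big <- parts[lengths(parts) >= minClusterSize]
    big <- big[order(-lengths(big))]
    names(big) <- NULL
    list(clusters = big,
         small = sort(unlist(parts[lengths(parts) < minClusterSize],
                             use.names = FALSE)))
}

#' Composite index of a DNB cluster
#'
#' \code{CI = meanSd * pcc1 / pcc0}: mean within-group SD of the cluster
#' genes, scaled by the ratio of mean absolute intra-cluster correlation to
#' mean absolute cluster-to-rest correlation. An isolated cluster
#' (\code{pcc0} below \code{eps}) has no defined CI and raises an error.
#'
#' @param meanSd mean per-gene within-group SD (>= 0).
#' @param pcc1 mean absolute intra-cluster Pearson correlation in [0, 1].
#' @param pcc0 mean absolute cluster-to-others correlation in [0, 1].
#' @param eps degeneracy guard for pcc0, default 1e-6.
#' @return the composite index.
#' @examples
#' compositeIndex(10.69, 0.96, 0.44)  # 23.32 at two decimals
#' @export
compositeIndex <- function(meanSd, pcc1, pcc0, eps = 1e-6) {
    if (meanSd < 0) stop("meanSd must be >= 0")
    if (pcc1 < 0 || pcc1 > 1 || pcc0 < 0 || pcc0 > 1)
        stop("pcc1 and pcc0 must be in [0, 1]")
    if (pcc0 < eps)
        stop("degenerate cluster: pcc0 below eps, CI undefined")
    meanSd * pcc1 / pcc0
}

# stats for one candidate cluster inside the selected-gene universe
.clusterStats <- function(cluster, pcc, sds, eps = 1e-6) {
    others <- setdiff(rownames(pcc), cluster)
    sub <- pcc[cluster, cluster, drop = FALSE]
    pcc1 <- mean(abs(sub[upper.tri(sub)]))
    pcc0 <- if (length(others))
        mean(abs(pcc[cluster, others, drop = FALSE])) else NA_real_
    meanSd <- mean(sds[cluster])
    ci <- if (!is.na(pcc0) && pcc0 >= eps)
        compositeIndex(meanSd, pcc1, pcc0, eps) else NA_real_
    list(genes = cluster, size = length(cluster), mean_SD = meanSd,
         pcc1 = pcc1, pcc0 = pcc0, CI = ci)
}

#' Evaluate the DNB composite index for one group
#'
#' Chains \code{\link{selectHighSdGenes}}, \code{\link{pccMatrix}} and
#' \code{\link{clusterByCorrelation}}, then computes per-cluster statistics
#' with \code{pcc0} taken against all other selected genes of the group.
#' The best cluster maximizes CI (ties: larger cluster, then
#' lexicographically first gene). A group without a usable cluster returns
#' an NA-flagged result rather than an error.
#'
#' @param x a \linkS4class{TimecourseExperiment} (log2 scale recommended).
#' @param group group to evaluate.
#' @param reference reference group for the SD fold rule.
#' @param sdFold,minExpressedFraction see \code{\link{selectHighSdGenes}}.
#' @param pccThreshold,minClusterSize,clusterMode see
#'   \code{\link{clusterByCorrelation}}.
#' @return list: \code{group}, \code{selected} (data.frame),
#'   \code{selected_gene_number}, \code{candidates} (per-cluster stats),
#'   \code{best} (stats of the best cluster or NULL), \code{edges}
#'   (data.frame gene_a, gene_b, pcc at |PCC| >= threshold).
#' @export
evaluateDnbGroup <- function(x, group, reference = referenceGroup(x),
                             sdFold = 2, minExpressedFraction = 0.5,
                             pccThreshold = 0.9, minClusterSize = 5,
                             clusterMode = "hclust") {
    sel <- selectHighSdGenes(x, group, reference, sdFold,
                             minExpressedFraction)
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        pcc = numeric())
    base <- list(group = group, selected = sel,
                 selected_gene_number = nrow(sel),
                 candidates = list(), best = NULL, edges = empty)
    if (nrow(sel) < 2L) return(base)
    pcc <- suppressWarnings(pccMatrix(x, group, sel$gene_id))
    sds <- setNames(sel$sd_group, sel$gene_id)
    cl <- clusterByCorrelation(pcc, pccThreshold, minClusterSize,
                               clusterMode)
    ut <- which(upper.tri(pcc) & abs(pcc) >= pccThreshold, arr.ind = TRUE)
    base$edges <- data.frame(gene_a = rownames(pcc)[ut[, 1L]],
                             gene_b = rownames(pcc)[ut[, 2L]],
                             pcc = pcc[ut])
    if (!length(cl$clusters)) return(base)
    base$candidates <- lapply(cl$clusters, .clusterStats, pcc = pcc,
                              sds = sds)
    ok <- !vapply(base$candidates, function(s) is.na(s$CI), logical(1L))
    if (any(ok)) {
        cand <- base$candidates[ok]
        o <- order(-vapply(cand, `[[`, numeric(1L), "CI"),
                   -vapply(cand, `[[`, numeric(1L), "size"),
                   vapply(cand, function(s) sort(s$genes)[1L],
                          character(1L)))
        base$best <- cand[[o[1L]]]
    }
    base
}

#' Run the DNB analysis over all non-reference groups
#'
#' @param x a \linkS4class{TimecourseExperiment}.
#' @param groups groups to evaluate, default all non-reference groups.
#' @param reference the reference group.
#' @param sdFold,minExpressedFraction,pccThreshold,minClusterSize,clusterMode
#'   stage parameters, see \code{\link{evaluateDnbGroup}}.
#' @return a \linkS4class{DnbResult}
#' @export
runDnb <- function(x, groups = setdiff(groupOrder(x), referenceGroup(x)),
                   reference = referenceGroup(x), sdFold = 2,
                   minExpressedFraction = 0.5, pccThreshold = 0.9,
                   minClusterSize = 5, clusterMode = "hclust") {
    res <- lapply(groups, function(g)
        evaluateDnbGroup(x, g, reference, sdFold, minExpressedFraction,
                         pccThreshold, minClusterSize, clusterMode))
    names(res) <- groups
    rows <- lapply(res, function(r) {
        b <- r$best
        data.frame(group = r$group,
                   selected_gene_number = r$selected_gene_number,
                   cluster_size = if (is.null(b)) NA_integer_ else b$size,
                   mean_SD = if (is.null(b)) NA_real_ else b$mean_SD,
                   pcc1 = if (is.null(b)) NA_real_ else b$pcc1,
                   pcc0 = if (is.null(b)) NA_real_ else b$pcc0,
                   CI = if (is.null(b)) NA_real_ else b$CI)
    })
    new("DnbResult",
        groupTable = do.call(rbind, c(rows, list(make.row.names = FALSE))),
        candidates = lapply(res, `[[`, "candidates"),
        bestClusters = lapply(res, function(r)
            if (is.null(r$best)) character() else r$best$genes),
        edges = lapply(res, `[[`, "edges"),
        selected = lapply(res, `[[`, "selected"),
        params = list(sdFold = sdFold,
                      minExpressedFraction = minExpressedFraction,
                      pccThreshold = pccThreshold,
                      minClusterSize = minClusterSize,
                      clusterMode = clusterMode, reference = reference))
}

#' @describeIn tippingPoint arg-max CI over a named per-group CI vector.
#'   Returns list \code{group} (NA when no CI is defined, with a message),
#'   \code{ci} and \code{table} (group, CI in input order). A single
#'   defined CI wins by default but warns about low confidence.
#' @param x a named numeric vector of per-group composite indices, or a
#'   \linkS4class{DnbResult}.
#' @param ... unused.
#' @examples
#' tippingPoint(c(IR16 = 18.15, IR18 = 19.43, IR22 = 23.32,
#'                IR26 = 19.10, IR30 = 19.35))$group   # "IR22"
#' @export
setMethod("tippingPoint", "numeric", function(x, ...) {
    stopifnot(!is.null(names(x)))
    tab <- data.frame(group = names(x), CI = unname(x))
    defined <- which(!is.na(x))
    if (!length(defined)) {
        message("no transition detected: no group has a defined CI")
        return(list(group = NA_character_, ci = NA_real_, table = tab))
    }
    if (length(defined) == 1L)
        warning("only one group has a defined CI; low confidence")
    best <- defined[which.max(x[defined])]
    list(group = names(x)[best], ci = unname(x[best]), table = tab)
})

#' @describeIn tippingPoint arg-max CI over the groups of a DNB run.
#' @export
setMethod("tippingPoint", "DnbResult", function(x, ...) {
    ci <- setNames(x@groupTable$CI, x@groupTable$group)
    tippingPoint(ci)
})
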