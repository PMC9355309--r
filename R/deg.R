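#' Log2 counts-per-million normalization
#'
#' Computes \code{log2((count + pc) / (libSize + 2 * pc) * 1e6)} per cell.
#' The returned object keeps the raw counts alongside the new
#' \code{"logcpm"} assay and switches the active scale to \code{"log2"};
#' log-scale input is refused (no double normalization).
#'
#' @param x counts-scale \linkS4class{TimecourseExperiment}.
#' @param pseudocount positive offset, default 0.5.
#' @return a log2-scale \linkS4class{TimecourseExperiment}.
#' @export
normalizeLogCpm <- function(x, pseudocount = 0.5) {
    .requireScale(x, "counts")
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    counts <- assay(x, "counts")
    lib <- colSums(counts)
    if (any(lib == 0))
        stop(sprintf("sample '%s' has zero library size",
                     colnames(counts)[lib == 0][1L]))
    logcpm <- log2(sweep(counts + pseudocount, 2L, lib + 2 * pseudocount,
                         `/`) * 1e6)
    out <- x
    assays(out, withDimnames = FALSE) <-
        list(counts = counts, logcpm = logcpm)
    metadata(out)$assayScale <- "log2"
    validObject(out)
    out
}

#' Per-gene differential test of one group against the reference
#'
#' Log2 fold change is the difference of group means on the log2 scale; the
#' p-value comes from a two-sided Welch unequal-variance t-test across
#' replicates. Genes with zero variance in both groups get p = 1 when the
#' means are equal (and p = 0 otherwise). This is a transparent substitute
#' for a negative-binomial DEG test: the threshold rule applied downstream
#' (see \code{\link{callDegs}}) is the quantity of interest, not the test
#' machinery.
#'
#' @param x log2-scale \linkS4class{TimecourseExperiment}.
#' @param group group label to contrast.
#' @param reference reference group, default the first of the group order.
#' @return data.frame: \code{gene_id}, \code{group}, \code{log2FC},
#'   \code{p_value}.
#' @export
deTest <- function(x, group, reference = referenceGroup(x)) {
    .requireScale(x, "log2")
    a <- .groupValues(x, group, minReplicates = 2L)
    b <- .groupValues(x, reference, minReplicates = 2L)
    nA <- ncol(a); nB <- ncol(b)
    mA <- rowMeans(a); mB <- rowMeans(b)
    vA <- .rowVars(a); vB <- .rowVars(b)
    lfc <- mA - mB
    se2 <- vA / nA + vB / nB
    tt <- lfc / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
    p <- 2 * pt(-abs(tt), df)
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
    data.frame(gene_id = rownames(a), group = group, log2FC = unname(lfc),
               p_value = unname(p), row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted values (monotone step-up, clipped at 1), original order.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must be numeric in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Apply the DEG threshold rule
#'
#' A gene is a DEG iff \code{fdr < fdrThreshold} AND
#' \code{|log2FC| > lfcThreshold}, both strict, mirroring the screening
#' rule "adjusted p < 0.01 and log2 fold change > 1.2 or < -1.2". The FDR
#' column is computed with \code{\link{bhAdjust}} when absent and reused
#' otherwise, so the call is idempotent.
#'
#' @param records data.frame with \code{log2FC} and \code{p_value} (and
#'   optionally \code{fdr}).
#' @param fdrThreshold default 0.01.
#' @param lfcThreshold default 1.2.
#' @return the records with \code{fdr} and logical \code{is_deg} columns;
#'   attribute \code{summary} holds the up/down counts.
#' @export
callDegs <- function(records, fdrThreshold = 0.01, lfcThreshold = 1.2) {
    stopifnot(all(c("log2FC", "p_value") %in% colnames(records)))
    if (!"fdr" %in% colnames(records))
        records$fdr <- bhAdjust(records$p_value)
    records$is_deg <- records$fdr < fdrThreshold &
        abs(records$log2FC) > lfcThreshold
    attr(records, "summary") <-
        c(up = sum(records$is_deg & records$log2FC > 0),
          down = sum(records$is_deg & records$log2FC < 0))
    records
}

#' Screen every non-reference group for DEGs
#'
#' @param x log2-scale \linkS4class{TimecourseExperiment}.
#' @param groups groups to screen (default all non-reference groups).
#' @param fdrThreshold,lfcThreshold see \code{\link{callDegs}}.
#' @return named list of per-group DEG tables.
#' @export
degScreen <- function(x, groups = setdiff(groupOrder(x),
                                          referenceGroup(x)),
                      fdrThreshold = 0.01, lfcThreshold = 1.2) {
    res <- lapply(groups, function(g)
        callDegs(deTest(x, g), fdrThreshold, lfcThreshold))
    setNames(res, groups)
}

#' Overlap of per-group top-N DEG lists
#'
#' For each table the top \code{n} DEGs by \code{|log2FC|} are taken (ties
#' broken by smaller fdr, then gene id); the overlap across all tables is
#' reported both as \code{over_n} = |intersection| / n (the denominator the
#' published percentages appear to use) and \code{over_union} =
#' |intersection| / |union|. Tables with fewer than \code{n} DEGs trigger a
#' warning and shrink the denominator to the smallest list.
#'
#' @param degTables named list of \code{\link{callDegs}} outputs.
#' @param n list length, default 50.
#' @return list: \code{top} (per-group gene vectors), \code{over_n},
#'   \code{over_union}, \code{n} (effective denominator).
#' @export
topNOverlap <- function(degTables, n = 50) {
    stopifnot(length(degTables) >= 2L)
    top <- lapply(degTables, function(tab) {
        tab <- tab[tab$is_deg, , drop = FALSE]
        if (nrow(tab) < n)
            warning(sprintf("only %d DEGs available (n = %d requested)",
                            nrow(tab), n))
        tab <- tab[order(-abs(tab$log2FC), tab$fdr, tab$gene_id), ]
        head(tab$gene_id, n)
    })
    nEff <- min(n, min(lengths(top)))
    inter <- Reduce(intersect, top)
    uni <- Reduce(union, top)
    list(top = top, over_n = length(inter) / nEff,
         over_union = length(inter) / length(uni), n = nEff)
}

#' qPCR relative quantification by 2^-ddCt
#'
#' Per group, \code{dCt = mean Ct(target) - mean Ct(reference gene)};
#' \code{ddCt = dCt(group) - dCt(reference group)}; fold change =
#' \code{2^-ddCt}. The reference group's fold change is exactly 1.
#'
#' @param targetCt named list: group label -> numeric replicate Ct values
#'   of the target gene.
#' @param referenceCt same structure for the reference (housekeeping) gene,
#'   e.g. Ppia.
#' @param referenceGroup label of the reference condition; defaults to the
#'   first group of \code{targetCt}.
#' @return named numeric vector of fold changes per group.
#' @examples
#' ddctFoldChange(list(sham = c(20, 20, 20), IR18 = c(19, 19, 19)),
#'                list(sham = c(18, 18, 18), IR18 = c(18, 18, 18)))
#' @export
ddctFoldChange <- function(targetCt, referenceCt,
                           referenceGroup = names(targetCt)[1L]) {
    if (!identical(sort(names(targetCt)), sort(names(referenceCt))))
        stop("target and reference-gene Ct tables must cover the same groups")
    if (!referenceGroup %in% names(targetCt))
        stop(sprintf("reference group '%s' missing", referenceGroup))
    ok <- function(v) is.numeric(v) && all(is.finite(v)) && all(v > 0)
    if (!all(vapply(targetCt, ok, logical(1L))) ||
        !all(vapply(referenceCt, ok, logical(1L))))
        stop("Ct values must be finite and > 0")
    groups <- names(targetCt)
    dCt <- vapply(groups, function(g)
        mean(targetCt[[g]]) - mean(referenceCt[[g]]), numeric(1L))
    ddCt <- dCt - dCt[referenceGroup]
    fold <- 2^(-ddCt)
    fold[referenceGroup] <- 1
    fold
}
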