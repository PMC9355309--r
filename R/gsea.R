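# metric values for one contrast from a log2 matrix; used by both the
# observed ranking and phenotype permutations
.rankMetric <- function(a, b, metric) {
    mA <- rowMeans(a); mB <- rowMeans(b)
    if (metric == "log2fc") return(mA - mB)
    sA <- .rowSds(a); sB <- .rowSds(b)
    floorA <- pmax(0.2 * abs(mA), 0.2)   # classic signal-to-noise floor
    floorB <- pmax(0.2 * abs(mB), 0.2)
    (mA - mB) / (pmax(sA, floorA) + pmax(sB, floorB))
}

#' Rank genes for enrichment analysis
#'
#' Signal-to-noise is \code{(meanA - meanB) / (sdA + sdB)} with each SD
#' floored at \code{max(0.2 |mean|, 0.2)} (the classic GSEA convention);
#' \code{log2fc} is the plain difference of log2 means. Genes are sorted by
#' decreasing metric, ties broken by gene id.
#'
#' @param x log2-scale \linkS4class{TimecourseExperiment}.
#' @param groupA,groupB the contrast (positive metric = higher in A).
#' @param metric \code{"signal2noise"} (needs >= 2 replicates per group) or
#'   \code{"log2fc"}.
#' @return data.frame \code{gene_id}, \code{metric}, ordered; attribute
#'   \code{contrast} = c(groupA, groupB).
#' @export
rankGenes <- function(x, groupA, groupB,
                      metric = c("signal2noise", "log2fc")) {
    metric <- match.arg(metric)
    .requireScale(x, "log2")
    minRep <- if (metric == "signal2noise") 2L else 1L
    a <- tryCatch(.groupValues(x, groupA, minRep), error = function(e)
        stop(sprintf("%s; use metric = 'log2fc' for single replicates",
                     conditionMessage(e))))
    b <- tryCatch(.groupValues(x, groupB, minRep), error = function(e)
        stop(sprintf("%s; use metric = 'log2fc' for single replicates",
                     conditionMessage(e))))
    r <- .rankMetric(a, b, metric)
    o <- order(-r, rownames(x))
    out <- data.frame(gene_id = rownames(x)[o], metric = unname(r[o]))
    attr(out, "contrast") <- c(groupA, groupB)
    out
}

# core running-sum computation over an ordered gene vector
.runningSum <- function(genes, metrics, geneSet, p = 1) {
    hits <- genes %in% geneSet
    nHit <- sum(hits)
    N <- length(genes)
    if (nHit == 0L) stop("gene set does not intersect the ranked list")
    if (nHit == N) stop("gene set covers the whole ranked list")
    w <- abs(metrics)^p
    w[!hits] <- 0
    denom <- sum(w)
    if (denom == 0) {          # all hit metrics zero: fall back to p = 0
        w[hits] <- 1
        denom <- nHit
    }
    steps <- ifelse(hits, w / denom, -1 / (N - nHit))
    cumsum(steps)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking the ranked list, set members ("hits") add
#' \code{|r|^p / sum(|r|^p over hits)} and non-members subtract
#' \code{1 / (N - N_hit)}; the enrichment score is the signed maximal
#' deviation of the running sum from zero (first position on ties).
#'
#' @param ranked output of \code{\link{rankGenes}} (or any data.frame with
#'   \code{gene_id} and \code{metric} in rank order).
#' @param geneSet character vector of member gene ids.
#' @param p weight exponent, default 1 (classic GSEA); p = 0 gives the
#'   unweighted KS statistic.
#' @return list: \code{es}, \code{runningSum}, \code{peakIndex}.
#' @export
enrichmentScore <- function(ranked, geneSet, p = 1) {
    rs <- .runningSum(ranked$gene_id, ranked$metric, geneSet, p)
    peak <- which.max(abs(rs))
    list(es = rs[peak], runningSum = rs, peakIndex = peak)
}

#' Null enrichment scores by permutation
#'
#' Phenotype mode permutes the sample-to-group labels of the contrast (all
#' distinct relabelings when there are at most \code{B}, otherwise
#' \code{B} random ones) and recomputes the ranking and score each time;
#' geneset mode scores \code{B} random same-size gene sets against the
#' observed ranking.
#'
#' @param x log2-scale \linkS4class{TimecourseExperiment}.
#' @param groupA,groupB the contrast.
#' @param geneSet the set whose null is wanted.
#' @param B number of permutations, >= 100.
#' @param mode \code{"geneset"} or \code{"phenotype"}.
#' @param metric,p see \code{\link{rankGenes}} / \code{\link{enrichmentScore}}.
#' @param seed integer seed.
#' @return numeric vector of B null enrichment scores.
#' @export
permutationNull <- function(x, groupA, groupB, geneSet, B = 1000L,
                            mode = c("geneset", "phenotype"),
                            metric = "signal2noise", p = 1, seed = 1L) {
    mode <- match.arg(mode)
    if (B < 100L) stop("B must be >= 100")
    set.seed(as.integer(seed))
    if (mode == "geneset") {
        ranked <- rankGenes(x, groupA, groupB, metric)
        k <- sum(ranked$gene_id %in% geneSet)
        if (k == 0L) stop("gene set does not intersect the ranked list")
        vapply(seq_len(B), function(i) {
            enrichmentScore(ranked,
                            sample(ranked$gene_id, k), p)$es
        }, numeric(1L))
    } else {
        sa <- groupSamples(x, groupA)
        sb <- groupSamples(x, groupB)
        if (length(sa) < 2L || length(sb) < 2L)
            stop("phenotype mode needs >= 2 replicates per group")
        vals <- .activeValues(x)[, c(sa, sb), drop = FALSE]
        nA <- length(sa); nTot <- nA + length(sb)
        if (choose(nTot, nA) <= B) {
            idxA <- combn(nTot, nA, simplify = FALSE)
        } else {
            idxA <- lapply(seq_len(B), function(i) sample.int(nTot, nA))
        }
        vapply(idxA, function(ia) {
            a <- vals[, ia, drop = FALSE]
            b <- vals[, -ia, drop = FALSE]
            r <- .rankMetric(a, b, metric)
            o <- order(-r, rownames(vals))
            es <- enrichmentScore(
                data.frame(gene_id = rownames(vals)[o],
                           metric = unname(r[o])), geneSet, p)
            es$es
        }, numeric(1L))
    }
}

# one-sided permutation p-value on the matching sign side
.nominalP <- function(es, nulls) {
    if (es == 0) return(1)
    side <- nulls[sign(nulls) == sign(es)]
    (1 + sum(abs(side) >= abs(es))) / (1 + length(side))
}

# NES = ES scaled by the mean same-sign null magnitude
.nes <- function(es, nulls) {
    if (es == 0) return(0)
    side <- nulls[if (es > 0) nulls > 0 else nulls < 0]
    if (!length(side)) return(NA_real_)
    es / abs(mean(side))
}

#' Leading-edge subset of a gene set
#'
#' For a positive score: set members at ranks up to and including the
#' running-sum peak; for a negative score: members at ranks at or after the
#' peak. Rank order is preserved.
#'
#' @param ranked the ranked list used for scoring.
#' @param geneSet the gene set.
#' @param es,peakIndex from \code{\link{enrichmentScore}}.
#' @return character vector (empty, with a warning, when es = 0).
#' @export
leadingEdge <- function(ranked, geneSet, es, peakIndex) {
    if (es == 0) {
        warning("enrichment score is 0; leading edge undefined")
        return(character())
    }
    genes <- ranked$gene_id
    idx <- if (es > 0) seq_len(peakIndex)
           else seq(peakIndex, length(genes))
    genes[idx][genes[idx] %in% geneSet]
}

#' Run gene-set enrichment for a contrast
#'
#' Scores every set, builds its permutation null, derives the one-sided
#' nominal p, the normalized enrichment score (ES divided by the mean
#' same-sign null), Benjamini-Hochberg adjusted p across all tested sets
#' (significant at adjusted p < 0.05), and the leading-edge genes. Sets
#' that do not intersect the ranked list are skipped with a warning. The
#' default permutation mode follows standard GSEA guidance: phenotype
#' permutation when both groups have >= 7 replicates, geneset permutation
#' otherwise (small time-course designs force the latter).
#'
#' @param x log2-scale \linkS4class{TimecourseExperiment}.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param groupA,groupB the contrast.
#' @param metric,p,B,seed see the stage functions.
#' @param mode permutation mode; NULL picks the default above.
#' @return a \linkS4class{GseaResult}
#' @export
runGsea <- function(x, sets, groupA, groupB, metric = "signal2noise",
                    p = 1, B = 1000L, mode = NULL, seed = 1L) {
    stopifnot(is(sets, "GeneSetCollection"))
    if (is.null(mode)) {
        mode <- if (length(groupSamples(x, groupA)) >= 7L &&
                    length(groupSamples(x, groupB)) >= 7L)
            "phenotype" else "geneset"
    }
    ranked <- rankGenes(x, groupA, groupB, metric)
    keep <- vapply(names(sets), function(nm)
        any(ranked$gene_id %in% sets[[nm]]) &&
            !all(ranked$gene_id %in% sets[[nm]]), logical(1L))
    if (any(!keep))
        warning(sprintf("skipping %d set(s) with empty or full overlap",
                        sum(!keep)))
    nms <- names(sets)[keep]
    rows <- vector("list", length(nms))
    rsums <- list()
    ledges <- list()
    for (i in seq_along(nms)) {
        nm <- nms[i]
        esr <- enrichmentScore(ranked, sets[[nm]], p)
        nulls <- permutationNull(x, groupA, groupB, sets[[nm]], B = B,
                                 mode = mode, metric = metric, p = p,
                                 seed = .childSeed(seed, i))
        le <- if (esr$es == 0) character()
              else leadingEdge(ranked, sets[[nm]], esr$es, esr$peakIndex)
        rows[[i]] <- data.frame(
            set = nm,
            size = sum(ranked$gene_id %in% sets[[nm]]),
            es = esr$es, nes = .nes(esr$es, nulls),
            nominal_p = .nominalP(esr$es, nulls),
            peak_index = esr$peakIndex,
            leading_edge = paste(le, collapse = ";"))
        rsums[[nm]] <- esr$runningSum
        ledges[[nm]] <- le
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab)) tab <- data.frame()
    if (nrow(tab)) {
        tab$adjusted_p <- bhAdjust(tab$nominal_p)
        tab$significant <- tab$adjusted_p < 0.05
        tab <- tab[, c("set", "size", "es", "nes", "nominal_p",
                       "adjusted_p", "significant", "peak_index",
                       "leading_edge")]
    }
    new("GseaResult", table = tab, runningSums = rsums,
        leadingEdge = ledges, contrast = c(groupA, groupB), mode = mode,
        nPermutations = as.integer(B))
}

#' Key-gene screen on leading-edge genes
#'
#' A gene passes when its absolute log2 fold changes in the mild and severe
#' contrast groups satisfy (|mild| > 0.7 AND |severe| > 1) OR (|mild| > 1
#' AND |severe| > 0.7) — the limit-fold-change rule applied to leading-edge
#' subsets, read on absolute values since validated genes include
#' downregulated ones.
#'
#' @param genes character vector (e.g. a leading edge).
#' @param lfcMild named numeric: log2 fold change in the mild group.
#' @param lfcSevere named numeric: log2 fold change in the severe group.
#' @param lower,upper the two thresholds, defaults 0.7 and 1.
#' @return data.frame \code{gene_id}, \code{lfc_mild}, \code{lfc_severe},
#'   \code{passes}, sorted by \code{max(|mild|, |severe|)} descending.
#' @export
keyGeneScreen <- function(genes, lfcMild, lfcSevere, lower = 0.7,
                          upper = 1) {
    have <- genes %in% names(lfcMild) & genes %in% names(lfcSevere)
    if (any(!have))
        warning(sprintf("%d gene(s) without fold changes skipped",
                        sum(!have)))
    g <- genes[have]
    am <- abs(lfcMild[g]); as_ <- abs(lfcSevere[g])
    out <- data.frame(gene_id = g, lfc_mild = unname(lfcMild[g]),
                      lfc_severe = unname(lfcSevere[g]),
                      passes = unname((am > lower & as_ > upper) |
                                      (am > upper & as_ > lower)))
    out[order(-pmax(am, as_)), , drop = FALSE]
}
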