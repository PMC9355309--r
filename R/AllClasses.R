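#' tipDNB: tipping-point detection in ordered-condition expression time
#' courses via dynamic network biomarkers
#'
#' The package takes a gene-by-sample expression matrix whose samples fall
#' into ordered condition groups (the first group is the reference, e.g. a
#' sham operation, the later groups increasing severities of an insult) and
#' locates the condition at which the transcriptome is about to shift state.
#' The core statistic is the dynamic network biomarker (DNB) composite index
#' CI = mean_SD * PCC1 / PCC0, computed per group from a cluster of
#' high-variance, strongly inter-correlated genes; the group at which CI
#' peaks is the candidate tipping point. Supporting stages implement a
#' threshold-based differential-expression screen, fuzzy c-means clustering
#' of standardized temporal profiles, gene-set enrichment with permutation
#' nulls and leading-edge key-gene screening, and a synthetic-data generator
#' whose planted structure makes every stage testable.
#'
#' @import methods
#' @importFrom stats cor cutree dist hclust p.adjust pt rnbinom rnorm runif
#'   sd var setNames
#' @importFrom utils head read.delim write.table combn packageVersion
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames colData rowData
#' @include AllGenerics.R
#' @name tipDNB-package
"_PACKAGE"

#' TimecourseExperiment: expression matrix with an ordered group design
#'
#' Extends \linkS4class{SummarizedExperiment}. The assay is either a raw
#' count matrix (assay \code{"counts"}, scale \code{"counts"}) or a log2
#' matrix (assay \code{"logcpm"}, scale \code{"log2"});
#' \code{\link{normalizeLogCpm}} produces an object carrying both.
#' \code{colData(x)$group} maps every sample to a group label and
#' \code{metadata(x)$groupOrder} fixes the condition order; its first
#' element is the reference group by definition.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @aliases TimecourseExperiment-class
#' @exportClass TimecourseExperiment
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
    msg <- character()
    gi <- rownames(object)
    si <- colnames(object)
    if (is.null(gi) || any(gi == "") || anyNA(gi))
        msg <- c(msg, "gene ids must be non-empty strings")
    if (anyDuplicated(gi))
        msg <- c(msg, sprintf("duplicate gene id: '%s'",
                              gi[duplicated(gi)][1L]))
    if (is.null(si) || any(si == "") || anyNA(si))
        msg <- c(msg, "sample ids must be non-empty strings")
    if (anyDuplicated(si))
        msg <- c(msg, sprintf("duplicate sample id: '%s'",
                              si[duplicated(si)][1L]))
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    go <- metadata(object)$groupOrder
    sc <- metadata(object)$assayScale
    if (is.null(go) || !is.character(go) || length(go) < 2L ||
        anyDuplicated(go)) {
        msg <- c(msg, "metadata$groupOrder must list >= 2 distinct groups")
    } else if ("group" %in% colnames(colData(object))) {
        grp <- as.character(colData(object)$group)
        if (!all(grp %in% go))
            msg <- c(msg, sprintf("sample group '%s' not in groupOrder",
                                  setdiff(grp, go)[1L]))
        if (!all(go %in% grp))
            msg <- c(msg, sprintf("group '%s' in groupOrder has no samples",
                                  setdiff(go, grp)[1L]))
    }
    if (is.null(sc) || !sc %in% c("counts", "log2")) {
        msg <- c(msg, "metadata$assayScale must be 'counts' or 'log2'")
    } else if (length(assays(object)) > 0L) {
        v <- assay(object, if (sc == "counts") "counts" else "logcpm")
        if (!all(is.finite(v)))
            msg <- c(msg, "expression values must be finite")
        else if (sc == "counts" && any(v < 0))
            msg <- c(msg, "counts must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TimecourseExperiment
#'
#' @param values numeric gene x sample matrix with row and column names.
#' @param design data.frame with columns \code{sample_id} and \code{group}
#'   (one row per sample), or a named character vector sample -> group.
#' @param groupOrder character vector of group labels in condition order,
#'   reference first. Defaults to order of first appearance in the design.
#' @param scale \code{"counts"} (non-negative raw counts) or \code{"log2"}.
#' @return a \linkS4class{TimecourseExperiment}
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample_id = paste0("s", 1:4),
#'                 group = rep(c("sham", "IR22"), each = 2))
#' TimecourseExperiment(m, d)
#' @export
TimecourseExperiment <- function(values, design, groupOrder = NULL,
                                 scale = c("counts", "log2")) {
    scale <- match.arg(scale)
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.data.frame(design)) {
        if (!all(c("sample_id", "group") %in% colnames(design)))
            stop("design must have columns 'sample_id' and 'group'")
        s2g <- setNames(as.character(design$group),
                        as.character(design$sample_id))
    } else if (is.character(design) && !is.null(names(design))) {
        s2g <- design
    } else stop("design must be a data.frame or named character vector")
    if (anyDuplicated(names(s2g)))
        stop(sprintf("duplicate sample id in design: '%s'",
                     names(s2g)[duplicated(names(s2g))][1L]))
    missing <- setdiff(colnames(values), names(s2g))
    if (length(missing))
        stop(sprintf("sample '%s' missing from design", missing[1L]))
    s2g <- s2g[colnames(values)]
    if (is.null(groupOrder)) groupOrder <- unique(unname(s2g))
    an <- if (scale == "counts") "counts" else "logcpm"
    se <- SummarizedExperiment(
        assays = setNames(list(values), an),
        colData = DataFrame(group = unname(s2g), row.names = names(s2g)))
    metadata(se)$groupOrder <- groupOrder
    metadata(se)$assayScale <- scale
    new("TimecourseExperiment", se)
}

#' @describeIn TimecourseExperiment ordered group labels, reference first
#' @param x a TimecourseExperiment
#' @export
setMethod("groupOrder", "TimecourseExperiment",
          function(x) metadata(x)$groupOrder)

#' @describeIn TimecourseExperiment the reference group (first of the order)
#' @export
setMethod("referenceGroup", "TimecourseExperiment",
          function(x) metadata(x)$groupOrder[1L])

#' @describeIn TimecourseExperiment \code{"counts"} or \code{"log2"}
#' @export
setMethod("assayScale", "TimecourseExperiment",
          function(x) metadata(x)$assayScale)

#' @describeIn TimecourseExperiment named vector sample id -> group label
#' @export
setMethod("sampleGroups", "TimecourseExperiment", function(x)
    setNames(as.character(colData(x)$group), colnames(x)))

#' @describeIn TimecourseExperiment sample ids belonging to one group
#' @param group a group label
#' @export
setMethod("groupSamples", "TimecourseExperiment", function(x, group) {
    if (!group %in% groupOrder(x))
        stop(sprintf("unknown group '%s'", group))
    colnames(x)[as.character(colData(x)$group) == group]
})

setMethod("show", "TimecourseExperiment", function(object) {
    callNextMethod()
    cat("groupOrder:", paste(groupOrder(object), collapse = " < "), "\n")
    cat("assayScale:", assayScale(object), "\n")
})

#' GeneSetCollection: named gene sets (GMT-style)
#'
#' @slot sets named list of character vectors (unique genes per set).
#' @slot descriptions named character vector, one per set.
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (length(object@sets)) {
        if (is.null(nm) || any(nm == "")) msg <- c(msg, "sets must be named")
        if (anyDuplicated(nm))
            msg <- c(msg, sprintf("duplicate set name: '%s'",
                                  nm[duplicated(nm)][1L]))
        for (i in seq_along(object@sets)) {
            s <- object@sets[[i]]
            if (!is.character(s) || length(s) == 0L) {
                msg <- c(msg, sprintf("set '%s' is empty", nm[i]))
            } else if (anyDuplicated(s)) {
                msg <- c(msg, sprintf("duplicate gene in set '%s'", nm[i]))
            }
        }
        if (!identical(sort(names(object@descriptions)), sort(nm)))
            msg <- c(msg, "descriptions must be named like the sets")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional named character vector of descriptions.
#' @return a \linkS4class{GeneSetCollection}
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions[names(sets)])
}

#' @describeIn GeneSetCollection the named list of gene-id vectors
#' @param x a GeneSetCollection
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection the per-set description strings
#' @export
setMethod("setDescriptions", "GeneSetCollection",
          function(x) x@descriptions)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @param i set name or index
#' @rdname GeneSetCollection-class
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection with %d sets (sizes %s)\n",
                length(object@sets),
                if (length(object@sets))
                    paste(range(lengths(object@sets)), collapse = "-")
                else "-"))
})

#' FuzzyClustering: soft partition of temporal profiles
#'
#' Result of \code{\link{fuzzyCMeans}}: the fuzzifier \code{m}, the
#' \code{c x groups} centroid matrix, the \code{gene x c} membership matrix
#' (rows sum to 1), the per-iteration objective trace (non-increasing), and
#' the convergence state.
#'
#' @slot centers centroid matrix (clusters x groups)
#' @slot membership membership matrix (genes x clusters)
#' @slot m fuzzifier (> 1)
#' @slot objective numeric, objective value per iteration
#' @slot iterations integer, iterations used
#' @slot converged logical
#' @aliases FuzzyClustering-class
#' @exportClass FuzzyClustering
setClass("FuzzyClustering",
         representation(centers = "matrix", membership = "matrix",
                        m = "numeric", objective = "numeric",
                        iterations = "integer", converged = "logical"))

setValidity("FuzzyClustering", function(object) {
    msg <- character()
    if (nrow(object@centers) != ncol(object@membership))
        msg <- c(msg, "centers rows must match membership columns")
    rs <- rowSums(object@membership)
    if (length(rs) && max(abs(rs - 1)) > 1e-9)
        msg <- c(msg, "membership rows must sum to 1")
    if (any(!is.finite(object@objective)))
        msg <- c(msg, "objective must be finite")
    if (object@m <= 1) msg <- c(msg, "fuzzifier m must be > 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn FuzzyClustering gene x cluster membership matrix
#' @param x a FuzzyClustering
#' @export
setMethod("membershipMatrix", "FuzzyClustering", function(x) x@membership)

#' @describeIn FuzzyClustering cluster x group centroid matrix
#' @export
setMethod("clusterCenters", "FuzzyClustering", function(x) x@centers)

#' @describeIn FuzzyClustering objective value at each iteration
#' @export
setMethod("objectiveTrace", "FuzzyClustering", function(x) x@objective)

setMethod("show", "FuzzyClustering", function(object) {
    cat(sprintf(paste0("FuzzyClustering: %d genes, %d clusters, m = %g\n",
                       "objective %.6g after %d iterations (%s)\n"),
                nrow(object@membership), nrow(object@centers), object@m,
                object@objective[length(object@objective)],
                object@iterations,
                if (object@converged) "converged" else "NOT converged"))
})

#' GseaResult: gene-set enrichment results for one contrast
#'
#' @slot table data.frame with one row per tested set: \code{set},
#'   \code{size}, \code{es}, \code{nes}, \code{nominal_p},
#'   \code{adjusted_p}, \code{significant}, \code{peak_index},
#'   \code{leading_edge} (semicolon-joined).
#' @slot runningSums named list of per-position running-sum vectors.
#' @slot leadingEdge named list of leading-edge gene vectors.
#' @slot contrast character(2), groups A and B of the ranking.
#' @slot mode permutation mode used ("phenotype" or "geneset").
#' @slot nPermutations integer
#' @aliases GseaResult-class
#' @exportClass GseaResult
setClass("GseaResult",
         representation(table = "data.frame", runningSums = "list",
                        leadingEdge = "list", contrast = "character",
                        mode = "character", nPermutations = "integer"))

#' @describeIn GseaResult the per-set result table
#' @param x a GseaResult
#' @export
setMethod("gseaTable", "GseaResult", function(x) x@table)

#' @describeIn GseaResult named list of running-sum vectors
#' @export
setMethod("runningSums", "GseaResult", function(x) x@runningSums)

#' @describeIn GseaResult named list of leading-edge gene vectors
#' @export
setMethod("leadingEdges", "GseaResult", function(x) x@leadingEdge)

setMethod("show", "GseaResult", function(object) {
    cat(sprintf("GseaResult: %s vs %s, %d sets, %d %s permutations\n",
                object@contrast[1L], object@contrast[2L],
                nrow(object@table), object@nPermutations, object@mode))
    print(head(object@table[, c("set", "size", "es", "nes",
                                "nominal_p", "adjusted_p")], 8L))
})

#' DnbResult: dynamic network biomarker analysis of all groups
#'
#' One row per evaluated group in \code{dnbTable}: the number of selected
#' high-deviation genes, and for the best correlation cluster its mean
#' within-group SD, mean intra-cluster |PCC| (pcc1), mean cluster-to-rest
#' |PCC| (pcc0) and composite index CI = mean_SD * pcc1 / pcc0 (NA when the
#' group yields no usable cluster). \code{tippingPoint} returns the arg-max
#' CI group.
#'
#' @slot groupTable data.frame: group, selected_gene_number, cluster_size,
#'   mean_SD, pcc1, pcc0, CI
#' @slot candidates named list (per group) of per-cluster stats
#' @slot bestClusters named list of best-cluster gene vectors
#' @slot edges named list of per-group edge-list data.frames
#' @slot selected named list of per-group selected-gene data.frames
#' @slot params list of the parameters used
#' @aliases DnbResult-class
#' @exportClass DnbResult
setClass("DnbResult",
         representation(groupTable = "data.frame", candidates = "list",
                        bestClusters = "list", edges = "list",
                        selected = "list", params = "list"))

#' @describeIn DnbResult the per-group composite-index table
#' @param x a DnbResult
#' @export
setMethod("dnbTable", "DnbResult", function(x) x@groupTable)

#' @describeIn DnbResult named list of best-cluster gene vectors
#' @export
setMethod("bestClusters", "DnbResult", function(x) x@bestClusters)

#' @describeIn DnbResult named list of per-group edge lists
#'   (gene_a, gene_b, pcc)
#' @export
setMethod("dnbEdges", "DnbResult", function(x) x@edges)

setMethod("show", "DnbResult", function(object) {
    cat("DnbResult over groups:",
        paste(object@groupTable$group, collapse = ", "), "\n")
    print(object@groupTable)
    tp <- tippingPoint(object)
    cat("tipping point:",
        if (is.na(tp$group)) "none detected" else tp$group, "\n")
})
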