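#' Read an expression matrix TSV plus its sample design
#'
#' The matrix file is tab-delimited with a header of sample ids and gene ids
#' in the first column (header \code{gene_id}). The design file has columns
#' \code{sample_id} and \code{group}; the condition order may be given as a
#' comment line \code{# group_order: g1,g2,...} at its top (reference group
#' first), via the \code{groupOrder} argument, or defaults to order of first
#' appearance. Gene identifiers are matched case-sensitively throughout the
#' package.
#'
#' @param path path to the expression TSV.
#' @param designPath path to the design TSV.
#' @param groupOrder optional character vector overriding the group order.
#' @param scale \code{"counts"} or \code{"log2"}.
#' @return a \linkS4class{TimecourseExperiment}; gene and sample order are
#'   preserved from the file.
#' @export
readExpressionTsv <- function(path, designPath, groupOrder = NULL,
                              scale = c("counts", "log2")) {
    scale <- match.arg(scale)
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character",
                      comment.char = "")
    if (ncol(tab) < 2L) stop("expression TSV needs gene ids plus >= 1 sample")
    gid <- tab[[1L]]
    if (anyDuplicated(gid))
        stop(sprintf("duplicate gene id '%s' in %s",
                     gid[duplicated(gid)][1L], path))
    sid <- colnames(tab)[-1L]
    if (anyDuplicated(sid))
        stop(sprintf("duplicate sample id '%s' in %s",
                     sid[duplicated(sid)][1L], path))
    vals <- matrix(NA_real_, nrow(tab), length(sid),
                   dimnames = list(gid, sid))
    for (j in seq_along(sid)) {
        v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
        bad <- which(is.na(v) & !is.na(tab[[j + 1L]]))
        if (length(bad))
            stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                         bad[1L], sid[j], tab[bad[1L], j + 1L]))
        vals[, j] <- v
    }
    design <- readDesignTsv(designPath)
    if (is.null(groupOrder))
        groupOrder <- attr(design, "groupOrder")
    TimecourseExperiment(vals, design, groupOrder = groupOrder,
                         scale = scale)
}

#' Read a sample-design TSV
#'
#' @param path TSV with columns \code{sample_id} and \code{group}; an
#'   optional leading comment \code{# group_order: a,b,c} fixes the order.
#' @return data.frame with attribute \code{groupOrder} (or NULL).
#' @export
readDesignTsv <- function(path) {
    lines <- readLines(path)
    go <- NULL
    hdr <- grep("^#", lines, value = TRUE)
    m <- regmatches(hdr, regexpr("group_order:\\s*\\S.*$", hdr))
    if (length(m))
        go <- trimws(strsplit(sub("group_order:\\s*", "", m[1L]), ",")[[1L]])
    d <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                    colClasses = "character")
    if (!all(c("sample_id", "group") %in% colnames(d)))
        stop(sprintf("design %s must have columns sample_id and group", path))
    attr(d, "groupOrder") <- go
    d
}

#' Write an expression matrix (and its design) as TSV
#'
#' Values are written at 17 significant digits so a read/write round trip is
#' value-identical; the first column header is \code{gene_id}.
#'
#' @param x a \linkS4class{TimecourseExperiment}.
#' @param path output path for the matrix TSV.
#' @param designPath optional path to also write the design TSV (with a
#'   \code{# group_order:} comment).
#' @return invisibly, \code{path}.
#' @export
writeExpressionTsv <- function(x, path, designPath = NULL) {
    stopifnot(is(x, "TimecourseExperiment"))
    v <- .activeValues(x)
    if (nrow(v) == 0L) stop("refusing to write a matrix with no genes")
    body <- apply(v, 2L, function(col) formatC(col, digits = 17,
                                               format = "g"))
    body <- matrix(trimws(body), nrow = nrow(v))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
    writeLines(paste(rownames(v),
                     apply(body, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
    if (!is.null(designPath)) {
        dcon <- file(designPath, "w")
        writeLines(c(paste0("# group_order: ",
                            paste(groupOrder(x), collapse = ",")),
                     "sample_id\tgroup",
                     paste(colnames(v), sampleGroups(x)[colnames(v)],
                           sep = "\t")), dcon)
        close(dcon)
    }
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' Broad dialect: one set per line, \code{name TAB description TAB gene TAB
#' gene ...}. Duplicate genes within a line are dropped with a warning;
#' duplicate set names or lines with fewer than three fields are errors.
#'
#' @param path path to the GMT file.
#' @return a \linkS4class{GeneSetCollection}
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has %d field(s); >= 3 required",
                         i, length(f)))
        nm <- f[1L]
        if (nm %in% names(sets))
            stop(sprintf("duplicate set name '%s' at GMT line %d", nm, i))
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes)) {
            warning(sprintf("set '%s': duplicate genes dropped", nm))
            genes <- unique(genes)
        }
        sets[[nm]] <- genes
        desc[nm] <- f[2L]
    }
    GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection as GMT
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(x, path) {
    stopifnot(is(x, "GeneSetCollection"))
    d <- setDescriptions(x)
    lines <- vapply(names(x), function(nm)
        paste(c(nm, if (nzchar(d[[nm]])) d[[nm]] else "na", x[[nm]]),
              collapse = "\t"), character(1L))
    writeLines(lines, path)
    invisible(path)
}
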