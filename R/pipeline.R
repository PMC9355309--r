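# schema of the run configuration: defaults plus a validator per key.
# unknown keys anywhere are hard errors (no silent typo tolerance).
.configSchema <- function() {
    num <- function(lo, hi, open = FALSE) function(v, key) {
        if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
            (open && (v <= lo || v >= hi)) ||
            (!open && (v < lo || v > hi)))
            stop(sprintf("config key '%s' must be in %s%g, %g%s", key,
                         if (open) "(" else "[", lo, hi,
                         if (open) ")" else "]"))
        v
    }
    flag <- function(v, key) {
        if (!is.logical(v) || length(v) != 1L || is.na(v))
            stop(sprintf("config key '%s' must be TRUE/FALSE", key))
        v
    }
    chr <- function(n = 1L) function(v, key) {
        if (!is.character(v) || length(v) != n)
            stop(sprintf("config key '%s' must be character(%d)", key, n))
        v
    }
    list(
        matrix = list(default = NULL, check = chr()),
        design = list(default = NULL, check = chr()),
        sets = list(default = NULL, check = chr()),
        out_dir = list(default = "tipdnb_out", check = chr()),
        seed = list(default = 1, check = num(0, 2^31 - 1)),
        log_level = list(default = "info", check = function(v, key) {
            if (!v %in% c("debug", "info"))
                stop(sprintf("config key '%s' must be debug or info", key))
            v
        }),
        stages = list(default = list(deg = TRUE, cluster = TRUE,
                                     gsea = TRUE, dnb = TRUE),
                      fields = list(deg = flag, cluster = flag,
                                    gsea = flag, dnb = flag)),
        deg = list(default = list(fdr_threshold = 0.01,
                                  lfc_threshold = 1.2, pseudocount = 0.5,
                                  top_n = 50),
                   fields = list(fdr_threshold = num(0, 1, open = TRUE),
                                 lfc_threshold = num(0, Inf),
                                 pseudocount = num(1e-12, Inf),
                                 top_n = num(1, Inf))),
        cluster = list(default = list(c = 8, m = 1.25, tol = 1e-6,
                                      max_iter = 500),
                       fields = list(c = num(2, Inf), m = num(1, 10,
                                                              open = TRUE),
                                     tol = num(0, 1, open = TRUE),
                                     max_iter = num(1, Inf))),
        gsea = list(default = list(contrast = c("IR30", "IR18"),
                                   metric = "signal2noise",
                                   permutations = 1000, weight = 1),
                    fields = list(contrast = chr(2L),
                                  metric = function(v, key) {
                                      if (!v %in% c("signal2noise",
                                                    "log2fc"))
                                          stop(sprintf(
                                              "config key '%s' invalid",
                                              key))
                                      v
                                  },
                                  permutations = num(100, Inf),
                                  weight = num(0, 2))),
        dnb = list(default = list(sd_fold = 2, pcc_threshold = 0.9,
                                  min_cluster_size = 5,
                                  min_expressed_fraction = 0.5),
                   fields = list(sd_fold = num(1e-6, Inf),
                                 pcc_threshold = num(0, 1, open = TRUE),
                                 min_cluster_size = num(2, Inf),
                                 min_expressed_fraction = num(0, 1))))
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML path or a nested list, checks every key against the
#' schema (types and ranges), rejects unknown keys outright, and fills in
#' defaults. Referenced input paths must exist.
#'
#' @param config path to a YAML file, or a list.
#' @return the completed configuration (class \code{tipDNBConfig}).
#' @export
validateConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML path")
    schema <- .configSchema()
    unknown <- setdiff(names(config), names(schema))
    if (length(unknown))
        stop(sprintf("unknown config key '%s'", unknown[1L]))
    out <- list()
    for (key in names(schema)) {
        spec <- schema[[key]]
        if (!is.null(spec$fields)) {
            sub <- if (key %in% names(config)) config[[key]] else list()
            bad <- setdiff(names(sub), names(spec$fields))
            if (length(bad))
                stop(sprintf("unknown config key '%s.%s'", key, bad[1L]))
            out[[key]] <- spec$default
            for (f in names(sub))
                out[[key]][[f]] <- spec$fields[[f]](sub[[f]],
                                                    paste(key, f,
                                                          sep = "."))
        } else if (key %in% names(config) && !is.null(config[[key]])) {
            out[[key]] <- spec$check(config[[key]], key)
        } else {
            out[[key]] <- spec$default
        }
    }
    for (key in c("matrix", "design", "sets")) {
        if (!is.null(out[[key]]) && !file.exists(out[[key]]))
            stop(sprintf("config key '%s': file '%s' does not exist",
                         key, out[[key]]))
    }
    if (is.null(out$matrix) || is.null(out$design))
        stop("config keys 'matrix' and 'design' are required")
    class(out) <- "tipDNBConfig"
    out
}

.writeTsv <- function(d, path)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order and as toggled: DEG screen, temporal soft
#' clustering, GSEA and DNB analysis, materializing every intermediate as
#' TSV/JSON under \code{out_dir} and recording a manifest (package
#' version, parameters, seed, input checksums, per-stage wall times,
#' skipped stages). Stage seeds derive deterministically from the global
#' seed, so identical configurations yield identical outputs.
#'
#' @param config a \code{\link{validateConfig}} result, list, or YAML path.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "tipDNBConfig")) config <- validateConfig(config)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(config$seed)
    x <- readExpressionTsv(config$matrix, config$design, scale = "counts")
    xl <- normalizeLogCpm(x, config$deg$pseudocount)
    sets <- if (!is.null(config$sets)) readGmt(config$sets) else NULL
    manifest <- list(
        package = "tipDNB",
        version = as.character(packageVersion("tipDNB")),
        seed = seed,
        parameters = unclass(config),
        inputs = as.list(tools::md5sum(unlist(
            config[c("matrix", "design", "sets")], use.names = TRUE))),
        stages = list())
    results <- list()
    timeIt <- function(name, fun) {
        t0 <- proc.time()[["elapsed"]]
        r <- fun()
        manifest$stages[[name]] <<- list(
            status = "completed",
            seconds = round(proc.time()[["elapsed"]] - t0, 3))
        r
    }

    if (isTRUE(config$stages$deg)) {
        results$deg <- timeIt("deg", function() {
            d <- file.path(config$out_dir, "deg")
            dir.create(d, showWarnings = FALSE)
            tabs <- degScreen(xl,
                              fdrThreshold = config$deg$fdr_threshold,
                              lfcThreshold = config$deg$lfc_threshold)
            for (g in names(tabs))
                .writeTsv(tabs[[g]], file.path(d, paste0(g, ".tsv")))
            summ <- lapply(tabs, function(t) as.list(attr(t, "summary")))
            ov <- tryCatch(
                suppressWarnings(topNOverlap(tabs, config$deg$top_n)),
                error = function(e) NULL)
            jsonlite::write_json(
                list(counts = summ,
                     top_n_overlap = if (is.null(ov)) NULL else
                         ov[c("over_n", "over_union", "n")]),
                file.path(d, "summary.json"), auto_unbox = TRUE,
                digits = NA)
            tabs
        })
    } else manifest$stages$deg <- list(status = "skipped")

    if (isTRUE(config$stages$cluster)) {
        results$cluster <- timeIt("cluster", function() {
            d <- file.path(config$out_dir, "clusters")
            dir.create(d, showWarnings = FALSE)
            prof <- standardizeProfiles(xl)
            fc <- fuzzyCMeans(prof, c = config$cluster$c,
                              m = config$cluster$m,
                              tol = config$cluster$tol,
                              maxIter = config$cluster$max_iter,
                              seed = .childSeed(seed, 2L))
            memb <- data.frame(gene_id = rownames(prof),
                               membershipMatrix(fc),
                               check.names = FALSE)
            .writeTsv(memb, file.path(d, "membership.tsv"))
            cent <- data.frame(cluster = rownames(clusterCenters(fc)),
                               clusterCenters(fc), check.names = FALSE)
            .writeTsv(cent, file.path(d, "centroids.tsv"))
            asg <- assignClusters(fc)
            .writeTsv(data.frame(gene_id = names(asg), cluster = asg),
                      file.path(d, "assignments.tsv"))
            shapes <- apply(clusterCenters(fc), 1L, labelClusterShape)
            jsonlite::write_json(as.list(shapes),
                                 file.path(d, "shapes.json"),
                                 auto_unbox = TRUE)
            fc
        })
    } else manifest$stages$cluster <- list(status = "skipped")

    if (isTRUE(config$stages$gsea) && !is.null(sets)) {
        results$gsea <- timeIt("gsea", function() {
            d <- file.path(config$out_dir, "gsea")
            dir.create(d, showWarnings = FALSE)
            ct <- config$gsea$contrast
            gr <- runGsea(xl, sets, ct[1L], ct[2L],
                          metric = config$gsea$metric,
                          p = config$gsea$weight,
                          B = config$gsea$permutations,
                          seed = .childSeed(seed, 3L))
            .writeTsv(gseaTable(gr), file.path(d, "results.tsv"))
            for (nm in names(runningSums(gr)))
                .writeTsv(data.frame(position =
                                         seq_along(runningSums(gr)[[nm]]),
                                     running_sum = runningSums(gr)[[nm]]),
                          file.path(d, paste0("running_sum_", nm,
                                              ".tsv")))
            gr
        })
    } else manifest$stages$gsea <-
        list(status = if (is.null(sets)) "skipped (no gene sets)"
             else "skipped")

    if (isTRUE(config$stages$dnb)) {
        results$dnb <- timeIt("dnb", function() {
            d <- file.path(config$out_dir, "dnb")
            dir.create(d, showWarnings = FALSE)
            dr <- runDnb(xl, sdFold = config$dnb$sd_fold,
                         pccThreshold = config$dnb$pcc_threshold,
                         minClusterSize = config$dnb$min_cluster_size,
                         minExpressedFraction =
                             config$dnb$min_expressed_fraction)
            .writeTsv(dnbTable(dr), file.path(d, "group_table.tsv"))
            for (g in names(bestClusters(dr))) {
                bc <- bestClusters(dr)[[g]]
                if (length(bc))
                    writeLines(bc, file.path(d, paste0("best_cluster_",
                                                       g, ".txt")))
                .writeTsv(dnbEdges(dr)[[g]],
                          file.path(d, paste0("edges_", g, ".tsv")))
            }
            tp <- suppressWarnings(suppressMessages(tippingPoint(dr)))
            jsonlite::write_json(list(tipping_group = tp$group,
                                      ci = tp$ci, table = tp$table),
                                 file.path(d, "tipping.json"),
                                 auto_unbox = TRUE, digits = NA)
            dr
        })
    } else manifest$stages$dnb <- list(status = "skipped")

    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(results, list(manifest = manifest)))
}
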