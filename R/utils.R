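# internal helpers shared across stages

# active expression values: logcpm when scale is log2, counts otherwise
.activeValues <- function(x) {
    stopifnot(is(x, "TimecourseExperiment"))
    assay(x, if (assayScale(x) == "log2") "logcpm" else "counts")
}

# row-wise sample variance (denominator n - 1); n == 1 -> 0
.rowVars <- function(m) {
    n <- ncol(m)
    if (n < 2L) return(setNames(rep(0, nrow(m)), rownames(m)))
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (n - 1L)
}

.rowSds <- function(m) sqrt(.rowVars(m))

# columns of the active assay for one group, with a replicate check
.groupValues <- function(x, group, minReplicates = 1L) {
    s <- groupSamples(x, group)
    if (length(s) < minReplicates)
        stop(sprintf("group '%s' has %d replicate(s); >= %d required",
                     group, length(s), minReplicates))
    .activeValues(x)[, s, drop = FALSE]
}

.requireScale <- function(x, scale) {
    if (assayScale(x) != scale)
        stop(sprintf("matrix must be on the %s scale (found '%s')",
                     scale, assayScale(x)))
    invisible(x)
}

# deterministic sub-seed derivation (keeps values < 2^31)
.childSeed <- function(seed, k) (as.integer(seed) + 1103L * as.integer(k)) %% 2147483647L
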