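# shared fixtures and independent oracles used across test files

suppressPackageStartupMessages(library(SummarizedExperiment))

# small deterministic experiment: g genes, two or more groups, r replicates
makeToyExperiment <- function(nGenes = 20, groups = c("sham", "IR18", "IR30"),
                              reps = 3, seed = 42, scale = "counts") {
    set.seed(seed)
    samples <- paste0(rep(groups, each = reps), "_r",
                      rep(seq_len(reps), length(groups)))
    vals <- matrix(rnbinom(nGenes * length(samples), mu = 100, size = 50),
                   nGenes, length(samples),
                   dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                   samples))
    if (scale == "log2") vals <- log2(vals + 1)
    TimecourseExperiment(vals,
                         setNames(rep(groups, each = reps), samples),
                         groupOrder = groups, scale = scale)
}

# brute-force GSEA running sum, written independently of the package:
# walks the list position by position
bruteRunningSum <- function(genes, metrics, geneSet, p = 1) {
    N <- length(genes)
    hits <- genes %in% geneSet
    nh <- sum(hits)
    denom <- sum(abs(metrics[hits])^p)
    rs <- numeric(N)
    acc <- 0
    for (i in seq_len(N)) {
        acc <- acc + if (hits[i]) abs(metrics[i])^p / denom
                     else -1 / (N - nh)
        rs[i] <- acc
    }
    rs
}

bruteEs <- function(genes, metrics, geneSet, p = 1) {
    rs <- bruteRunningSum(genes, metrics, geneSet, p)
    rs[which.max(abs(rs))]
}

# brute-force composite index straight from the raw per-group matrix:
# per-gene SDs with stats::sd, all pairwise correlations with stats::cor
# on vectors, no reuse of package internals
bruteCi <- function(values, cluster, others) {
    sds <- vapply(cluster, function(g) sd(values[g, ]), numeric(1))
    pairs <- combn(cluster, 2, simplify = FALSE)
    pcc1 <- mean(vapply(pairs, function(p)
        abs(cor(values[p[1], ], values[p[2], ])), numeric(1)))
    cross <- expand.grid(a = cluster, b = others,
                         stringsAsFactors = FALSE)
    pcc0 <- mean(mapply(function(a, b)
        abs(cor(values[a, ], values[b, ])), cross$a, cross$b))
    mean(sds) * pcc1 / pcc0
}

# BH step-up evaluated directly from its definition:
# adjusted p_(i) = min over j >= i of p_(j) * n / j, clipped at 1
bruteBh <- function(p) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(n)
    for (i in seq_len(n))
        adj[i] <- min(pmin(ps[i:n] * n / (i:n), 1))
    out <- numeric(n)
    out[o] <- adj
    out
}

# planted standardized profiles with gaussian noise, for recovery tests
makePlantedProfiles <- function(shapes, perShape = 50, nGroups = 6,
                                noiseSd = 0.2, seed = 1) {
    set.seed(seed)
    t <- seq_len(nGroups - 1) / (nGroups - 1)
    base <- list(mono_up = c(0, t * 2),
                 mono_down = c(0, -t * 2),
                 up_down = c(0, 2 * (1 - abs(2 * t - 1))),
                 late_only = c(rep(0, nGroups - 1), 2))
    rows <- list(); labels <- integer()
    for (i in seq_along(shapes)) {
        for (j in seq_len(perShape)) {
            p <- base[[shapes[i]]] + rnorm(nGroups, 0, noiseSd)
            rows[[length(rows) + 1L]] <- (p - mean(p)) /
                sqrt(mean((p - mean(p))^2))
            labels <- c(labels, i)
        }
    }
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
    list(profiles = m, labels = labels)
}
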