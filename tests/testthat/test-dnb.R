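# experiment with hand-placed replicate values for exact SD/correlation
# control: 3 groups x 4 replicates
makeDnbToy <- function(vals, groups = c("sham", "IR22")) {
    reps <- ncol(vals) / length(groups)
    colnames(vals) <- paste0(rep(groups, each = reps), "_r",
                             seq_len(reps))
    TimecourseExperiment(vals, setNames(rep(groups, each = reps),
                                        colnames(vals)),
                         groupOrder = groups, scale = "log2")
}

test_that("high-deviation selection applies the SD-fold rule", {
    vals <- rbind(
        big   = c(5, 5, 5, 5,  1, 5, 9, 13),    # sd 0 -> zero-ref flag
        four  = c(4, 5, 6, 7,  1, 5, 9, 13),    # ratio 4/1.29 = 3.1
        equal = c(4, 5, 6, 7,  4, 5, 6, 7),     # ratio 1
        off   = c(0, 0, 0, 0,  0, 0, 0, 0))     # all zero: not expressed
    x <- makeDnbToy(vals)
    sel <- selectHighSdGenes(x, "IR22", "sham", sdFold = 2)
    expect_setequal(sel$gene_id, c("big", "four"))
    expect_true(sel$zero_reference[sel$gene_id == "big"])
    expect_false(sel$zero_reference[sel$gene_id == "four"])
    # identical per-group SDs select nothing at fold 2
    expect_identical(nrow(selectHighSdGenes(x, "sham", "IR22",
                                            sdFold = 2)), 0L)
    expect_error(selectHighSdGenes(makeToyExperiment(reps = 1), "IR18"),
                 "replicate")
})

test_that("correlation matrices match hand-evaluated Pearson values", {
    vals <- rbind(a = c(0, 0, 0, 1, 2, 3),
                  b = c(0, 0, 0, 3, 2, 1),
                  c = c(0, 0, 0, 1, 2, 4),
                  d = c(5, 5, 5, 7, 7, 7))
    x <- makeDnbToy(vals, groups = c("sham", "IR22"))
    r <- pccMatrix(x, "IR22", c("a", "b", "c"))
    expect_equal(unname(diag(r)), rep(1, 3))
    expect_equal(r["a", "b"], -1, tolerance = 1e-12)
    expect_equal(r["a", "c"], 1.5 / sqrt(1 * 7 / 3), tolerance = 1e-12)
    expect_equal(r, t(r))
    # zero-variance gene warns and gets 0
    expect_warning(r2 <- pccMatrix(x, "IR22", c("a", "d")),
                   "zero-variance")
    expect_equal(r2["a", "d"], 0)
    expect_error(pccMatrix(x, "IR22", "a"), ">= 2")
})

test_that("correlation clustering recovers planted blocks both ways", {
    set.seed(2)
    n1 <- 6; n2 <- 5; nbg <- 6
    blockCor <- function(n, rho) {
        m <- matrix(rho, n, n); diag(m) <- 1; m
    }
    pcc <- matrix(0, n1 + n2 + nbg, n1 + n2 + nbg)
    pcc[1:n1, 1:n1] <- blockCor(n1, 0.95)
    pcc[n1 + (1:n2), n1 + (1:n2)] <- blockCor(n2, 0.95)
    off <- pcc == 0
    pcc[off] <- runif(sum(off), -0.1, 0.1)
    pcc[lower.tri(pcc)] <- t(pcc)[lower.tri(pcc)]
    diag(pcc) <- 1
    rownames(pcc) <- colnames(pcc) <- sprintf("g%02d", seq_len(nrow(pcc)))
    for (mode in c("hclust", "components")) {
        cl <- clusterByCorrelation(pcc, threshold = 0.9,
                                   minClusterSize = 5, mode = mode)
        expect_length(cl$clusters, 2L)
        expect_setequal(cl$clusters[[1]], sprintf("g%02d", 1:n1))
        expect_setequal(cl$clusters[[2]], sprintf("g%02d", n1 + (1:n2)))
    }
    # homogeneous mid correlation yields no cluster at 0.9
    mid <- blockCor(8, 0.5)
    rownames(mid) <- colnames(mid) <- paste0("m", 1:8)
    expect_length(clusterByCorrelation(mid, 0.9, 5)$clusters, 0L)
    expect_error(clusterByCorrelation(mid, 1.2), "\\(0, 1\\)")
})

test_that("composite index reproduces its closed form and bounds", {
    # the published worked example: IR22 row
    expect_equal(round(compositeIndex(10.69, 0.96, 0.44), 2), 23.32)
    # ratio identity
    expect_equal(compositeIndex(3.7, 0.5, 0.5), 3.7, tolerance = 1e-15)
    set.seed(4)
    for (i in 1:50) {
        ms <- runif(1, 0, 20); p1 <- runif(1); p0 <- runif(1, 0.01, 1)
        expect_equal(compositeIndex(ms, p1, p0), ms * p1 / p0,
                     tolerance = 1e-15)
    }
    expect_error(compositeIndex(1, 0.5, 1e-9), "degenerate")
    expect_error(compositeIndex(-1, 0.5, 0.5), ">= 0")
    expect_error(compositeIndex(1, 1.5, 0.5), "\\[0, 1\\]")
})

test_that("group evaluation equals the brute-force CI oracle", {
    cfg <- simulationConfig(nGenes = 50, groups = paste0("G", 0:4),
                            replicates = 3, dnbModule = NULL,
                            profileClusters = NULL, geneSetSpec = NULL,
                            deFraction = 0)
    for (s in 1:10) {
        sim <- simulateTimecourse(cfg, seed = s)
        x <- normalizeLogCpm(sim$experiment)
        v <- assay(x, "logcpm")
        for (g in c("G2", "G4")) {
            # relaxed thresholds so random data yields candidate clusters
            r <- evaluateDnbGroup(x, g, "G0", sdFold = 1,
                                  pccThreshold = 0.5, minClusterSize = 3)
            if (is.null(r$best)) next
            cols <- groupSamples(x, g)
            others <- setdiff(r$selected$gene_id, r$best$genes)
            expect_equal(r$best$CI,
                         bruteCi(v[, cols], r$best$genes, others),
                         tolerance = 1e-12)
        }
    }
})

test_that("CI is invariant to gene order and replicate relabeling", {
    cfg <- simulationConfig(nGenes = 80, replicates = 5,
                            profileClusters = NULL)
    sim <- simulateTimecourse(cfg, seed = 13)
    x <- normalizeLogCpm(sim$experiment)
    r1 <- evaluateDnbGroup(x, "IR22")
    # permute genes
    counts <- assay(sim$experiment, "counts")
    perm <- sample(nrow(counts))
    xp <- normalizeLogCpm(TimecourseExperiment(
        counts[perm, ], sampleGroups(sim$experiment),
        groupOrder = groupOrder(sim$experiment)))
    r2 <- evaluateDnbGroup(xp, "IR22")
    expect_setequal(r1$best$genes, r2$best$genes)
    expect_equal(r1$best$CI, r2$best$CI, tolerance = 1e-12)
    # swap replicate columns within the tipping group
    cols <- colnames(counts)
    tip <- groupSamples(sim$experiment, "IR22")
    cols[match(tip, cols)] <- rev(tip)
    xs <- normalizeLogCpm(TimecourseExperiment(
        counts[, cols], sampleGroups(sim$experiment)[cols],
        groupOrder = groupOrder(sim$experiment)))
    r3 <- evaluateDnbGroup(xs, "IR22")
    expect_equal(r1$best$CI, r3$best$CI, tolerance = 1e-12)
})

test_that("the planted module is recalled and identified", {
    # variance inflation such that the SD ratio is sqrt(10) ~ 3.2: at fold
    # 1.5 and 30 replicates the module genes should almost all be selected
    cfg <- simulationConfig(nGenes = 200, replicates = 30,
                            profileClusters = NULL)
    sim <- simulateTimecourse(cfg, seed = 17)
    x <- normalizeLogCpm(sim$experiment)
    sel <- selectHighSdGenes(x, "IR22", sdFold = 1.5)
    mod <- sim$truth$dnbModule$genes
    expect_gte(mean(mod %in% sel$gene_id), 0.9)
    # and the best cluster at defaults overlaps the module strongly
    r <- evaluateDnbGroup(x, "IR22")
    jac <- length(intersect(r$best$genes, mod)) /
        length(union(r$best$genes, mod))
    expect_gte(jac, 0.6)
})

test_that("tipping point picks the arg-max CI and handles edge cases", {
    # the published per-group CI profile peaks at the 22-minute group
    tab <- c(IR16 = 18.15, IR18 = 19.43, IR22 = 23.32, IR26 = 19.10,
             IR30 = 19.35)
    tp <- tippingPoint(tab)
    expect_identical(tp$group, "IR22")
    expect_equal(tp$ci, 23.32)
    expect_identical(tp$table$group, names(tab))
    # single defined CI: returned with a warning
    expect_warning(tp1 <- tippingPoint(c(a = NA, b = 2, c = NA)),
                   "low confidence")
    expect_identical(tp1$group, "b")
    # nothing defined: explicit no-transition answer
    expect_message(tp0 <- tippingPoint(c(a = NA_real_, b = NA_real_)),
                   "no transition")
    expect_true(is.na(tp0$group))
})

test_that("evaluating the reference against itself finds no deviation", {
    cfg <- simulationConfig(nGenes = 300, replicates = 10)
    sim <- simulateTimecourse(cfg, seed = 23)
    x <- normalizeLogCpm(sim$experiment)
    r <- evaluateDnbGroup(x, "sham", "sham")
    expect_identical(r$selected_gene_number, 0L)
    expect_null(r$best)
})

test_that("runDnb assembles the per-group table and the best clusters", {
    cfg <- simulationConfig(nGenes = 250, replicates = 10)
    sim <- simulateTimecourse(cfg, seed = 29)
    dr <- runDnb(normalizeLogCpm(sim$experiment))
    tab <- dnbTable(dr)
    expect_identical(tab$group, groupOrder(sim$experiment)[-1])
    expect_true(all(tab$selected_gene_number >=
                    ifelse(is.na(tab$cluster_size), 0, tab$cluster_size)))
    ok <- !is.na(tab$CI)
    expect_true(all(tab$pcc1[ok] >= 0 & tab$pcc1[ok] <= 1))
    expect_true(all(tab$pcc0[ok] >= 0 & tab$pcc0[ok] <= 1))
    tp <- suppressWarnings(suppressMessages(tippingPoint(dr)))
    expect_identical(tp$group, "IR22")
    # edge list only contains pairs at or above the threshold
    e <- dnbEdges(dr)[["IR22"]]
    if (nrow(e)) expect_true(all(abs(e$pcc) >= 0.9))
})
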