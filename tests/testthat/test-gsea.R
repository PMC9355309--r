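test_that("ranking metric sign, ties and antisymmetry", {
    groups <- c("sham", "IR18", "IR30")
    set.seed(1)
    vals <- matrix(rnorm(5 * 9, 8, 0.5), 5, 9,
                   dimnames = list(paste0("g", 1:5),
                                   paste0(rep(groups, each = 3),
                                          "_r", 1:3)))
    vals["g3", 4:6] <- vals["g3", 4:6] + 3   # higher in IR18
    x <- TimecourseExperiment(vals, setNames(rep(groups, each = 3),
                                             colnames(vals)),
                              groupOrder = groups, scale = "log2")
    r <- rankGenes(x, "IR18", "sham")
    expect_identical(r$gene_id[1], "g3")
    expect_gt(r$metric[1], 0)
    rInv <- rankGenes(x, "sham", "IR18")
    expect_equal(sort(rInv$metric), sort(-r$metric), tolerance = 1e-12)
    expect_identical(rInv$gene_id[nrow(rInv)], "g3")
    # identical groups: all metrics 0, lexicographic order
    dup <- vals[, c(1:3, 1:3)]
    colnames(dup) <- paste0(rep(c("sham", "IR18"), each = 3), "_r", 1:3)
    xid <- TimecourseExperiment(
        dup, setNames(rep(c("sham", "IR18"), each = 3), colnames(dup)),
        groupOrder = c("sham", "IR18"), scale = "log2")
    r0 <- rankGenes(xid, "IR18", "sham")
    expect_true(all(r0$metric == 0))
    expect_identical(r0$gene_id, sort(r0$gene_id))
    expect_error(rankGenes(makeToyExperiment(reps = 1, scale = "log2"),
                           "IR18", "sham"), "log2fc")
})

test_that("enrichment score matches the exhaustive oracle", {
    # single-gene set at rank 1 -> ES = 1 at peak 1
    rk <- data.frame(gene_id = paste0("g", 1:5),
                     metric = c(3, 2, 1, 0.5, 0.1))
    es1 <- enrichmentScore(rk, "g1")
    expect_equal(es1$es, 1)
    expect_identical(es1$peakIndex, 1L)
    # single-gene set at the last rank: running sum is forced to -1 just
    # before the hit
    esN <- enrichmentScore(rk, "g5")
    expect_equal(esN$es, bruteEs(rk$gene_id, rk$metric, "g5"),
                 tolerance = 1e-12)
    expect_equal(esN$es, -1)
    expect_identical(esN$peakIndex, 4L)
    # random 20-gene instances against the brute-force running sum
    set.seed(7)
    for (i in 1:100) {
        genes <- paste0("x", sample(100, 20))
        metrics <- sort(rnorm(20), decreasing = TRUE)
        gs <- sample(genes, sample(2:8, 1))
        rki <- data.frame(gene_id = genes, metric = metrics)
        got <- enrichmentScore(rki, gs)
        brs <- bruteRunningSum(genes, metrics, gs)
        expect_equal(got$runningSum, brs, tolerance = 1e-12)
        expect_equal(abs(got$es), max(abs(brs)), tolerance = 1e-12)
        # sign comparison only when the extreme deviation is unambiguous
        if (max(brs) - abs(min(brs)) > 2e-12 ||
            abs(min(brs)) - max(brs) > 2e-12)
            expect_equal(got$es, brs[which.max(abs(brs))],
                         tolerance = 1e-12)
        expect_true(abs(got$es) <= 1)
    }
    expect_error(enrichmentScore(rk, "absent"), "intersect")
    expect_error(enrichmentScore(rk, rk$gene_id), "whole")
})

test_that("unweighted running sum returns to zero and fgsea agrees", {
    set.seed(3)
    genes <- paste0("g", 1:50)
    metrics <- sort(rnorm(50), decreasing = TRUE)
    rk <- data.frame(gene_id = genes, metric = metrics)
    gs <- sample(genes, 10)
    rs0 <- enrichmentScore(rk, gs, p = 0)$runningSum
    expect_lt(abs(rs0[length(rs0)]), 1e-9)
    skip_if_not_installed("fgsea")
    stats <- setNames(metrics, genes)
    for (i in 1:10) {
        gsi <- sample(genes, sample(3:15, 1))
        ours <- enrichmentScore(rk, gsi, p = 1)$es
        ref <- fgsea::calcGseaStat(stats,
                                   which(genes %in% gsi),
                                   gseaParam = 1)
        expect_equal(ours, ref, tolerance = 1e-12)
    }
})

test_that("permutation null is deterministic and bounds the p-value", {
    x <- makeToyExperiment(nGenes = 60, scale = "log2", seed = 21)
    gs <- rownames(x)[1:8]
    n1 <- permutationNull(x, "IR30", "sham", gs, B = 100, seed = 5)
    n2 <- permutationNull(x, "IR30", "sham", gs, B = 100, seed = 5)
    expect_identical(n1, n2)
    expect_length(n1, 100)
    # an observed score above every same-side null gets the floor p
    side <- n1[n1 > 0]
    pFloor <- 1 / (1 + length(side))
    expect_equal(tipDNB:::.nominalP(max(abs(n1)) + 1, n1), pFloor,
                 tolerance = 1e-12)
    expect_error(permutationNull(x, "IR30", "sham", gs, B = 50), ">= 100")
    # phenotype mode enumerates all relabelings when few
    np <- permutationNull(x, "IR30", "sham", gs, B = 100,
                          mode = "phenotype", seed = 5)
    expect_length(np, choose(6, 3))
})

test_that("nominal p-values are calibrated on null data", {
    # geneset-mode p for a random set on unstructured data is uniform-ish
    x <- makeToyExperiment(nGenes = 150, scale = "log2", seed = 31)
    rk <- rankGenes(x, "IR30", "sham")
    set.seed(9)
    ps <- vapply(1:200, function(i) {
        gs <- sample(rk$gene_id, 10)
        es <- enrichmentScore(rk, gs)$es
        nulls <- vapply(1:100, function(j)
            enrichmentScore(rk, sample(rk$gene_id, 10))$es, numeric(1))
        tipDNB:::.nominalP(es, nulls)
    }, numeric(1))
    d <- suppressWarnings(ks.test(ps, "punif"))$statistic
    expect_lt(unname(d), 0.1)
})

test_that("NES, BH and significance flags are assembled coherently", {
    x <- makeToyExperiment(nGenes = 80, scale = "log2", seed = 41)
    sets <- GeneSetCollection(list(s1 = rownames(x)[1:10],
                                   s2 = rownames(x)[11:25],
                                   s3 = rownames(x)[26:30]))
    gr <- runGsea(x, sets, "IR30", "sham", B = 100, seed = 3)
    tab <- gseaTable(gr)
    expect_identical(gr@mode, "geneset")   # n = 3 forces geneset mode
    expect_identical(nrow(tab), 3L)
    expect_true(all(tab$adjusted_p >= tab$nominal_p - 1e-12))
    expect_true(all(abs(tab$es) <= 1))
    expect_true(all(sign(tab$nes) == sign(tab$es) | tab$es == 0))
    expect_true(all(tab$nominal_p > 0 & tab$nominal_p <= 1))
    # single tested set: adjusted = nominal
    gr1 <- runGsea(x, GeneSetCollection(list(s1 = rownames(x)[1:10])),
                   "IR30", "sham", B = 100, seed = 3)
    expect_equal(gseaTable(gr1)$adjusted_p, gseaTable(gr1)$nominal_p)
})

test_that("the leading edge is the set slice at the peak side", {
    rk <- data.frame(gene_id = paste0("g", 1:10),
                     metric = seq(5, -4, length.out = 10))
    # positive score: members at or before the peak
    gs <- c("g1", "g2", "g9")
    es <- enrichmentScore(rk, gs)
    le <- leadingEdge(rk, gs, es$es, es$peakIndex)
    expect_identical(le, c("g1", "g2"))
    # a set concentrated at the bottom scores negatively and its leading
    # edge runs from the peak to the end of the list
    gsLate <- c("g9", "g10")
    esL <- enrichmentScore(rk, gsLate)
    expect_lt(esL$es, 0)
    expect_identical(leadingEdge(rk, gsLate, esL$es, esL$peakIndex),
                     c("g9", "g10"))
    # and a set entirely after a positive peak contributes nothing
    gsMix <- c("g1", "g10")
    esM <- enrichmentScore(rk, gsMix)
    expect_gt(esM$es, 0)
    expect_identical(leadingEdge(rk, gsMix, esM$es, esM$peakIndex), "g1")
    # brute-force definition on a toy example
    expect_identical(
        leadingEdge(rk, gs, es$es, es$peakIndex),
        rk$gene_id[seq_len(es$peakIndex)][
            rk$gene_id[seq_len(es$peakIndex)] %in% gs])
    expect_warning(leadingEdge(rk, gs, 0, 3), "undefined")
})

test_that("planted enriched sets outrank background sets by |NES|", {
    wins <- vapply(1:10, function(s) {
        cfg <- simulationConfig(nGenes = 400, deFraction = 0.1,
                                profileClusters = NULL, dnbModule = NULL,
                                geneSetSpec = list(nSets = 6, setSize = 25,
                                                   signalFraction = 0.6))
        sim <- simulateTimecourse(cfg, seed = s)
        x <- normalizeLogCpm(sim$experiment)
        gr <- runGsea(x, sim$geneSets, "IR30", "sham", B = 100, seed = s)
        tab <- gseaTable(gr)
        planted <- tab$set %in% sim$truth$enrichedSets$set
        mean(abs(tab$nes[planted]), na.rm = TRUE) >
            mean(abs(tab$nes[!planted]), na.rm = TRUE)
    }, logical(1))
    expect_gte(mean(wins), 0.9)
})

test_that("the key-gene screen applies the two-threshold disjunction", {
    lfcM <- c(a = 0.8, b = 1.2, c = 0.9, d = -1.1, e = 0.2)
    lfcS <- c(a = 1.1, b = 0.8, c = 0.9, d = -0.8, e = 2)
    out <- keyGeneScreen(c("a", "b", "c", "d", "e"), lfcM, lfcS)
    expect_identical(out$passes[match(c("a", "b", "c", "d", "e"),
                                      out$gene_id)],
                     c(TRUE, TRUE, FALSE, TRUE, FALSE))
    # sorted by the larger absolute fold change, descending
    expect_identical(out$gene_id[1], "e")
    expect_warning(keyGeneScreen(c("a", "zz"), lfcM, lfcS), "skipped")
})
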