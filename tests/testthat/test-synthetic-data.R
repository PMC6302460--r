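smallCfg <- function(seed = 5, ...) {
    simConfig(nPathways = 12, nGenes = 300, sizeRange = c(8L, 15L),
              nPlanted = 3, nTumor = 10, nNormal = 10, decoyFrac = 0,
              seed = seed, ...)
}

test_that("collection simulation respects sizes and is seed-deterministic", {
    cfg <- simConfig(nPathways = 5, nGenes = 100, sizeRange = c(10L, 10L),
                     seed = 1)
    coll <- simulateCollection(cfg)
    expect_length(geneSets(coll), 5L)
    expect_true(all(vapply(geneSets(coll),
                           function(g) length(members(g)), 0L) == 10L))
    coll2 <- simulateCollection(cfg)
    expect_identical(coll, coll2)

    noEdges <- simulateCollection(simConfig(nPathways = 4, nGenes = 100,
                                            nPlanted = 2, edgeDensity = 0,
                                            seed = 2))
    expect_true(all(vapply(topologies(noEdges),
                           function(t) nrow(t@edges), 0L) == 0L))
})

test_that("study simulation is fully deterministic under a fixed seed", {
    s1 <- simulateStudy(smallCfg())
    s2 <- simulateStudy(smallCfg())
    expect_identical(SummarizedExperiment::assay(s1$protein),
                     SummarizedExperiment::assay(s2$protein))
    expect_identical(SummarizedExperiment::assay(s1$phospho),
                     SummarizedExperiment::assay(s2$phospho))
    expect_identical(s1$truth, s2$truth)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeStudy(s1, d1); writeStudy(s2, d2)
    for (f in list.files(d1))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
})

test_that("missing fraction matches the censoring quantile", {
    s <- simulateStudy(smallCfg(missingQuantile = 0.1))
    for (layer in c("protein", "phospho")) {
        m <- SummarizedExperiment::assay(s[[layer]])
        expect_equal(mean(is.na(m)), 0.1, tolerance = 2 / length(m) / 0.1)
    }
    s0 <- simulateStudy(smallCfg(missingQuantile = 0))
    expect_false(anyNA(SummarizedExperiment::assay(s0$protein)))
})

test_that("layer split 1 with no overlap leaves the phospho layer null", {
    s <- simulateStudy(smallCfg(layerSplit = 1, overlapFrac = 0,
                                missingQuantile = 0))
    gt <- s$truth@geneTable
    expect_true(all(gt$layer == "protein"))
    # phospho tumor/normal means agree for planted genes (no planted shift)
    m <- SummarizedExperiment::assay(s$phospho)
    gr <- sampleGroups(s$phospho)
    genes <- sub("_[^_]+$", "", rownames(m))
    planted <- rownames(m)[genes %in% gt$gene]
    diffs <- rowMeans(m[planted, gr == "tumor"]) -
        rowMeans(m[planted, gr == "normal"])
    expect_lt(max(abs(diffs)), 2)  # noise-scale, not delta-scale
    expect_lt(abs(mean(diffs)), 0.3)
})

test_that("null simulation shows no group difference in expectation", {
    s <- simulateStudy(smallCfg(delta = 0, missingQuantile = 0, seed = 9))
    de <- differentialTest(s$protein)
    expect_lt(mean(de$is_de), 0.01)
    expect_gt(mean(de$p > 0.5), 0.4)  # p roughly uniform
})

test_that("planted genes are recovered as DE with high sensitivity", {
    s <- simulateStudy(simConfig(nPathways = 40, nGenes = 800,
                                 nPlanted = 5, nTumor = 20, nNormal = 20,
                                 decoyFrac = 0, missingQuantile = 0,
                                 seed = 21))
    gt <- s$truth@geneTable
    deP <- differentialTest(s$protein)
    protGenes <- gt$gene[gt$layer %in% c("protein", "both")]
    sens <- mean(protGenes %in% deP$feature[deP$is_de])
    expect_gt(sens, 0.9)
    phosGene <- collapseSites(s$phospho)
    deS <- differentialTest(phosGene)
    phosGenes <- gt$gene[gt$layer %in% c("phospho", "both")]
    expect_gt(mean(phosGenes %in% deS$feature[deS$is_de]), 0.9)
})

test_that("subtype planting shifts only the named subtype's tumors", {
    set.seed(1)
    spec <- list(Basal = "P002", LumA = "P005")
    s <- simulateStudy(simConfig(nPathways = 10, nGenes = 200,
                                 nPlanted = 2, nTumor = 12, nNormal = 8,
                                 decoyFrac = 0, missingQuantile = 0,
                                 overlapFrac = 1, subtypeSpec = spec,
                                 seed = 31))
    gt <- s$truth@geneTable
    basalGenes <- gt$gene[gt$scope == "Basal"]
    expect_gt(length(basalGenes), 0)
    m <- SummarizedExperiment::assay(s$protein)
    st <- sampleSubtypes(s$protein)
    gr <- sampleGroups(s$protein)
    basalCols <- gr == "tumor" & !is.na(st) & st == "Basal"
    lumCols <- gr == "tumor" & !is.na(st) & st == "LumA"
    normCols <- gr == "normal"
    sgn <- gt$sign[match(basalGenes, gt$gene)]
    shiftIn <- mean(sgn * (rowMeans(m[basalGenes, basalCols, drop = FALSE]) -
                           rowMeans(m[basalGenes, normCols, drop = FALSE])))
    shiftOut <- mean(abs(rowMeans(m[basalGenes, lumCols, drop = FALSE]) -
                         rowMeans(m[basalGenes, normCols, drop = FALSE])))
    expect_gt(shiftIn, 1)      # close to delta = 2
    expect_lt(shiftOut, 1)     # noise only
})

test_that("configuration invariants are enforced", {
    expect_error(simConfig(nPathways = 5, nPlanted = 6), "nPlanted")
    expect_error(simConfig(missingQuantile = 1), "missingQuantile")
    expect_error(simConfig(nGenes = 10, sizeRange = c(15L, 40L)),
                 "universe")
    expect_error(simConfig(delta = -1), "delta")
})
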