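test_that("GMT parsing maps lines to gene sets and collapses duplicates", {
    f <- withr::local_tempfile(lines = c(
        "hsa04115\tp53 signaling pathway\tTP53\tMDM2",
        "hsa04110\tCell cycle\tTP53\tTP53\tCDK1"))
    coll <- readGMT(f)
    expect_identical(pathwayIds(coll), c("hsa04115", "hsa04110"))
    expect_setequal(members(geneSets(coll)$hsa04115), c("TP53", "MDM2"))
    expect_identical(members(geneSets(coll)$hsa04110), c("TP53", "CDK1"))
})

test_that("malformed GMT lines are rejected with the line number", {
    f <- withr::local_tempfile(lines = c("ok\tdesc\tA", "bad\tonly-two"))
    expect_error(readGMT(f), "line 2")
})

test_that("the packaged breast-cancer target fixture has the 12 ids", {
    targets <- readTargets()
    expect_length(targets, 12L)
    expect_true(all(grepl("^hsa\\d{5}$", targets)))
    expect_true(all(c("hsa04115", "hsa04510", "hsa05200") %in% targets))
})

test_that("GMT round-trip preserves ids and member sets", {
    set.seed(42)
    sets <- lapply(1:8, function(i)
        GeneSet(sprintf("pw%02d", i),
                sample(LETTERS, sample(3:10, 1))))
    coll <- PathwayCollection(sets)
    f <- withr::local_tempfile()
    writeGMT(coll, f)
    back <- readGMT(f)
    expect_identical(pathwayIds(back), pathwayIds(coll))
    for (id in pathwayIds(coll))
        expect_setequal(members(geneSets(back)[[id]]),
                        members(geneSets(coll)[[id]]))
})

test_that("edge-list reading groups by pathway and applies the beta map", {
    f <- withr::local_tempfile(lines = c(
        "pathway_id\tsource\ttarget\trelation",
        "p1\tA\tB\tactivation",
        "p1\tB\tC\tinhibition",
        "p2\tX\tX\tmember",
        "p2\tY\tY\tmember"))
    tps <- readTopologyTable(f, betaMap = c(activation = 1,
                                            inhibition = -1))
    expect_named(tps, c("p1", "p2"))
    expect_equal(nrow(tps$p1@edges), 2L)
    B <- influenceMatrix(tps$p1)
    expect_equal(B["B", "A"], 1)
    expect_equal(B["C", "B"], -1)
    expect_setequal(members(tps$p2), c("X", "Y"))
    expect_equal(nrow(tps$p2@edges), 0L)
})

test_that("unknown relation types name the offender", {
    f <- withr::local_tempfile(lines = c(
        "pathway_id\tsource\ttarget\trelation",
        "p1\tA\tB\tbinding"))
    expect_error(readTopologyTable(f, betaMap = c(activation = 1)),
                 "binding")
})

test_that("edge-list round-trip preserves members and edges", {
    tp <- PathwayTopology("p9", members = c("A", "B", "C", "D"),
        edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                           relation = c("activation", "inhibition")))
    f <- withr::local_tempfile()
    writeTopologyTable(list(p9 = tp), f)
    back <- readTopologyTable(f)
    expect_setequal(members(back$p9), members(tp))
    expect_equal(influenceMatrix(back$p9)[members(tp), members(tp)],
                 influenceMatrix(tp))
})

test_that("influence matrix normalizes by out-degree with signed weights", {
    fan <- PathwayTopology("fan", edges = data.frame(
        from = "A", to = c("B", "C"), relation = "activation"))
    B <- influenceMatrix(fan)
    expect_equal(B["B", "A"], 0.5)
    expect_equal(B["C", "A"], 0.5)
    expect_equal(sum(B != 0), 2L)

    inh <- PathwayTopology("inh", edges = data.frame(
        from = "A", to = "B", relation = "inhibition"))
    expect_equal(influenceMatrix(inh)["B", "A"], -1)

    iso <- PathwayTopology("iso", members = c("A", "B", "C"))
    expect_equal(influenceMatrix(iso),
                 matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                                 c("A", "B", "C"))))
})

test_that("influence-matrix column sums equal sum(beta)/Nds by recount", {
    set.seed(7)
    for (i in 1:20) {
        tp <- randomAcyclicTopology(sample(3:15, 1), sample(0:25, 1))
        B <- influenceMatrix(tp)
        ed <- tp@edges
        for (g in members(tp)) {
            out <- ed[ed$from == g, ]
            expected <- if (nrow(out) == 0) 0 else
                sum(tp@betaMap[out$relation]) / nrow(out)
            expect_equal(sum(B[, g]), unname(expected))
        }
    }
})

test_that("collection validity enforces topology/gene-set agreement", {
    gs <- list(GeneSet("p1", c("A", "B")))
    tpBad <- list(p1 = PathwayTopology("p1", members = c("A", "C")))
    expect_error(PathwayCollection(gs, topologies = tpBad),
                 "members differ")
    expect_error(PathwayCollection(gs, targetIds = "nope"), "subset")
})
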