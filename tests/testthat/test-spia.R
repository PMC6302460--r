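test_that("toy topologies match hand-solved propagation", {
    # chain A->B->C, unit activations, perturbation at the root
    res <- netAccumulation(chainTopology(), c(A = 1))
    expect_equal(res$pf, c(A = 1, B = 1, C = 1))
    expect_equal(res$acc, c(A = 0, B = 1, C = 1))
    expect_equal(res$tA, 2)
    expect_equal(res$status, "ok")

    # single inhibition doubles down
    inh <- PathwayTopology("inh", edges = data.frame(
        from = "A", to = "B", relation = "inhibition"))
    res2 <- netAccumulation(inh, c(A = 2))
    expect_equal(res2$acc[["B"]], -2)
    expect_equal(res2$tA, -2)

    # fan-out splits by out-degree
    fan <- PathwayTopology("fan", edges = data.frame(
        from = "A", to = c("B", "C"), relation = "activation"))
    res3 <- netAccumulation(fan, c(A = 2))
    expect_equal(res3$acc[["B"]], 1)
    expect_equal(res3$acc[["C"]], 1)
    expect_equal(res3$tA, 2)

    # 2-cycle with unit gain is singular: flagged, not dropped
    cyc <- PathwayTopology("cyc", edges = data.frame(
        from = c("A", "B"), to = c("B", "A"), relation = "activation"))
    res4 <- netAccumulation(cyc, c(A = 1))
    expect_equal(res4$status, "singular")
    expect_true(is.na(res4$tA))
})

test_that("solved propagation equals iterative fixpoint on random dags", {
    set.seed(15)
    for (i in 1:40) {
        nG <- sample(3:30, 1)
        tp <- randomAcyclicTopology(nG, sample(0:(2 * nG), 1))
        dE <- setNames(rnorm(nG), members(tp))
        dE[sample(nG, nG %/% 2)] <- 0
        res <- netAccumulation(tp, dE[dE != 0])
        expect_equal(res$status, "ok")
        B <- influenceMatrix(tp)
        pfIter <- iterateAccumulation(B, dE[members(tp)])
        expect_equal(res$pf, pfIter, tolerance = 1e-9)
    }
})

test_that("accumulation is linear in the fold changes", {
    set.seed(16)
    tp <- randomAcyclicTopology(12, 20)
    dE <- setNames(rnorm(5), sample(members(tp), 5))
    base <- netAccumulation(tp, dE)
    scaled <- netAccumulation(tp, 3.5 * dE)
    expect_equal(scaled$tA, 3.5 * base$tA)
    expect_equal(scaled$acc, 3.5 * base$acc)
    # non-member fold changes are dropped with a warning
    expect_warning(netAccumulation(tp, c(dE, ZZZ = 1)), "ZZZ")
})

test_that("evidence combination matches the closed form and Monte Carlo", {
    expect_equal(combinePG(1, 1), 1)
    expect_equal(combinePG(0.1, 0.1), 0.01 - 0.01 * log(0.01))
    expect_equal(combinePG(0.1, 0.1), 0.05605170, tolerance = 1e-7)
    # c -> 0 limit
    expect_lt(combinePG(1e-12, 1e-12), 1e-10)
    set.seed(17)
    u1 <- runif(1e6); u2 <- runif(1e6)
    for (cc in c(0.001, 0.01, 0.1, 0.5)) {
        mc <- mean(u1 * u2 <= cc)
        se <- sqrt(mc * (1 - mc) / 1e6)
        expect_lt(abs(combinePG(sqrt(cc), sqrt(cc)) - mc), 3 * se)
    }
    expect_error(combinePG(0, 0.5), "pNde")
})

test_that("perturbation bootstrap honors trivial contracts", {
    coll <- tinyCollection()
    bg <- c("A", "B", "C", "D", "E", "F", "G")
    # no DE genes anywhere: all evidence null, ranks follow tie-breaks
    inp0 <- makeInput(character(), numeric(), bg,
                      profile = setNames(rep(0, 7), bg))
    out0 <- spiaScore(inp0, coll, nBoot = 5, seed = 1)
    expect_true(all(out0$pG == 1))
    expect_equal(out0$pathway_id[order(out0$rank)],
                 sort(out0$pathway_id))
    # nBoot = 1 forces pPERT into {0.5, 1}
    inp <- makeInput(c("A", "B"), c(A = 2, B = 1), bg,
                     profile = setNames(rnorm(7), bg))
    out1 <- spiaScore(inp, coll, nBoot = 1, seed = 2)
    expect_true(all(out1$pPERT %in% c(0.5, 1)))
    # pathways without topology degrade to over-representation evidence
    expect_equal(out1$status[out1$pathway_id == "p2"], "no_topology")
    expect_equal(out1$pPERT[out1$pathway_id == "p2"], 1)
    expect_equal(out1$pNDE[out1$pathway_id == "p1"],
                 hyperUpperTail(2, 3, 2, 7))
})

test_that("a coherent planted chain is detected by the bootstrap", {
    mem <- paste0("m", 1:10)
    tp <- PathwayTopology("chain10", members = mem,
        edges = data.frame(from = mem[-10], to = mem[-1],
                           relation = "activation"))
    coll <- PathwayCollection(list(GeneSet("chain10", mem)),
                              topologies = list(chain10 = tp))
    set.seed(18)
    bgOther <- paste0("bgx", 1:190)
    bg <- c(mem, bgOther)
    pool <- setNames(c(rep(0.1, 10), rnorm(190, 0, 0.3)), bg)
    hits <- 0
    for (s in 1:20) {
        inp <- makeInput(mem[1], c(m1 = 2), bg, profile = pool)
        out <- spiaScore(inp, coll, nBoot = 400, seed = s)
        if (out$pPERT[1] < 0.05) hits <- hits + 1
    }
    expect_gte(hits, 19)  # >= 95% of seeds
})

test_that("scoring is deterministic under a seed and ranks consistently", {
    set.seed(19)
    study <- simulateStudy(simConfig(nPathways = 15, nGenes = 300,
                                     nPlanted = 3, nTumor = 8,
                                     nNormal = 8, decoyFrac = 0,
                                     seed = 77))
    res <- runPipeline(study$protein, study$phospho, study$collection,
                       methods = "spia", nBoot = 50, seed = 5)
    res2 <- runPipeline(study$protein, study$phospho, study$collection,
                        methods = "spia", nBoot = 50, seed = 5)
    expect_identical(res$scores$spia, res2$scores$spia)
    sc <- res$scores$spia
    ord <- order(sc$pG, -ifelse(is.na(sc$tA), 0, abs(sc$tA)),
                 sc$pathway_id, method = "radix")
    expect_equal(sc$rank[ord], seq_len(nrow(sc)))
})
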