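test_that("worked three-gene running sums are exact", {
    ranked <- c(g1 = 3, g2 = 2, g3 = 1)
    top <- enrichmentScore(ranked, "g1", exponent = 1)
    expect_equal(top$running, c(1, 0.5, 0))
    expect_equal(top$es, 1)
    bottom <- enrichmentScore(ranked, "g3", exponent = 0)
    expect_equal(bottom$running, c(-0.5, -1, 0))
    expect_equal(bottom$es, -1)
    # all genes members: monotone climb to 1
    full <- enrichmentScore(ranked, c("g1", "g2", "g3"), exponent = 1)
    expect_equal(full$es, 1)
    expect_true(all(diff(full$running) > 0))
    expect_equal(full$running[3], 1)
})

test_that("incremental score equals brute-force prefix recomputation", {
    set.seed(12)
    for (i in 1:60) {
        L <- sample(5:50, 1)
        scores <- sort(rnorm(L), decreasing = TRUE)
        names(scores) <- paste0("g", seq_len(L))
        members <- sample(names(scores), sample(1:(L - 1), 1))
        pw <- sample(c(0, 1, 2), 1)
        fast <- enrichmentScore(scores, members, pw)
        slow <- bruteES(scores, members, pw)
        expect_equal(fast$running, slow$running)
        expect_equal(fast$es, slow$es)
        # and the C++ position-based path agrees (sign can differ only on
        # an exact peak/trough tie, where float noise picks the side)
        pos <- which(names(scores) %in% members)
        cppEs <- intePath:::cppEsFromPositions(abs(scores)^pw,
                                               as.integer(pos - 1L))
        expect_equal(abs(cppEs), abs(fast$es))
        mx <- max(fast$running, 0); mn <- min(fast$running, 0)
        if (abs(mx + mn) > 1e-9) expect_equal(cppEs, fast$es)
    }
})

test_that("zero member scores fall back to unweighted increments", {
    ranked <- c(a = 5, b = 0, c = 0, d = -5)
    expect_warning(res <- enrichmentScore(ranked, c("b", "c"), 1),
                   "unweighted")
    ref <- enrichmentScore(ranked, c("b", "c"), 0)
    expect_equal(res$es, ref$es)
    expect_error(enrichmentScore(ranked, "zzz"), "disjoint")
})

test_that("reversing the list and negating scores negates the KS score", {
    set.seed(13)
    for (i in 1:25) {
        L <- sample(6:40, 1)
        scores <- sort(rnorm(L), decreasing = TRUE)
        names(scores) <- paste0("g", seq_len(L))
        members <- sample(names(scores), sample(2:(L - 2), 1))
        f <- enrichmentScore(scores, members, 0)
        r <- enrichmentScore(rev(-scores), members, 0)
        expect_equal(abs(r$es), abs(f$es))
        # sign flips except on an exact peak/trough tie, where the
        # positive side is preferred in both directions by convention
        mx <- max(f$running, 0); mn <- min(f$running, 0)
        if (abs(mx + mn) > 1e-9) expect_equal(r$es, -f$es)
    }
})

test_that("permutation p-values honor the add-one floor and determinism", {
    coll <- tinyCollection()
    prof <- setNames(seq(3, -3, length.out = 20), paste0("x", 1:20))
    names(prof)[1:3] <- c("A", "B", "C")
    names(prof)[18:20] <- c("E", "D", "F")
    inp <- makeInput(character(), numeric(), names(prof), profile = prof,
                     mode = "full_profile")
    out1 <- gseaScore(inp, coll, nPerm = 99, minSize = 2, seed = 42)
    out2 <- gseaScore(inp, coll, nPerm = 99, minSize = 2, seed = 42)
    expect_identical(out1, out2)
    expect_true(all(out1$p >= 1 / 100))
    expect_true(all(abs(out1$ES) <= 1))
    one <- gseaScore(inp, coll, nPerm = 1, minSize = 2, seed = 1)
    expect_true(all(one$p %in% c(0.5, 1)))
})

test_that("small pathways are skipped with a message", {
    coll <- tinyCollection()  # p3 has 2 members
    prof <- setNames(10:1, c("A", "B", "C", "D", "E", "F", "G",
                             "h1", "h2", "h3"))
    inp <- makeInput(character(), numeric(), names(prof), profile = prof,
                     mode = "full_profile")
    expect_message(out <- gseaScore(inp, coll, nPerm = 19, minSize = 3,
                                    seed = 2), "skipped")
    expect_false("p3" %in% out$pathway_id)
    expect_true(all(c("p1", "p2") %in% out$pathway_id))
})

test_that("null member draws give approximately uniform p-values", {
    set.seed(14)
    L <- 400
    prof <- setNames(sort(rnorm(L), decreasing = TRUE),
                     paste0("g", seq_len(L)))
    sets <- lapply(1:300, function(i)
        GeneSet(sprintf("r%03d", i), sample(names(prof), 15)))
    coll <- PathwayCollection(sets)
    inp <- makeInput(character(), numeric(), names(prof), profile = prof,
                     mode = "full_profile")
    out <- gseaScore(inp, coll, nPerm = 200, seed = 99)
    frac <- mean(out$p < 0.05)
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(out)))
})
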