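# Small builders and independent oracles shared across the suite.

tinyCollection <- function() {
    gs <- list(GeneSet("p1", c("A", "B", "C"), "toy one"),
               GeneSet("p2", c("C", "D", "E"), "toy two"),
               GeneSet("p3", c("F", "G"), "toy three"))
    tp <- list(p1 = PathwayTopology("p1", members = c("A", "B", "C"),
                   edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                                      relation = "activation")))
    PathwayCollection(gs, topologies = tp)
}

dtRow <- function(feature, log_fc, is_de = TRUE, p = 0.01) {
    data.frame(feature = feature, log_fc = log_fc, t = 0, p = p,
               p_adj = p, is_de = is_de, degenerate = FALSE,
               stringsAsFactors = FALSE)
}

makeInput <- function(de, fc, bg, profile = NULL,
                      mode = "intersection") {
    if (is.null(profile)) profile <- sort(fc, decreasing = TRUE)
    new("IntegratedInput", mode = mode, deGenes = de, combinedFc = fc,
        background = bg, profile = profile)
}

# Exact hypergeometric upper tail by direct binomial-coefficient term
# summation (independent of dhyper); valid to ~1e-13 relative error for
# N <= 60.
oracleHyperTail <- function(k, m, n, N) {
    if (k == 0) return(1)
    i <- k:min(m, n)
    sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

# Exhaustive subset-enumeration oracle for tiny N: draw every n-subset of
# the N-gene background, count those with >= k pathway genes.
enumHyperTail <- function(k, m, n, N) {
    if (n == 0) return(as.numeric(k == 0))
    draws <- combn(N, n)
    mean(apply(draws, 2, function(d) sum(d <= m) >= k))
}

# Brute-force running-sum oracle: recomputes the sum from scratch at every
# prefix instead of accumulating.
bruteES <- function(ranked, members, exponent = 0) {
    L <- length(ranked)
    hit <- names(ranked) %in% members
    k <- sum(hit)
    w <- abs(ranked)^exponent
    if (exponent > 0 && sum(w[hit]) == 0) w <- rep(1, L)
    inc <- ifelse(hit, w / sum(w[hit]), if (L > k) -1 / (L - k) else 0)
    running <- vapply(seq_len(L), function(i) sum(inc[seq_len(i)]), 0)
    mx <- max(running, 0); mn <- min(running, 0)
    list(es = if (mx >= -mn) mx else mn, running = running)
}

# Step-up false-discovery-rate adjustment written directly from the
# definition: q(i) = min over j >= i of p(j) * m / j on the sorted scale.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# Fixed-point iteration oracle for the propagation model.
iterateAccumulation <- function(B, dE, tol = 1e-10, maxIter = 100000L) {
    pf <- dE
    for (i in seq_len(maxIter)) {
        pfNew <- dE + drop(B %*% pf)
        if (max(abs(pfNew - pf)) < tol) return(pfNew)
        pf <- pfNew
    }
    stop("fixpoint iteration did not converge")
}

chainTopology <- function() PathwayTopology("chain", edges = data.frame(
    from = c("A", "B"), to = c("B", "C"), relation = "activation"))

randomAcyclicTopology <- function(nGenes, nEdges) {
    mem <- sprintf("g%02d", seq_len(nGenes))
    from <- integer(0); to <- integer(0)
    if (nEdges > 0) {
        # edges only from lower to higher index: acyclic by construction
        pairs <- which(upper.tri(matrix(0, nGenes, nGenes)), arr.ind = TRUE)
        pick <- pairs[sample(nrow(pairs), min(nEdges, nrow(pairs))), ,
                      drop = FALSE]
        from <- pick[, 1]; to <- pick[, 2]
    }
    rel <- sample(c("activation", "inhibition"), length(from),
                  replace = TRUE, prob = c(0.7, 0.3))
    PathwayTopology("rnd", members = mem,
                    edges = data.frame(from = mem[from], to = mem[to],
                                       relation = rel),
                    betaMap = c(activation = 1, inhibition = -1))
}
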