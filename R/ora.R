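.logSumExp <- function(x) {
    if (length(x) == 0L) return(-Inf)
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, m, n): the probability of drawing at
#' least `k` pathway genes when `n` DE genes are sampled without
#' replacement from a background of `N` genes of which `m` lie in the
#' pathway. Computed by summing exact point probabilities in log space.
#'
#' @param k observed overlap (DE genes in the pathway).
#' @param m pathway genes present in the background.
#' @param n DE genes in the background.
#' @param N background size.
#' @return the upper-tail probability, in (0, 1].
#' @export
hyperUpperTail <- function(k, m, n, N) {
    stopifnot(k >= 0, m >= 0, n >= 0, N >= m, N >= n, k <= min(m, n))
    if (k == 0L) return(1)
    i <- k:min(m, n)
    exp(.logSumExp(dhyper(i, m, N - m, n, log = TRUE)))
}

#' Over-representation scoring of a pathway collection
#'
#' Classical hypergeometric ORA: each pathway is scored by the upper-tail
#' probability of its overlap with the DE gene list, against the quantified
#' background universe of the integrated input. Benjamini-Hochberg
#' adjustment across the scored pathways.
#'
#' @param input an [IntegratedInput] with a DE gene set (intersection,
#'   union or single-layer mode).
#' @param coll a [PathwayCollection].
#' @param minOverlap minimum pathway size in the background for a pathway
#'   to be scored (default 1).
#' @return data.frame with one row per scored pathway: `pathway_id`, `k`,
#'   `m`, `n`, `N`, `p`, `p_adj`, sorted as supplied in the collection.
#' @examples
#' coll <- PathwayCollection(list(GeneSet("p1", c("A", "B", "C"))))
#' inp <- new("IntegratedInput", mode = "intersection",
#'            deGenes = c("A", "B"),
#'            combinedFc = c(A = 2, B = 1),
#'            background = c("A", "B", "C", "D", "E"),
#'            profile = c(A = 2, B = 1))
#' oraScore(inp, coll)
#' @export
oraScore <- function(input, coll, minOverlap = 1L) {
    stopifnot(is(input, "IntegratedInput"), is(coll, "PathwayCollection"))
    bg <- background(input)
    if (length(bg) == 0L) stop("empty background universe")
    de <- intersect(deGenes(input), bg)
    if (length(deGenes(input)) == 0L)
        warning("no DE genes; all over-representation p-values are 1")
    N <- length(bg); n <- length(de)
    rows <- lapply(coll@geneSets, function(gs) {
        memBg <- intersect(gs@members, bg)
        m <- length(memBg)
        if (m < minOverlap) return(NULL)
        k <- length(intersect(memBg, de))
        data.frame(pathway_id = gs@pathwayId, k = k, m = m, n = n, N = N,
                   p = hyperUpperTail(k, m, n, N),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(pathway_id = character(), k = integer(),
                          m = integer(), n = integer(), N = integer(),
                          p = numeric(), p_adj = numeric()))
    out$p_adj <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
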