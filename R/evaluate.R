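#' Normalize raw ranks to the 1-100 range
#'
#' `ceiling(100 * r / N)`: rank 1 maps to a value >= 1 and rank N maps to
#' 100, so rankings over collections of different sizes are comparable.
#' Lower is better.
#'
#' @param raw integer raw ranks (1..N).
#' @param N ranking length.
#' @return integer normalized ranks in 1..100.
#' @examples
#' normalizeRanks(c(1, 5, 250), 250)
#' @export
normalizeRanks <- function(raw, N) {
    stopifnot(N >= 1, all(raw >= 1), all(raw <= N))
    as.integer(ceiling(100 * raw / N))
}

#' Rank pathways from a scorer's output table
#'
#' Deterministic ranking keys per scorer: over-representation — ascending
#' `p`, ties by descending overlap `k`, then pathway id; running-sum
#' enrichment — ascending `p`, ties by descending `|NES|`, then id;
#' topology — ascending `pG`, ties by descending `|tA|`, then id (already
#' computed by [spiaScore()]).
#'
#' @param scores a data.frame from [oraScore()], [gseaScore()] or
#'   [spiaScore()].
#' @param method `"ora"`, `"gsea"` or `"spia"`.
#' @return data.frame with `pathway_id`, `raw_rank`, `norm_rank`, sorted
#'   by rank.
#' @export
rankScores <- function(scores, method = c("ora", "gsea", "spia")) {
    method <- match.arg(method)
    ord <- switch(method,
        ora = order(scores$p, -scores$k, scores$pathway_id,
                    method = "radix"),
        gsea = order(scores$p, -abs(scores$NES), scores$pathway_id,
                     method = "radix"),
        spia = order(scores$rank))
    N <- nrow(scores)
    data.frame(pathway_id = scores$pathway_id[ord],
               raw_rank = seq_len(N),
               norm_rank = normalizeRanks(seq_len(N), N),
               stringsAsFactors = FALSE)
}

.rankOf <- function(ranking, ids, normalized = TRUE) {
    col <- if (normalized) "norm_rank" else "raw_rank"
    ranking[[col]][match(ids, ranking$pathway_id)]
}

.fiveNum <- function(x) {
    q <- unname(quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
    setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Target-pathway rank report
#'
#' For each supplied ranking, looks up the normalized ranks of the target
#' pathways and summarizes them (min, Q1, median, Q3, max; the median of an
#' even count is the mean of the middle two). Targets absent from a ranking
#' are reported with rank `NA`, never silently dropped.
#'
#' @param rankings named list of ranking data.frames (from [rankScores()]);
#'   names identify the method/input-mode combination.
#' @param targets character vector of target pathway ids.
#' @return list with `ranks` (long data.frame: `ranking`, `pathway_id`,
#'   `norm_rank`), `summary` (one row per ranking with the five-number
#'   summary and `n_missing`), and `medians` (named numeric, for pairwise
#'   comparisons across modes).
#' @export
tpRankReport <- function(rankings, targets) {
    stopifnot(length(rankings) >= 1, length(targets) >= 1)
    if (is.null(names(rankings)))
        names(rankings) <- paste0("ranking", seq_along(rankings))
    long <- do.call(rbind, lapply(names(rankings), function(nm) {
        data.frame(ranking = nm, pathway_id = targets,
                   norm_rank = .rankOf(rankings[[nm]], targets),
                   stringsAsFactors = FALSE)
    }))
    summ <- do.call(rbind, lapply(names(rankings), function(nm) {
        r <- long$norm_rank[long$ranking == nm]
        miss <- sum(is.na(r))
        if (miss == length(r))
            fn <- setNames(rep(NA_real_, 5L),
                           c("min", "q1", "median", "q3", "max"))
        else fn <- .fiveNum(r)
        cbind(data.frame(ranking = nm, stringsAsFactors = FALSE),
              as.data.frame(as.list(fn)), n_missing = miss)
    }))
    rownames(summ) <- NULL
    list(ranks = long, summary = summ,
         medians = setNames(summ$median, summ$ranking))
}

#' Pathways common to every top-K
#'
#' @param rankings named list of ranking data.frames.
#' @param K top-list depth (must not exceed any ranking's length).
#' @return data.frame of the common pathway ids with each ranking's raw
#'   rank as a column.
#' @export
topKOverlap <- function(rankings, K) {
    stopifnot(length(rankings) >= 1)
    if (is.null(names(rankings)))
        names(rankings) <- paste0("ranking", seq_along(rankings))
    lens <- vapply(rankings, nrow, 0L)
    if (any(K > lens)) stop("K exceeds a ranking's length")
    tops <- lapply(rankings, function(r)
        r$pathway_id[r$raw_rank <= K])
    common <- Reduce(intersect, tops)
    out <- data.frame(pathway_id = common, stringsAsFactors = FALSE)
    for (nm in names(rankings))
        out[[paste0("rank_", nm)]] <- .rankOf(rankings[[nm]], common,
                                              normalized = FALSE)
    out
}

#' Compare subtype-specific rankings
#'
#' Venn region counts of the subtypes' top-K pathway sets (all
#' `2^s - 1` membership patterns) plus the per-target normalized rank in
#' each subtype's ranking.
#'
#' @param rankings named list (one ranking per subtype; at least two).
#' @param targets target pathway ids.
#' @param K top-list depth for the Venn regions (default 20).
#' @return list with `venn` (data.frame: `region` such as
#'   `"LumA&Basal"`, `count`), `targetRanks` (data.frame: targets x
#'   subtypes of normalized ranks), and `unionSize` (number of pathways in
#'   the union of the top-K sets; the Venn counts partition it).
#' @export
subtypeCompare <- function(rankings, targets, K = 20L) {
    stopifnot(length(rankings) >= 2L, !is.null(names(rankings)))
    lens <- vapply(rankings, nrow, 0L)
    if (any(K > lens)) stop("K exceeds a ranking's length")
    subtypes <- names(rankings)
    tops <- lapply(rankings, function(r) r$pathway_id[r$raw_rank <= K])
    un <- Reduce(union, tops)
    membership <- vapply(tops, function(tk) un %in% tk,
                         logical(length(un)))
    if (length(un) == 1L) membership <- matrix(membership, nrow = 1L)
    pattern <- apply(membership, 1L, function(z)
        paste(subtypes[z], collapse = "&"))
    allPatterns <- unlist(lapply(seq_along(subtypes), function(sz)
        apply(combn(subtypes, sz), 2L, paste, collapse = "&")))
    counts <- table(factor(pattern, levels = allPatterns))
    venn <- data.frame(region = names(counts),
                       count = as.integer(counts),
                       stringsAsFactors = FALSE)
    tr <- vapply(rankings, function(r) .rankOf(r, targets),
                 numeric(length(targets)))
    if (length(targets) == 1L)
        tr <- matrix(tr, nrow = 1L, dimnames = list(NULL, subtypes))
    targetRanks <- data.frame(pathway_id = targets, tr,
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
    list(venn = venn, targetRanks = targetRanks,
         unionSize = length(un))
}

#' Box-plot of target-pathway normalized ranks
#'
#' One box per ranking, mirroring the usual method-comparison display
#' (lower is better).
#'
#' @param report output of [tpRankReport()].
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @importFrom graphics boxplot
#' @export
plotTpRanks <- function(report, ...) {
    invisible(boxplot(norm_rank ~ ranking, data = report$ranks,
                      ylab = "normalized target-pathway rank",
                      xlab = "", las = 2, ...))
}
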