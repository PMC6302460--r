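#' Collapse a differential table to unique gene keys
#'
#' Protein tables may carry several isoform rows per gene; downstream
#' integration is gene-keyed. The row with the largest absolute log fold
#' change per gene is kept.
#'
#' @param tab differential table from [differentialTest()].
#' @param geneOf optional function mapping feature ids to gene symbols
#'   (default: identity).
#' @return a differential table with one row per gene, `feature` replaced
#'   by the gene symbol.
#' @export
collapseGenes <- function(tab, geneOf = identity) {
    genes <- geneOf(tab$feature)
    ord <- order(genes, -abs(tab$log_fc))
    keep <- ord[!duplicated(genes[ord])]
    keep <- keep[order(match(genes[keep], genes))]
    out <- tab[keep, , drop = FALSE]
    out$feature <- genes[keep]
    rownames(out) <- NULL
    out
}

.deSet <- function(tab) tab$feature[tab$is_de]

.fcMap <- function(tab) setNames(tab$log_fc, tab$feature)

.sortedProfile <- function(fc) {
    # descending by combined fold change; ties by gene symbol, then stable
    fc[order(-fc, names(fc), method = "radix")]
}

#' Integrate protein and phosphoprotein differential tables
#'
#' Builds the method-facing input under one of five modes:
#' \describe{
#'   \item{intersection}{DE genes = DE in both layers; each gene's combined
#'     fold change is the sum of its two log fold changes. The stringent
#'     integrated input for over-representation and topology scoring.}
#'   \item{union}{DE in either layer; genes DE in one layer take that
#'     layer's fold change, genes DE in both take the sum. A supported
#'     negative-control mode (noisy by construction).}
#'   \item{protein_only / phospho_only}{the single layer's DE set and fold
#'     changes.}
#'   \item{full_profile}{no DE set; the summed log fold changes over every
#'     gene quantified in both layers, sorted decreasing — the integrated
#'     ranked list for running-sum enrichment.}
#' }
#' For the integrated modes the ranked `profile` is always the both-layer
#' summed fold-change list; for single-layer modes it is that layer's own
#' fold-change list. The background universe is the both-layer overlap for
#' integrated modes and the layer's quantified genes for single-layer modes.
#'
#' Both tables must be gene-keyed (collapse isoforms/sites first; see
#' [collapseGenes()], [collapseSites()]).
#'
#' @param prot protein-level differential table.
#' @param phos phosphoprotein-level differential table.
#' @param mode integration mode (see Details).
#' @return an [IntegratedInput].
#' @examples
#' prot <- data.frame(feature = c("A", "B"), log_fc = c(1, -1),
#'                    t = 0, p = 0.01, p_adj = 0.01,
#'                    is_de = c(TRUE, TRUE), degenerate = FALSE)
#' phos <- data.frame(feature = c("A", "C"), log_fc = c(0.5, 2),
#'                    t = 0, p = 0.01, p_adj = 0.01,
#'                    is_de = c(TRUE, TRUE), degenerate = FALSE)
#' integrateTables(prot, phos, "union")
#' @export
integrateTables <- function(prot, phos,
                            mode = c("intersection", "union",
                                     "protein_only", "phospho_only",
                                     "full_profile")) {
    mode <- match.arg(mode)
    for (tb in list(prot, phos))
        if (anyDuplicated(tb$feature))
            stop("differential tables must be gene-keyed; collapse ",
                 "duplicate gene rows first (collapseGenes)")
    fcP <- .fcMap(prot); fcS <- .fcMap(phos)
    overlap <- intersect(prot$feature, phos$feature)
    sumFc <- .sortedProfile(fcP[overlap] + fcS[overlap])

    if (mode == "protein_only" || mode == "phospho_only") {
        tab <- if (mode == "protein_only") prot else phos
        de <- .deSet(tab)
        fc <- .fcMap(tab)
        return(new("IntegratedInput", mode = mode, deGenes = de,
                   combinedFc = fc[de], background = tab$feature,
                   profile = .sortedProfile(fc)))
    }
    if (length(overlap) == 0L)
        stop("no genes quantified in both layers")
    if (mode == "full_profile")
        return(new("IntegratedInput", mode = mode, deGenes = character(),
                   combinedFc = sumFc, background = overlap,
                   profile = sumFc))
    deP <- intersect(.deSet(prot), overlap)
    deS <- intersect(.deSet(phos), overlap)
    if (mode == "intersection") {
        de <- intersect(deP, deS)
        if (length(de) == 0L)
            warning("empty DE intersection between layers")
        fc <- setNames(fcP[de] + fcS[de], de)
    } else {  # union
        de <- union(deP, deS)
        fc <- setNames(numeric(length(de)), de)
        both <- intersect(deP, deS)
        fc[both] <- fcP[both] + fcS[both]
        onlyP <- setdiff(deP, deS); onlyS <- setdiff(deS, deP)
        fc[onlyP] <- fcP[onlyP]
        fc[onlyS] <- fcS[onlyS]
    }
    new("IntegratedInput", mode = mode, deGenes = de, combinedFc = fc,
        background = overlap, profile = sumFc)
}

#' Write an integrated input as TSV
#'
#' One row per background gene with its combined fold change (from the
#' ranked profile) and DE flag; the mode is recorded in a header comment.
#'
#' @param input an [IntegratedInput].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeIntegratedInput <- function(input, path) {
    prof <- rankedProfile(input)
    tab <- data.frame(gene = names(prof), combined_fc = unname(prof),
                      is_de = names(prof) %in% deGenes(input))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# mode=", input@mode), con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
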