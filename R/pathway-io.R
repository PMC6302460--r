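#' Construct a gene set
#'
#' @param pathwayId short pathway identifier (KEGG-style).
#' @param members character vector of gene symbols; duplicates collapsed.
#' @param name optional free-text pathway name.
#' @return a [GeneSet].
#' @examples
#' GeneSet("hsa04115", c("TP53", "MDM2"), name = "p53 signaling pathway")
#' @export
GeneSet <- function(pathwayId, members, name = "") {
    new("GeneSet", pathwayId = as.character(pathwayId),
        name = as.character(name), members = unique(as.character(members)))
}

#' Construct a pathway topology
#'
#' @param pathwayId pathway identifier.
#' @param members gene symbols; defaults to the union of edge endpoints.
#' @param edges data.frame with columns `from`, `to`, `relation`.
#' @param betaMap named numeric mapping relation type to signed weight.
#' @return a [PathwayTopology].
#' @export
PathwayTopology <- function(pathwayId, members = NULL,
                            edges = data.frame(from = character(),
                                               to = character(),
                                               relation = character()),
                            betaMap = defaultBetaMap()) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(members))
        members <- unique(c(edges$from, edges$to))
    new("PathwayTopology", pathwayId = as.character(pathwayId),
        members = as.character(members), edges = edges,
        betaMap = betaMap)
}

#' Construct a pathway collection
#'
#' @param geneSets list of [GeneSet] objects (names taken from their ids).
#' @param topologies optional named list of [PathwayTopology].
#' @param targetIds optional target pathway ids.
#' @return a [PathwayCollection].
#' @export
PathwayCollection <- function(geneSets = list(), topologies = list(),
                              targetIds = character()) {
    if (length(geneSets) && is.null(names(geneSets)))
        names(geneSets) <- vapply(geneSets, slot, "", "pathwayId")
    new("PathwayCollection", geneSets = geneSets, topologies = topologies,
        targetIds = as.character(targetIds))
}

#' Default relation weights
#'
#' Signed weights for the perturbation model: +1 for activation-like,
#' -1 for inhibition-like relation types, the standard convention for
#' KEGG-derived signed signaling edges.
#'
#' @return named numeric vector.
#' @export
defaultBetaMap <- function() {
    c(activation = 1, expression = 1, phosphorylation = 1,
      inhibition = -1, repression = -1, dephosphorylation = -1)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set exchange format: one pathway per line,
#' fields are id, description, then one gene symbol per field. Duplicate
#' symbols within a line are collapsed.
#'
#' @param path path to a GMT file.
#' @param targetIds optional character vector of ids to flag as target
#'   pathways.
#' @return a [PathwayCollection] (gene sets only).
#' @seealso [writeGMT()], [readTargets()]
#' @export
readGMT <- function(path, targetIds = character()) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("malformed GMT line ", i, ": fewer than 3 tab-separated ",
                 "fields")
        genes <- unique(f[-(1:2)])
        genes <- genes[nzchar(genes)]
        if (length(genes) == 0L)
            stop("malformed GMT line ", i, ": no gene symbols")
        sets[[i]] <- GeneSet(f[1], genes, name = f[2])
    }
    ids <- vapply(sets, slot, "", "pathwayId")
    if (anyDuplicated(ids))
        stop("duplicate pathway ids in GMT file: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(sets) <- ids
    PathwayCollection(geneSets = sets,
                      targetIds = intersect(targetIds, ids))
}

#' Write gene sets to a GMT file
#'
#' @param coll a [PathwayCollection].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(coll, path) {
    stopifnot(is(coll, "PathwayCollection"))
    lines <- vapply(coll@geneSets, function(gs) {
        nm <- if (length(gs@name) && nzchar(gs@name[1])) gs@name[1] else
            gs@pathwayId
        paste(c(gs@pathwayId, nm, gs@members), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a target-pathway id list
#'
#' One pathway id per line; blank lines and `#` comments ignored. The
#' packaged fixture `targets_breast.txt` holds the twelve literature-curated
#' breast-cancer target pathways used as positive controls in rank
#' evaluation.
#'
#' @param path path to the id list; defaults to the packaged breast-cancer
#'   target list.
#' @return character vector of pathway ids.
#' @examples
#' readTargets()
#' @export
readTargets <- function(path = system.file("extdata", "targets_breast.txt",
                                           package = "intePath")) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a signed pathway edge list
#'
#' Flat TSV interchange format for pathway topologies, one edge per row:
#' `pathway_id<TAB>source<TAB>target<TAB>relation`, with a header row.
#' Rows whose relation is `member` declare an isolated member gene (the
#' `target` field is ignored). Members are inferred as the union of edge
#' endpoints plus the declared isolated members. Unknown relation types are
#' rejected.
#'
#' @param path path to the edge-list TSV.
#' @param betaMap named numeric mapping relation type to signed weight.
#' @return named list of [PathwayTopology], keyed by pathway id.
#' @seealso [writeTopologyTable()], [influenceMatrix()]
#' @export
readTopologyTable <- function(path, betaMap = defaultBetaMap()) {
    if (!file.exists(path)) stop("edge-list file not found: ", path)
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("pathway_id", "source", "target", "relation")
    if (!all(need %in% colnames(tab)))
        stop("edge list must have columns: ", paste(need, collapse = ", "))
    unknown <- setdiff(unique(tab$relation), c(names(betaMap), "member"))
    if (length(unknown))
        stop("relation type(s) not in beta configuration: ",
             paste(unknown, collapse = ", "))
    nself <- sum(tab$source == tab$target & tab$relation != "member")
    if (nself > 0)
        message("note: ", nself, " self-loop edge(s) retained")
    out <- lapply(split(tab, tab$pathway_id), function(sub) {
        isMember <- sub$relation == "member"
        ed <- sub[!isMember, c("source", "target", "relation")]
        names(ed) <- c("from", "to", "relation")
        rownames(ed) <- NULL
        mem <- unique(c(ed$from, ed$to, sub$source[isMember]))
        PathwayTopology(sub$pathway_id[1], members = mem, edges = ed,
                        betaMap = betaMap)
    })
    out[unique(tab$pathway_id)]
}

#' Write pathway topologies as a signed edge list
#'
#' @param topologies named list of [PathwayTopology].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTopologyTable <- function(topologies, path) {
    rows <- lapply(topologies, function(tp) {
        ed <- tp@edges
        iso <- setdiff(tp@members, unique(c(ed$from, ed$to)))
        rbind(
            if (nrow(ed)) data.frame(pathway_id = tp@pathwayId,
                                     source = ed$from, target = ed$to,
                                     relation = ed$relation),
            if (length(iso)) data.frame(pathway_id = tp@pathwayId,
                                        source = iso, target = iso,
                                        relation = "member"))
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        tab <- data.frame(pathway_id = character(), source = character(),
                          target = character(), relation = character())
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Normalized influence matrix of a pathway topology
#'
#' The propagation weight matrix of the perturbation model:
#' `B[i, j] = beta(j -> i) / Nds(j)`, where `beta` is the signed weight of
#' the edge from gene j to gene i and `Nds(j)` is the number of outgoing
#' edges of j. Parallel edges between the same pair sum their weights.
#' Genes with no outgoing edges contribute zero columns; a topology with no
#' edges yields the zero matrix.
#'
#' @param topology a [PathwayTopology].
#' @return a |members| x |members| numeric matrix with dimnames equal to
#'   the member genes.
#' @seealso [netAccumulation()]
#' @export
influenceMatrix <- function(topology) {
    stopifnot(is(topology, "PathwayTopology"))
    mem <- topology@members
    B <- matrix(0, length(mem), length(mem), dimnames = list(mem, mem))
    ed <- topology@edges
    if (nrow(ed) == 0L) return(B)
    beta <- unname(topology@betaMap[ed$relation])
    nds <- table(factor(ed$from, levels = mem))
    for (r in seq_len(nrow(ed))) {
        B[ed$to[r], ed$from[r]] <- B[ed$to[r], ed$from[r]] +
            beta[r] / as.numeric(nds[[ed$from[r]]])
    }
    B
}
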