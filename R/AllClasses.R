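#' @import methods
#' @importFrom stats median quantile rnorm runif setNames p.adjust pt dhyper
#'   phyper sd
#' @importFrom utils read.delim write.table combn head
#' @useDynLib intePath, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Gene set
#'
#' A named collection of gene symbols belonging to one pathway, identified by
#' a short KEGG-style id (e.g. \code{"hsa04115"}).
#'
#' @slot pathwayId single pathway identifier, unique within a collection.
#' @slot name free-text pathway name.
#' @slot members character vector of unique gene symbols; non-empty.
#'
#' @seealso [readGMT()], [PathwayCollection]
#' @export
setClass("GeneSet",
    representation(pathwayId = "character", name = "character",
                   members = "character"))

setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId))
        msg <- c(msg, "pathwayId must be a single non-empty string")
    if (length(object@members) == 0L)
        msg <- c(msg, "members must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must not contain duplicates")
    if (any(!nzchar(object@members)))
        msg <- c(msg, "members must not contain empty symbols")
    if (is.null(msg)) TRUE else msg
})

#' Pathway topology
#'
#' Gene membership plus a signed, typed, directed edge list for one pathway.
#' Each relation type maps to a signed real weight (beta), typically +1 for
#' activation-like and -1 for inhibition-like interactions; these weights
#' drive the perturbation-propagation model (see [influenceMatrix()]).
#'
#' @slot pathwayId single pathway identifier.
#' @slot members ordered character vector of gene symbols.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{relation}; endpoints must be members.
#' @slot betaMap named numeric: relation type -> signed weight.
#'
#' @export
setClass("PathwayTopology",
    representation(pathwayId = "character", members = "character",
                   edges = "data.frame", betaMap = "numeric"))

setValidity("PathwayTopology", function(object) {
    msg <- NULL
    if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId))
        msg <- c(msg, "pathwayId must be a single non-empty string")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must not contain duplicates")
    ed <- object@edges
    if (!all(c("from", "to", "relation") %in% colnames(ed)))
        msg <- c(msg, "edges must have columns from, to, relation")
    else {
        bad <- setdiff(unique(c(ed$from, ed$to)), object@members)
        if (length(bad))
            msg <- c(msg, paste0("edge endpoints not in members: ",
                                 paste(head(bad, 5L), collapse = ", ")))
        missing_rel <- setdiff(unique(ed$relation), names(object@betaMap))
        if (length(missing_rel))
            msg <- c(msg, paste0("relation types missing from betaMap: ",
                                 paste(missing_rel, collapse = ", ")))
    }
    if (length(object@betaMap) && any(!is.finite(object@betaMap)))
        msg <- c(msg, "betaMap weights must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Pathway collection
#'
#' Gene sets for a whole pathway database, optional topologies for a subset
#' of them, and the ids flagged as target pathways (literature-curated
#' positive controls for rank evaluation).
#'
#' @slot geneSets named list of [GeneSet]; names are the pathway ids.
#' @slot topologies named list of [PathwayTopology] covering a subset of the
#'   gene-set ids; each topology's members must equal its gene set's members.
#' @slot targetIds character vector of target pathway ids, a subset of the
#'   gene-set ids.
#'
#' @seealso [readGMT()], [readTopologyTable()], [readTargets()]
#' @export
setClass("PathwayCollection",
    representation(geneSets = "list", topologies = "list",
                   targetIds = "character"))

setValidity("PathwayCollection", function(object) {
    msg <- NULL
    gs <- object@geneSets
    if (length(gs)) {
        if (is.null(names(gs)) || anyDuplicated(names(gs)))
            msg <- c(msg, "geneSets must be uniquely named by pathway id")
        ok <- vapply(gs, is, logical(1), class2 = "GeneSet")
        if (!all(ok)) msg <- c(msg, "geneSets must all be GeneSet objects")
        else if (!is.null(names(gs)) &&
                 !identical(names(gs),
                            unname(vapply(gs, slot, "", "pathwayId"))))
            msg <- c(msg, "geneSets names must equal their pathwayId slots")
    }
    tp <- object@topologies
    if (length(tp)) {
        if (!all(names(tp) %in% names(gs)))
            msg <- c(msg, "topologies must refer to known pathway ids")
        for (id in names(tp)) {
            if (!is(tp[[id]], "PathwayTopology")) {
                msg <- c(msg, "topologies must all be PathwayTopology objects")
                break
            }
            if (!setequal(tp[[id]]@members, gs[[id]]@members)) {
                msg <- c(msg, paste0("topology members differ from gene set ",
                                     "members for ", id))
            }
        }
    }
    if (length(object@targetIds) &&
        !all(object@targetIds %in% names(gs)))
        msg <- c(msg, "targetIds must be a subset of the gene-set ids")
    if (is.null(msg)) TRUE else msg
})

#' Integrated differential input
#'
#' The method-facing product of combining the protein-level and
#' phosphoprotein-level differential tables. Over-representation and
#' topology scoring consume \code{deGenes}/\code{combinedFc}; running-sum
#' enrichment consumes the full ranked \code{profile}.
#'
#' @slot mode one of \code{"intersection"}, \code{"union"},
#'   \code{"protein_only"}, \code{"phospho_only"}, \code{"full_profile"}.
#' @slot deGenes character vector of differentially abundant gene symbols
#'   under the mode's rule (empty for \code{full_profile}).
#' @slot combinedFc named numeric of (summed) log fold changes for
#'   \code{deGenes}.
#' @slot background character vector: the quantified gene universe for the
#'   mode (both-layer overlap for integrated modes, the layer's genes for
#'   single-layer modes).
#' @slot profile named numeric: the full ranked log-fold-change profile,
#'   sorted decreasing (ties broken by gene symbol).
#'
#' @seealso [integrateTables()]
#' @export
setClass("IntegratedInput",
    representation(mode = "character", deGenes = "character",
                   combinedFc = "numeric", background = "character",
                   profile = "numeric"))

setValidity("IntegratedInput", function(object) {
    msg <- NULL
    modes <- c("intersection", "union", "protein_only", "phospho_only",
               "full_profile")
    if (length(object@mode) != 1L || !object@mode %in% modes)
        msg <- c(msg, paste0("mode must be one of: ",
                             paste(modes, collapse = ", ")))
    if (!all(object@deGenes %in% object@background))
        msg <- c(msg, "deGenes must be a subset of background")
    if (length(object@deGenes) &&
        !all(object@deGenes %in% names(object@combinedFc)))
        msg <- c(msg, "combinedFc must cover every DE gene")
    if (any(!is.finite(object@combinedFc)))
        msg <- c(msg, "combinedFc must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Simulation configuration
#'
#' Parameters of the synthetic paired proteome/phosphoproteome study.
#' Construct with [simConfig()], which supplies defaults.
#'
#' @slot nPathways number of pathways in the simulated collection.
#' @slot nGenes size of the shared gene universe.
#' @slot sizeRange integer (min, max) pathway sizes.
#' @slot edgeDensity expected directed edges per gene in each topology.
#' @slot nPlanted number of globally perturbed (planted) pathways.
#' @slot delta mean log-scale group shift applied to perturbed genes.
#' @slot layerSplit fraction (lambda) of single-layer planted genes whose
#'   shift goes to the protein layer; the remainder go to the phospho layer.
#' @slot overlapFrac fraction of planted genes shifted in both layers.
#' @slot decoyFrac fraction of pathways per layer receiving a layer-specific
#'   spurious perturbation of magnitude delta (models single-omics noise;
#'   zero decoys when delta is zero).
#' @slot sitesPerGeneRange integer (min, max) phosphosites per gene.
#' @slot nTumor,nNormal sample counts per group.
#' @slot noiseSd per-measurement Gaussian noise standard deviation (sigma).
#' @slot mu0 grand mean of per-gene baseline log abundance.
#' @slot missingQuantile tau: values below the global tau-quantile of each
#'   matrix are censored to missing (low-abundance MNAR missingness).
#' @slot subtypeSpec optional named list: subtype label -> pathway ids
#'   planted only in that subtype's tumors. Tumor samples are split evenly
#'   over the subtype labels.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SimConfig",
    representation(nPathways = "integer", nGenes = "integer",
                   sizeRange = "integer", edgeDensity = "numeric",
                   nPlanted = "integer", delta = "numeric",
                   layerSplit = "numeric", overlapFrac = "numeric",
                   decoyFrac = "numeric", sitesPerGeneRange = "integer",
                   nTumor = "integer", nNormal = "integer",
                   noiseSd = "numeric", mu0 = "numeric",
                   missingQuantile = "numeric", subtypeSpec = "list",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@nPlanted < 0L || object@nPlanted > object@nPathways)
        msg <- c(msg, "need 0 <= nPlanted <= nPathways")
    if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
    if (object@missingQuantile < 0 || object@missingQuantile >= 1)
        msg <- c(msg, "missingQuantile must be in [0, 1)")
    if (object@layerSplit < 0 || object@layerSplit > 1)
        msg <- c(msg, "layerSplit must be in [0, 1]")
    if (object@overlapFrac < 0 || object@overlapFrac > 1)
        msg <- c(msg, "overlapFrac must be in [0, 1]")
    if (object@decoyFrac < 0 || object@decoyFrac > 1)
        msg <- c(msg, "decoyFrac must be in [0, 1]")
    if (length(object@sizeRange) != 2L || any(object@sizeRange < 1L) ||
        object@sizeRange[1] > object@sizeRange[2])
        msg <- c(msg, "sizeRange must be an increasing positive pair")
    if (object@sizeRange[2] > object@nGenes)
        msg <- c(msg, "gene universe too small for the largest pathway")
    if (length(object@sitesPerGeneRange) != 2L ||
        any(object@sitesPerGeneRange < 1L) ||
        object@sitesPerGeneRange[1] > object@sitesPerGeneRange[2])
        msg <- c(msg, "sitesPerGeneRange must be an increasing positive pair")
    if (object@nTumor < 1L || object@nNormal < 1L)
        msg <- c(msg, "need at least one sample per group")
    if (length(object@subtypeSpec) &&
        is.null(names(object@subtypeSpec)))
        msg <- c(msg, "subtypeSpec must be a named list")
    if (is.null(msg)) TRUE else msg
})

#' Simulation ground truth
#'
#' Which pathways carry planted signal, which layer each perturbed gene's
#' shift went to, and the per-layer decoy pathways.
#'
#' @slot plantedIds ids of globally planted pathways.
#' @slot geneTable data.frame with columns \code{gene}, \code{pathway},
#'   \code{layer} (\code{protein}, \code{phospho} or \code{both}),
#'   \code{sign} (+1/-1, topology-propagated), \code{scope} (\code{global},
#'   a subtype label, or \code{decoy_protein}/\code{decoy_phospho}).
#' @slot decoyProtein,decoyPhospho pathway ids with layer-specific spurious
#'   perturbation.
#' @slot subtypePlanted named list: subtype -> pathway ids planted only
#'   there.
#'
#' @export
setClass("SimTruth",
    representation(plantedIds = "character", geneTable = "data.frame",
                   decoyProtein = "character", decoyPhospho = "character",
                   subtypePlanted = "list"))

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet", object@pathwayId,
        if (length(object@name) && nzchar(object@name[1]))
            paste0("(", object@name[1], ")") else "",
        "with", length(object@members), "members\n")
})

setMethod("show", "PathwayTopology", function(object) {
    cat("PathwayTopology", object@pathwayId, "with",
        length(object@members), "members and", nrow(object@edges),
        "edges\n")
})

setMethod("show", "PathwayCollection", function(object) {
    cat("PathwayCollection with", length(object@geneSets), "gene sets,",
        length(object@topologies), "topologies,",
        length(object@targetIds), "target pathways\n")
})

setMethod("show", "IntegratedInput", function(object) {
    cat("IntegratedInput [", object@mode, "]: ",
        length(object@deGenes), " DE genes over a background of ",
        length(object@background), " genes; ranked profile of ",
        length(object@profile), " genes\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nPathways, "pathways /", object@nGenes,
        "genes;", object@nPlanted, "planted (delta =", object@delta,
        "); samples", object@nTumor, "tumor vs", object@nNormal,
        "normal; seed", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@plantedIds), "planted pathways,",
        length(object@decoyProtein), "+", length(object@decoyPhospho),
        "layer decoys,", length(object@subtypePlanted),
        "subtype-specific sets\n")
})
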