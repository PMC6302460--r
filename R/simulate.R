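#' Simulation configuration with study defaults
#'
#' Defaults describe the package's reference synthetic study: 200 pathways
#' of 15-40 genes over a 3000-gene universe, 5 planted pathways with a
#' log-scale shift of delta = 2 against unit measurement noise
#' (delta = 2 sigma), the planted signal split evenly between the protein
#' and phospho layers (lambda = 0.5) with 30% of planted genes shifted in
#' both layers, 10% of pathways per layer carrying a layer-specific decoy
#' perturbation (the single-omics noise that integration is meant to
#' filter), 1-4 phosphosites per gene, a balanced 20 vs 20 tumor/normal
#' design, and 5% low-abundance censoring. See the methods vignette for the
#' rationale behind each default.
#'
#' @param nPathways,nGenes,sizeRange,edgeDensity,nPlanted,delta,layerSplit
#'   see [SimConfig].
#' @param overlapFrac,decoyFrac,sitesPerGeneRange,nTumor,nNormal,noiseSd
#'   see [SimConfig].
#' @param mu0,missingQuantile,subtypeSpec,seed see [SimConfig].
#' @return a validated [SimConfig].
#' @examples
#' simConfig(nPathways = 20, nGenes = 300, seed = 7)
#' @export
simConfig <- function(nPathways = 200L, nGenes = 3000L,
                      sizeRange = c(15L, 40L), edgeDensity = 1.5,
                      nPlanted = 5L, delta = 2, layerSplit = 0.5,
                      overlapFrac = 0.3, decoyFrac = 0.1,
                      sitesPerGeneRange = c(1L, 4L), nTumor = 20L,
                      nNormal = 20L, noiseSd = 1, mu0 = 20,
                      missingQuantile = 0.05, subtypeSpec = list(),
                      seed = 1L) {
    new("SimConfig", nPathways = as.integer(nPathways),
        nGenes = as.integer(nGenes), sizeRange = as.integer(sizeRange),
        edgeDensity = edgeDensity, nPlanted = as.integer(nPlanted),
        delta = delta, layerSplit = layerSplit, overlapFrac = overlapFrac,
        decoyFrac = decoyFrac,
        sitesPerGeneRange = as.integer(sitesPerGeneRange),
        nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
        noiseSd = noiseSd, mu0 = mu0, missingQuantile = missingQuantile,
        subtypeSpec = subtypeSpec, seed = as.integer(seed))
}

.geneUniverse <- function(cfg) sprintf("G%04d", seq_len(cfg@nGenes))

.sampleRange <- function(range, n) {
    if (range[1] == range[2]) rep(range[1], n)
    else sample(seq(range[1], range[2]), n, replace = TRUE)
}

.simCollection <- function(cfg) {
    universe <- .geneUniverse(cfg)
    ids <- sprintf("P%03d", seq_len(cfg@nPathways))
    sizes <- .sampleRange(cfg@sizeRange, cfg@nPathways)
    beta <- c(activation = 1, inhibition = -1)
    sets <- vector("list", cfg@nPathways)
    tops <- vector("list", cfg@nPathways)
    for (i in seq_len(cfg@nPathways)) {
        mem <- sample(universe, sizes[i])
        nE <- round(cfg@edgeDensity * sizes[i])
        ed <- data.frame(from = character(), to = character(),
                         relation = character())
        if (nE > 0) {
            from <- sample(mem, nE, replace = TRUE)
            to <- sample(mem, nE, replace = TRUE)
            rel <- sample(c("activation", "inhibition"), nE,
                          replace = TRUE, prob = c(0.8, 0.2))
            keep <- from != to & !duplicated(paste(from, to))
            ed <- data.frame(from = from[keep], to = to[keep],
                             relation = rel[keep],
                             stringsAsFactors = FALSE)
        }
        sets[[i]] <- GeneSet(ids[i], mem,
                             name = paste("Simulated pathway", i))
        tops[[i]] <- PathwayTopology(ids[i], members = mem, edges = ed,
                                     betaMap = beta)
    }
    names(sets) <- ids
    names(tops) <- ids
    PathwayCollection(geneSets = sets, topologies = tops)
}

#' Simulate a pathway collection
#'
#' Draws `nPathways` gene sets of sizes uniform in `sizeRange` from a
#' shared gene universe (genes may belong to several pathways), each with a
#' random directed signed topology of expected `edgeDensity` edges per
#' gene; relations are activation/inhibition with probability 0.8/0.2.
#' Deterministic under the config seed.
#'
#' @param cfg a [SimConfig].
#' @return a [PathwayCollection] with topologies for every pathway.
#' @export
simulateCollection <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(cfg@seed)
    .simCollection(cfg)
}

# Topology-propagated perturbation signs: breadth-first from the pathway's
# first member (the designated root), neighbors explored in member order,
# sign = product of edge beta signs along the first discovered (shortest)
# path; genes unreached from the root default to +1.
.signProp <- function(tp) {
    mem <- tp@members
    sgn <- setNames(rep(1, length(mem)), mem)
    ed <- tp@edges
    if (nrow(ed) == 0L) return(sgn)
    beta <- sign(tp@betaMap[ed$relation])
    adj <- split(seq_len(nrow(ed)), factor(ed$from, levels = mem))
    visited <- setNames(logical(length(mem)), mem)
    root <- mem[1]
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
        cur <- queue[1]
        queue <- queue[-1]
        outs <- adj[[cur]]
        if (length(outs)) {
            tgt <- ed$to[outs]
            ord <- order(match(tgt, mem))
            for (j in outs[ord]) {
                child <- ed$to[j]
                if (!visited[child]) {
                    visited[child] <- TRUE
                    sgn[child] <- sgn[cur] * beta[j]
                    queue <- c(queue, child)
                }
            }
        }
    }
    sgn
}

.assignLayers <- function(mem, cfg) {
    n <- length(mem)
    nOv <- round(cfg@overlapFrac * n)
    nP <- round(cfg@layerSplit * (n - nOv))
    layer <- rep("phospho", n)
    if (nOv > 0) layer[seq_len(nOv)] <- "both"
    if (nP > 0) layer[nOv + seq_len(nP)] <- "protein"
    setNames(layer, mem)
}

.planTruth <- function(cfg, coll) {
    ids <- pathwayIds(coll)
    subtypeIds <- unique(unlist(cfg@subtypeSpec))
    if (length(subtypeIds) && !all(subtypeIds %in% ids))
        stop("subtypeSpec names unknown pathway ids")
    free <- setdiff(ids, subtypeIds)
    planted <- sort(sample(free, cfg@nPlanted))
    free <- setdiff(free, planted)
    nDecoy <- round(cfg@decoyFrac * cfg@nPathways)
    if (2L * nDecoy > length(free))
        stop("not enough pathways left for the requested decoy fraction")
    decoyP <- sort(sample(free, nDecoy))
    decoyS <- sort(sample(setdiff(free, decoyP), nDecoy))
    rows <- list()
    claimed <- character()
    addPathway <- function(id, layers, scope) {
        tp <- coll@topologies[[id]]
        mem <- members(geneSets(coll)[[id]])
        sgn <- if (!is.null(tp)) .signProp(tp)
               else setNames(rep(1, length(mem)), mem)
        newGenes <- setdiff(mem, claimed)
        if (length(newGenes) == 0L) return(NULL)
        data.frame(gene = newGenes, pathway = id,
                   layer = unname(layers[newGenes]),
                   sign = unname(sgn[newGenes]), scope = scope,
                   stringsAsFactors = FALSE)
    }
    for (id in planted) {
        mem <- members(geneSets(coll)[[id]])
        r <- addPathway(id, .assignLayers(mem, cfg), "global")
        if (!is.null(r)) { rows <- c(rows, list(r)); claimed <- c(claimed, r$gene) }
    }
    for (st in names(cfg@subtypeSpec)) {
        for (id in cfg@subtypeSpec[[st]]) {
            mem <- members(geneSets(coll)[[id]])
            r <- addPathway(id, .assignLayers(mem, cfg), st)
            if (!is.null(r)) { rows <- c(rows, list(r)); claimed <- c(claimed, r$gene) }
        }
    }
    for (id in decoyP) {
        mem <- members(geneSets(coll)[[id]])
        r <- addPathway(id, setNames(rep("protein", length(mem)), mem),
                        "decoy_protein")
        if (!is.null(r)) { rows <- c(rows, list(r)); claimed <- c(claimed, r$gene) }
    }
    for (id in decoyS) {
        mem <- members(geneSets(coll)[[id]])
        r <- addPathway(id, setNames(rep("phospho", length(mem)), mem),
                        "decoy_phospho")
        if (!is.null(r)) { rows <- c(rows, list(r)); claimed <- c(claimed, r$gene) }
    }
    geneTable <- if (length(rows)) do.call(rbind, rows)
        else data.frame(gene = character(), pathway = character(),
                        layer = character(), sign = numeric(),
                        scope = character(), stringsAsFactors = FALSE)
    rownames(geneTable) <- NULL
    new("SimTruth", plantedIds = planted, geneTable = geneTable,
        decoyProtein = decoyP, decoyPhospho = decoyS,
        subtypePlanted = cfg@subtypeSpec)
}

#' Plan the planted-signal ground truth
#'
#' Chooses the planted pathways, the per-layer decoy pathways and, per
#' perturbed gene, the layer carrying its shift and the
#' topology-propagated sign. Genes belonging to more than one perturbed
#' pathway are claimed by the first pathway processed (global planted,
#' then subtype-planted, then decoys), deterministically.
#'
#' @param cfg a [SimConfig].
#' @param coll the collection from [simulateCollection()].
#' @return a [SimTruth].
#' @export
simulateTruth <- function(cfg, coll) {
    stopifnot(is(cfg, "SimConfig"), is(coll, "PathwayCollection"))
    set.seed(cfg@seed)
    .planTruth(cfg, coll)
}

.simAbundances <- function(cfg, coll, truth) {
    universe <- .geneUniverse(cfg)
    nT <- cfg@nTumor; nN <- cfg@nNormal
    samples <- c(sprintf("T%02d", seq_len(nT)), sprintf("N%02d", seq_len(nN)))
    groups <- rep(c("tumor", "normal"), c(nT, nN))
    subtypes <- NULL
    if (length(cfg@subtypeSpec)) {
        labels <- names(cfg@subtypeSpec)
        subtypes <- c(rep(labels, length.out = nT), rep(NA, nN))
    }
    tumorCols <- which(groups == "tumor")
    shiftCols <- function(scope) {
        if (scope %in% c("global", "decoy_protein", "decoy_phospho"))
            tumorCols
        else tumorCols[subtypes[tumorCols] == scope]
    }
    nS <- length(samples)
    mu <- setNames(rnorm(cfg@nGenes, cfg@mu0, 1), universe)
    shiftP <- matrix(0, cfg@nGenes, nS, dimnames = list(universe, samples))
    shiftS <- shiftP
    gt <- truth@geneTable
    for (r in seq_len(nrow(gt))) {
        val <- cfg@delta * gt$sign[r]
        cols <- shiftCols(gt$scope[r])
        if (gt$layer[r] %in% c("protein", "both"))
            shiftP[gt$gene[r], cols] <- shiftP[gt$gene[r], cols] + val
        if (gt$layer[r] %in% c("phospho", "both"))
            shiftS[gt$gene[r], cols] <- shiftS[gt$gene[r], cols] + val
    }
    prot <- mu + shiftP +
        matrix(rnorm(cfg@nGenes * nS, 0, cfg@noiseSd), cfg@nGenes, nS)
    dimnames(prot) <- list(universe, samples)

    nSites <- .sampleRange(cfg@sitesPerGeneRange, cfg@nGenes)
    geneOfSite <- rep(seq_len(cfg@nGenes), nSites)
    siteIds <- paste0(universe[geneOfSite], "_S",
                      unlist(lapply(nSites, seq_len)))
    offset <- rnorm(length(siteIds), 0, 1)
    phos <- mu[geneOfSite] + shiftS[geneOfSite, , drop = FALSE] + offset +
        matrix(rnorm(length(siteIds) * nS, 0, cfg@noiseSd),
               length(siteIds), nS)
    dimnames(phos) <- list(siteIds, samples)

    censor <- function(m) {
        if (cfg@missingQuantile <= 0) return(m)
        q <- quantile(m, cfg@missingQuantile)
        m[m < q] <- NA
        m
    }
    list(protein = makeAbundanceSE(censor(prot), groups, subtypes),
         phospho = makeAbundanceSE(censor(phos), groups, subtypes))
}

#' Simulate paired protein and phosphosite abundance matrices
#'
#' Log-scale abundances: per-gene baseline `Normal(mu0, 1)`, tumor samples
#' of perturbed genes shifted by `+/- delta` (sign propagated along the
#' topology from the pathway root), per-measurement noise
#' `Normal(0, noiseSd)`. Each gene emits 1 or more phosphosite rows
#' (`GENE_S1`, `GENE_S2`, ...) equal to the gene value plus a fixed site
#' offset plus noise; a gene's shift reaches only the layer(s) the truth
#' assigns it to. Values below the global `missingQuantile` of each matrix
#' are censored to missing. Deterministic under the config seed.
#'
#' @param cfg a [SimConfig].
#' @param coll collection from [simulateCollection()].
#' @param truth ground truth from [simulateTruth()].
#' @return list with elements `protein` and `phospho` (abundance
#'   SummarizedExperiments).
#' @export
simulateAbundances <- function(cfg, coll, truth) {
    stopifnot(is(cfg, "SimConfig"), is(truth, "SimTruth"))
    set.seed(cfg@seed)
    .simAbundances(cfg, coll, truth)
}

#' Simulate a complete synthetic study
#'
#' One call drawing the collection, the ground truth and the paired
#' abundance matrices from a single seeded RNG stream. The planted pathway
#' ids are flagged as the collection's target pathways.
#'
#' @param cfg a [SimConfig].
#' @return list with `collection`, `truth`, `protein`, `phospho`, and
#'   `config`.
#' @examples
#' study <- simulateStudy(simConfig(nPathways = 10, nGenes = 200,
#'                                  nPlanted = 2, seed = 42))
#' study$collection
#' @export
simulateStudy <- function(cfg = simConfig()) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(cfg@seed)
    coll <- .simCollection(cfg)
    truth <- .planTruth(cfg, coll)
    ab <- .simAbundances(cfg, coll, truth)
    targetIds(coll) <- truth@plantedIds
    list(collection = coll, truth = truth, protein = ab$protein,
         phospho = ab$phospho, config = cfg)
}

#' Write a simulated study to disk
#'
#' Writes `protein.tsv` and `phospho.tsv` (features x samples),
#' `samples.tsv` (sample, group, subtype), `pathways.gmt`, `edges.tsv`
#' (signed edge list), `targets.txt` (planted pathway ids) and
#' `truth.yaml`.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeAbundanceMatrix(study$protein, p("protein.tsv"), p("samples.tsv"))
    writeAbundanceMatrix(study$phospho, p("phospho.tsv"),
                         idColumn = "phosphosite")
    writeGMT(study$collection, p("pathways.gmt"))
    writeTopologyTable(topologies(study$collection), p("edges.tsv"))
    writeLines(study$truth@plantedIds, p("targets.txt"))
    tr <- study$truth
    yaml::write_yaml(list(
        planted = as.list(tr@plantedIds),
        decoy_protein = as.list(tr@decoyProtein),
        decoy_phospho = as.list(tr@decoyPhospho),
        subtype_planted = tr@subtypePlanted,
        genes = lapply(seq_len(nrow(tr@geneTable)), function(i)
            as.list(tr@geneTable[i, ]))), p("truth.yaml"))
    invisible(dir)
}
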