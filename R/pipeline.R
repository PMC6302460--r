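.dropAllMissing <- function(se, label = "features") {
    m <- assay(se, "abundance")
    bad <- rowSums(!is.na(m)) == 0L
    if (any(bad)) {
        message("dropping ", sum(bad), " fully-missing ", label)
        se <- se[!bad, ]
    }
    se
}

#' Run the full integrative pathway-prioritization workflow
#'
#' Executes the pipeline stages in order: minimum-value imputation of both
#' layers, phosphosite-to-gene collapse, per-layer differential testing
#' with Benjamini-Hochberg control, layer integration under the requested
#' mode, pathway scoring by the requested methods, ranking, and (when
#' target pathways are known) the target-rank evaluation report. With the
#' same inputs and seed, reruns are byte-identical.
#'
#' In the integrated modes, over-representation and topology scoring use
#' the mode's DE gene set with summed fold changes while running-sum
#' enrichment uses the full summed fold-change profile over the
#' both-layer overlap; in single-layer modes every method sees that layer
#' only.
#'
#' @param protein protein-level abundance SummarizedExperiment.
#' @param phospho phosphosite-level abundance SummarizedExperiment.
#' @param coll a [PathwayCollection].
#' @param mode integration mode (default `"intersection"`).
#' @param methods subset of `c("ora", "gsea", "spia")`.
#' @param alpha DE significance level on adjusted p (default 0.05).
#' @param nPerm permutations for the enrichment null (default 2000).
#' @param nBoot bootstrap draws for the perturbation null (default 2000).
#' @param exponent running-sum weight exponent (default 1).
#' @param collapseRule phosphosite collapse rule (see [collapseSites()]).
#' @param imputeScope imputation scope (see [imputeMin()]).
#' @param varEqual pooled-variance t-test if `TRUE` (default).
#' @param seed integer seed covering all stochastic stages.
#' @param targets target pathway ids for the evaluation report; defaults
#'   to the collection's target ids.
#' @param outDir optional directory; when given, every stage's table is
#'   written there as TSV plus a YAML run summary.
#' @return list with `de` (per-layer differential tables), `input` (the
#'   [IntegratedInput]), `scores` and `rankings` (named by method), and
#'   `report` (from [tpRankReport()], or `NULL` without targets).
#' @examples
#' study <- simulateStudy(simConfig(nPathways = 15, nGenes = 250,
#'                                  nPlanted = 2, nTumor = 6, nNormal = 6,
#'                                  decoyFrac = 0, seed = 3))
#' res <- runPipeline(study$protein, study$phospho, study$collection,
#'                    methods = "ora", seed = 3)
#' head(res$rankings$ora)
#' @export
runPipeline <- function(protein, phospho, coll,
                        mode = c("intersection", "union", "protein_only",
                                 "phospho_only"),
                        methods = c("ora", "gsea", "spia"),
                        alpha = 0.05, nPerm = 2000L, nBoot = 2000L,
                        exponent = 1,
                        collapseRule = c("max_abs_fc_site", "mean"),
                        imputeScope = c("per_feature", "global"),
                        varEqual = TRUE, seed = NULL,
                        targets = targetIds(coll), outDir = NULL) {
    mode <- match.arg(mode)
    methods <- match.arg(methods, several.ok = TRUE)
    collapseRule <- match.arg(collapseRule)
    imputeScope <- match.arg(imputeScope)
    if (!is.null(seed)) set.seed(seed)

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    protein <- stage("impute_protein",
                     imputeMin(.dropAllMissing(protein, "protein features"),
                               imputeScope))
    phospho <- stage("impute_phospho",
                     imputeMin(.dropAllMissing(phospho, "phosphosites"),
                               imputeScope))
    phosGene <- stage("collapse_sites", collapseSites(phospho, collapseRule))
    deProt <- stage("differential_protein",
                    collapseGenes(differentialTest(protein, alpha, varEqual)))
    dePhos <- stage("differential_phospho",
                    collapseGenes(differentialTest(phosGene, alpha, varEqual)))
    input <- stage("integrate", integrateTables(deProt, dePhos, mode))

    scores <- list(); rankings <- list()
    for (m in methods) {
        scores[[m]] <- stage(paste0("score_", m), switch(m,
            ora = oraScore(input, coll),
            gsea = gseaScore(input, coll, nPerm = nPerm,
                             exponent = exponent),
            spia = spiaScore(input, coll, nBoot = nBoot)))
        rankings[[m]] <- rankScores(scores[[m]], m)
    }
    report <- if (length(targets))
        tpRankReport(rankings, intersect(targets, pathwayIds(coll)))
    else NULL

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        p <- function(f) file.path(outDir, f)
        writeDifferentialTable(deProt, p("de_protein.tsv"))
        writeDifferentialTable(dePhos, p("de_phospho.tsv"))
        writeIntegratedInput(input, p(paste0("input_", mode, ".tsv")))
        for (m in names(scores)) {
            write.table(scores[[m]], p(paste0("scores_", m, ".tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            write.table(rankings[[m]], p(paste0("ranking_", m, ".tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        if (!is.null(report)) {
            write.table(report$ranks, p("target_ranks.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            write.table(report$summary, p("target_rank_summary.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        yaml::write_yaml(list(
            mode = mode, methods = methods, alpha = alpha,
            n_perm = as.integer(nPerm), n_boot = as.integer(nBoot),
            exponent = exponent, collapse_rule = collapseRule,
            impute_scope = imputeScope, var_equal = varEqual,
            seed = if (is.null(seed)) NA else as.integer(seed),
            n_pathways_scored = vapply(scores, nrow, 0L),
            target_medians = if (is.null(report)) NULL
                else as.list(report$medians)), p("run.yaml"))
    }
    list(de = list(protein = deProt, phospho = dePhos), input = input,
         scores = scores, rankings = rankings, report = report)
}

#' Per-subtype pathway ranking
#'
#' Runs the workflow once per subtype, contrasting that subtype's tumor
#' samples against the shared normal samples, and compares the resulting
#' rankings ([subtypeCompare()]).
#'
#' @param protein,phospho abundance SummarizedExperiments with subtype
#'   labels.
#' @param coll a [PathwayCollection].
#' @param method single scoring method to rank by (default `"spia"`, the
#'   standard choice for subtype contrasts).
#' @param K top-list depth for the Venn comparison (default 20).
#' @param targets target pathway ids (default: the collection's).
#' @param seed integer seed.
#' @param ... further arguments to [runPipeline()].
#' @return list with `rankings` (named by subtype), `compare` (from
#'   [subtypeCompare()], `NULL` with fewer than two subtypes).
#' @export
runSubtypeAnalysis <- function(protein, phospho, coll, method = "spia",
                               K = 20L, targets = targetIds(coll),
                               seed = NULL, ...) {
    st <- sampleSubtypes(protein)
    if (is.null(st)) stop("protein experiment has no subtype labels")
    gr <- sampleGroups(protein)
    subtypes <- sort(unique(st[gr == "tumor" & !is.na(st)]))
    if (length(subtypes) == 0L) stop("no subtype labels on tumor samples")
    if (!is.null(seed)) set.seed(seed)
    rankings <- lapply(setNames(subtypes, subtypes), function(s) {
        res <- runPipeline(subsetSubtype(protein, s),
                           subsetSubtype(phospho, s), coll,
                           methods = method, targets = character(), ...)
        res$rankings[[method]]
    })
    compare <- if (length(subtypes) >= 2L)
        subtypeCompare(rankings, targets = targets, K = K)
    else NULL
    list(rankings = rankings, compare = compare)
}
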