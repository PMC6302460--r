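#' Build an abundance SummarizedExperiment
#'
#' The common carrier for both omic layers: a features x samples matrix of
#' log-scale abundances (missing values as `NA`) with per-sample group
#' labels (`tumor`/`normal`) and optional subtype labels in `colData`.
#'
#' @param values numeric matrix, features x samples, log scale; dimnames
#'   required.
#' @param groups character vector (or factor) of length `ncol(values)` with
#'   values `"tumor"` or `"normal"`.
#' @param subtypes optional character vector of subtype labels per sample
#'   (`NA` for normals).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"abundance"`.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
makeAbundanceSE <- function(values, groups, subtypes = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("values must have feature and sample dimnames")
    groups <- as.character(groups)
    if (length(groups) != ncol(values))
        stop("groups must have one entry per sample")
    if (!all(groups %in% c("tumor", "normal")))
        stop("groups must be 'tumor' or 'normal'")
    cd <- DataFrame(group = groups, row.names = colnames(values))
    if (!is.null(subtypes)) {
        if (length(subtypes) != ncol(values))
            stop("subtypes must have one entry per sample")
        cd$subtype <- as.character(subtypes)
    }
    SummarizedExperiment(assays = list(abundance = values), colData = cd)
}

#' Per-sample group labels of an abundance experiment
#'
#' @param se a SummarizedExperiment built by [makeAbundanceSE()] or
#'   [readAbundanceMatrix()].
#' @return named character vector of `"tumor"`/`"normal"` labels.
#' @export
sampleGroups <- function(se) {
    setNames(as.character(colData(se)$group), colnames(se))
}

#' Per-sample subtype labels of an abundance experiment
#'
#' @param se a SummarizedExperiment with a `subtype` colData column.
#' @return named character vector, or `NULL` when no subtypes are recorded.
#' @export
sampleSubtypes <- function(se) {
    cd <- colData(se)
    if (!"subtype" %in% colnames(cd)) return(NULL)
    setNames(as.character(cd$subtype), colnames(se))
}

#' Read an abundance matrix with sample annotation
#'
#' Matrix TSV: header row of sample ids, first column of feature ids.
#' Annotation TSV: columns `sample`, `group` and optionally `subtype`.
#' Empty cells and `NA` become missing values.
#'
#' @param matrixPath path to the matrix TSV.
#' @param annotationPath path to the sample-annotation TSV.
#' @return a SummarizedExperiment as from [makeAbundanceSE()].
#' @export
readAbundanceMatrix <- function(matrixPath, annotationPath) {
    tab <- read.delim(matrixPath, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    ann <- read.delim(annotationPath, header = TRUE,
                      stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% colnames(ann)))
        stop("annotation must have columns 'sample' and 'group'")
    idx <- match(colnames(m), ann$sample)
    if (anyNA(idx))
        stop("samples missing from annotation: ",
             paste(colnames(m)[is.na(idx)], collapse = ", "))
    makeAbundanceSE(m, groups = ann$group[idx],
                    subtypes = if ("subtype" %in% colnames(ann))
                        ann$subtype[idx] else NULL)
}

#' Write an abundance matrix and its sample annotation
#'
#' @param se abundance SummarizedExperiment.
#' @param matrixPath output path for the matrix TSV.
#' @param annotationPath optional output path for the annotation TSV.
#' @param idColumn name of the feature-id column in the matrix header.
#' @return `matrixPath`, invisibly.
#' @export
writeAbundanceMatrix <- function(se, matrixPath, annotationPath = NULL,
                                 idColumn = "feature") {
    m <- assay(se, "abundance")
    tab <- data.frame(rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab)[1] <- idColumn
    write.table(tab, matrixPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(annotationPath)) {
        ann <- data.frame(sample = colnames(se),
                          group = sampleGroups(se))
        st <- sampleSubtypes(se)
        if (!is.null(st)) ann$subtype <- st
        write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(matrixPath)
}

#' Subset an abundance experiment to one subtype's tumors plus all normals
#'
#' Subtype analyses contrast each subtype's tumor samples against the shared
#' normal samples.
#'
#' @param se abundance SummarizedExperiment with subtype labels.
#' @param subtype subtype label to keep.
#' @return the subsetted SummarizedExperiment.
#' @export
subsetSubtype <- function(se, subtype) {
    st <- sampleSubtypes(se)
    if (is.null(st)) stop("experiment has no subtype labels")
    gr <- sampleGroups(se)
    keep <- gr == "normal" | (!is.na(st) & st == subtype)
    if (!any(keep & gr == "tumor"))
        stop("no tumor samples with subtype ", subtype)
    se[, keep]
}
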