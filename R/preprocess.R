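#' Minimum-value imputation
#'
#' Replaces missing entries by the minimum observed value, the standard
#' treatment when missingness is low-abundance censoring: an unobserved
#' value was most plausibly below the detection floor. `per_feature` scope
#' uses each feature's own observed minimum; `global` uses the matrix-wide
#' minimum.
#'
#' @param se abundance SummarizedExperiment.
#' @param scope `"per_feature"` (default) or `"global"`.
#' @return the experiment with assay `"abundance"` fully observed.
#' @export
imputeMin <- function(se, scope = c("per_feature", "global")) {
    scope <- match.arg(scope)
    m <- assay(se, "abundance")
    if (!anyNA(m)) return(se)
    if (scope == "global") {
        if (all(is.na(m))) stop("no observed values to impute from")
        m[is.na(m)] <- min(m, na.rm = TRUE)
    } else {
        nObs <- rowSums(!is.na(m))
        if (any(nObs == 0L))
            stop("feature(s) fully missing under per_feature scope: ",
                 paste(head(rownames(m)[nObs == 0L], 5L), collapse = ", "))
        rmin <- apply(m, 1L, min, na.rm = TRUE)
        idx <- which(is.na(m), arr.ind = TRUE)
        m[idx] <- rmin[idx[, 1L]]
    }
    SummarizedExperiment::assay(se, "abundance") <- m
    se
}

.siteGene <- function(ids) {
    ok <- grepl("^.+_[A-Za-z0-9]+$", ids)
    if (!all(ok))
        stop("unparseable phosphosite id(s): ",
             paste(head(ids[!ok], 5L), collapse = ", "),
             " (expected GENE_S123)")
    sub("_[^_]+$", "", ids)
}

#' Collapse phosphosite rows to phosphoprotein (gene) level
#'
#' Site ids must follow the `GENE_S123` convention (gene symbol, underscore,
#' site label). Two rules: `max_abs_fc_site` keeps, per gene, the single
#' site whose absolute tumor-minus-normal mean difference is largest —
#' preserving the strongest regulatory signal; `mean` averages sites per
#' sample.
#'
#' @param se phosphosite abundance SummarizedExperiment (no missing values;
#'   impute first).
#' @param rule `"max_abs_fc_site"` (default) or `"mean"`.
#' @return gene-level abundance SummarizedExperiment.
#' @export
collapseSites <- function(se, rule = c("max_abs_fc_site", "mean")) {
    rule <- match.arg(rule)
    m <- assay(se, "abundance")
    if (anyNA(m)) stop("collapseSites requires a fully observed matrix")
    genes <- .siteGene(rownames(m))
    if (rule == "mean") {
        out <- rowsum(m, genes) / as.vector(table(genes)[sort(unique(genes))])
        out <- out[unique(genes)[order(match(unique(genes), genes))], ,
                   drop = FALSE]
    } else {
        gr <- sampleGroups(se)
        d <- rowMeans(m[, gr == "tumor", drop = FALSE]) -
            rowMeans(m[, gr == "normal", drop = FALSE])
        ord <- order(genes, -abs(d))
        keep <- ord[!duplicated(genes[ord])]
        keep <- keep[order(match(genes[keep], genes))]  # original gene order
        out <- m[keep, , drop = FALSE]
        rownames(out) <- genes[keep]
    }
    makeAbundanceSE(out, groups = sampleGroups(se),
                    subtypes = sampleSubtypes(se))
}

.rowVars <- function(m, means) {
    rowSums((m - means)^2) / (ncol(m) - 1L)
}

#' Differential-abundance testing
#'
#' Per-feature two-sample t-test of tumor against normal on log-scale
#' abundances, with Benjamini-Hochberg adjustment across all features of
#' the layer. The fold change is the difference of group means on the log
#' scale (log fold change), so summed fold changes across layers remain
#' additive and signed. The classical pooled-variance (Student) test is the
#' default; Welch is available via `varEqual = FALSE`.
#'
#' Degenerate rows (zero variance in both groups) cannot be tested: equal
#' group means get p = 1, unequal means (perfect separation) get p = 0;
#' both are flagged in the `degenerate` column.
#'
#' @param se abundance SummarizedExperiment with no missing values and at
#'   least two samples per group.
#' @param alpha significance level on the adjusted p-value for the DE flag.
#' @param varEqual pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return data.frame with columns `feature`, `log_fc`, `t`, `p`, `p_adj`,
#'   `is_de`, `degenerate`.
#' @export
differentialTest <- function(se, alpha = 0.05, varEqual = TRUE) {
    m <- assay(se, "abundance")
    if (anyNA(m)) stop("differentialTest requires a fully observed matrix")
    gr <- sampleGroups(se)
    x <- m[, gr == "tumor", drop = FALSE]
    y <- m[, gr == "normal", drop = FALSE]
    nx <- ncol(x); ny <- ncol(y)
    if (nx < 2L || ny < 2L)
        stop("need at least 2 samples per group (have ", nx, " tumor, ",
             ny, " normal)")
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- .rowVars(x, mx); vy <- .rowVars(y, my)
    fc <- mx - my
    if (varEqual) {
        sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
        sePool <- sqrt(sp2 * (1 / nx + 1 / ny))
        df <- rep(nx + ny - 2L, length(fc))
    } else {
        sePool <- sqrt(vx / nx + vy / ny)
        df <- (vx / nx + vy / ny)^2 /
            ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
    }
    tstat <- fc / sePool
    p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
    degenerate <- !is.finite(sePool) | sePool == 0
    tstat[degenerate] <- ifelse(fc[degenerate] == 0, 0, Inf * sign(fc[degenerate]))
    p[degenerate] <- ifelse(fc[degenerate] == 0, 1, 0)
    pAdj <- p.adjust(p, method = "BH")
    data.frame(feature = rownames(m), log_fc = fc, t = tstat, p = p,
               p_adj = pAdj, is_de = pAdj < alpha, degenerate = degenerate,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a differential table as TSV
#'
#' @param tab a data.frame from [differentialTest()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDifferentialTable <- function(tab, path) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
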