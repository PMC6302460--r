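#' Net perturbation accumulation over a pathway topology
#'
#' Solves the linear propagation model `PF = dE + B %*% PF`, where `dE` is
#' the vector of observed log fold changes of the pathway's DE genes (zero
#' elsewhere) and `B` the normalized influence matrix (see
#' [influenceMatrix()]). Each gene's perturbation factor `PF` is its own
#' fold change plus the weighted perturbation of its upstream regulators;
#' the accumulation `Acc = PF - dE` isolates the topology-propagated part,
#' and `tA = sum(Acc)` is the pathway's total net accumulation.
#'
#' When `I - B` is singular or numerically near-singular (reciprocal
#' condition number below `rcondTol`), the pathway cannot be scored for
#' perturbation evidence and is flagged rather than dropped.
#'
#' @param topology a [PathwayTopology].
#' @param deltaE named numeric of log fold changes; names outside the
#'   membership are dropped with a warning, members without a value get 0.
#' @param rcondTol reciprocal-condition-number threshold below which the
#'   system is declared unscorable (default 1e-10).
#' @return list with `pf`, `acc` (named per-gene vectors), `tA`, and
#'   `status` (`"ok"` or `"singular"`; on `"singular"` the vectors are NA
#'   and `tA` is NA).
#' @examples
#' tp <- PathwayTopology("p1", edges = data.frame(
#'     from = c("A", "B"), to = c("B", "C"),
#'     relation = "activation"))
#' netAccumulation(tp, c(A = 1))
#' @export
netAccumulation <- function(topology, deltaE, rcondTol = 1e-10) {
    stopifnot(is(topology, "PathwayTopology"))
    mem <- topology@members
    extra <- setdiff(names(deltaE), mem)
    if (length(extra)) {
        warning("dropping fold changes for non-member gene(s): ",
                paste(head(extra, 5L), collapse = ", "))
        deltaE <- deltaE[setdiff(names(deltaE), extra)]
    }
    dE <- setNames(numeric(length(mem)), mem)
    dE[names(deltaE)] <- deltaE
    B <- influenceMatrix(topology)
    M <- diag(length(mem)) - B
    if (rcond(M) < rcondTol) {
        na <- setNames(rep(NA_real_, length(mem)), mem)
        return(list(pf = na, acc = na, tA = NA_real_,
                    status = "singular"))
    }
    pf <- drop(solve(M, dE))
    names(pf) <- mem
    acc <- pf - dE
    list(pf = pf, acc = acc, tA = sum(acc), status = "ok")
}

#' Combine over-representation and perturbation evidence
#'
#' Combines the two independent p-values into one by the probability that
#' the product of two independent uniforms falls below `c = pNde * pPert`:
#' `pG = c - c * log(c)`.
#'
#' @param pNde hypergeometric over-representation p-value, in (0, 1].
#' @param pPert perturbation bootstrap p-value, in (0, 1].
#' @return the combined p-value `pG`, in (0, 1].
#' @examples
#' combinePG(0.1, 0.1)  # 0.01 - 0.01 * log(0.01)
#' @export
combinePG <- function(pNde, pPert) {
    stopifnot(all(pNde > 0 & pNde <= 1), all(pPert > 0 & pPert <= 1))
    cc <- pNde * pPert
    cc - cc * log(cc)
}

# Null distribution of tA for one pathway: place nDe fold changes drawn
# without replacement from the measured pool onto uniformly chosen members
# and recompute tA. By linearity of the propagation model, tA = v . dE with
# v = colSums(solve(I - B)) - 1, so each draw is an inner product.
.tANull <- function(v, nDe, pool, nBoot) {
    nm <- length(v)
    replaceFc <- length(pool) < nDe
    posDraw <- vapply(seq_len(nBoot),
                      function(i) sample.int(nm, nDe), integer(nDe))
    fcDraw <- vapply(seq_len(nBoot),
                     function(i) pool[sample.int(length(pool), nDe,
                                                 replace = replaceFc)],
                     numeric(nDe))
    if (nDe == 1L) {
        posDraw <- matrix(posDraw, nrow = 1L)
        fcDraw <- matrix(fcDraw, nrow = 1L)
    }
    colSums(matrix(v[posDraw], nrow = nDe) * fcDraw)
}

#' Topology-based pathway scoring
#'
#' Per pathway, two types of evidence are combined: `pNDE`, the
#' hypergeometric probability of observing at least the pathway's DE-gene
#' count (same kernel as [oraScore()]); and `pPERT`, a bootstrap p-value
#' for the total net accumulation `tA` (see [netAccumulation()]). The
#' bootstrap null places the pathway's DE-gene count of fold changes, drawn
#' without replacement from the pool of all measured combined fold changes,
#' on uniformly chosen members, recomputes `tA`, and is centered at its
#' median; `pPERT` is the two-sided add-one tail probability around that
#' median. Evidence is combined by [combinePG()], adjusted by
#' Benjamini-Hochberg, and pathways are ranked by ascending `pG` with ties
#' broken by descending `|tA|`, then pathway id.
#'
#' Pathways without a topology are scored on over-representation evidence
#' only (`pPERT = 1`, status `"no_topology"`); singular propagation systems
#' degrade the same way (status `"singular"`) so the ranking length is
#' stable.
#'
#' @param input an [IntegratedInput] with DE genes and combined fold
#'   changes (intersection mode in the standard workflow).
#' @param coll a [PathwayCollection] with topologies.
#' @param nBoot bootstrap draws for `pPERT` (default 2000).
#' @param seed optional integer seed.
#' @param rcondTol passed to [netAccumulation()].
#' @return data.frame with columns `pathway_id`, `n_de`, `tA`, `pNDE`,
#'   `pPERT`, `pG`, `pG_adj`, `status`, `rank`.
#' @export
spiaScore <- function(input, coll, nBoot = 2000L, seed = NULL,
                      rcondTol = 1e-10) {
    stopifnot(is(input, "IntegratedInput"), is(coll, "PathwayCollection"),
              nBoot >= 1L)
    if (!is.null(seed)) set.seed(seed)
    bg <- background(input)
    de <- intersect(deGenes(input), bg)
    fc <- combinedFc(input)
    pool <- unname(rankedProfile(input))
    if (length(pool) == 0L) pool <- 0
    N <- length(bg); n <- length(de)
    rows <- vector("list", length(coll@geneSets))
    for (i in seq_along(coll@geneSets)) {
        gs <- coll@geneSets[[i]]
        id <- gs@pathwayId
        memBg <- intersect(gs@members, bg)
        m <- length(memBg)
        deIn <- intersect(memBg, de)
        k <- length(deIn)
        pNde <- if (m == 0L) 1 else hyperUpperTail(k, m, n, N)
        tp <- coll@topologies[[id]]
        tA <- 0; pPert <- 1; status <- "ok"
        if (is.null(tp)) {
            status <- "no_topology"
        } else if (k == 0L) {
            status <- "no_de"
        } else {
            mem <- tp@members
            B <- influenceMatrix(tp)
            M <- diag(length(mem)) - B
            if (rcond(M) < rcondTol) {
                status <- "singular"
                tA <- NA_real_
            } else {
                v <- colSums(solve(M)) - 1
                names(v) <- mem
                dE <- setNames(numeric(length(mem)), mem)
                dE[deIn] <- fc[deIn]
                tA <- sum(v * dE)
                tNull <- .tANull(v, k, pool, nBoot)
                med <- median(tNull)
                pPert <- (1 + sum(abs(tNull - med) >= abs(tA - med))) /
                    (1 + nBoot)
            }
        }
        rows[[i]] <- data.frame(pathway_id = id, n_de = k, tA = tA,
                                pNDE = pNde, pPERT = pPert,
                                pG = combinePG(pNde, pPert),
                                status = status, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$pG_adj <- p.adjust(out$pG, method = "BH")
    absTA <- ifelse(is.na(out$tA), 0, abs(out$tA))
    out$rank <- order(order(out$pG, -absTA, out$pathway_id,
                            method = "radix"))
    out <- out[, c("pathway_id", "n_de", "tA", "pNDE", "pPERT", "pG",
                   "pG_adj", "status", "rank")]
    rownames(out) <- NULL
    out
}
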