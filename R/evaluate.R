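#' Top-k retrieval and success rates of a set of rankings
#'
#' For each complex the rank of its best near-native decoy is located under
#' the consensus ranking (and, for comparison, under the docking engine's
#' initial ranking).  At each `k`:
#' \itemize{
#'   \item *retrieval rate*: percentage of complexes **with at least one
#'     sampled near-native** whose best near-native rank is `<= k`;
#'   \item *success rate*: the same numerator over **all** complexes,
#'     including those where docking sampled no near-native.
#' }
#' Quality-upgrade counts compare the CAPRI class of the top-ranked
#' near-native before vs after re-ranking, over complexes where a near-native
#' appears within `k` of both orderings.
#'
#' @param sets named list of labelled [DecoySet-class] objects.
#' @param consensus named list of consensus rankings (integer permutations,
#'   best first), one per complex in `sets`.
#' @param ks rank cutoffs (default 1, 10, 100).
#' @return An evaluation report: list with `perComplex` (data frame: complex,
#'   hasNearNative, bestNN rank before/after), `rates` (data frame: k,
#'   retrieval and success percentages, before and after), and
#'   `qualityUpgrades` (data frame per k: complexes whose top-ranked
#'   near-native class improved / worsened after re-ranking).
#' @export
evaluateRankings <- function(sets, consensus, ks = c(1L, 10L, 100L)) {
    names(sets) <- vapply(sets, complexId, character(1))
    ids <- names(sets)
    stopifnot(all(ids %in% names(consensus)))
    per <- data.frame(
        complex = ids,
        hasNearNative = vapply(sets, hasNearNative, logical(1)),
        bestBefore = vapply(ids, function(id)
            bestNearNativeRank(order(initialRanks(sets[[id]])),
                               labels(sets[[id]])), numeric(1)),
        bestAfter = vapply(ids, function(id)
            bestNearNativeRank(consensus[[id]], labels(sets[[id]])),
            numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    nAll <- nrow(per)
    nWith <- sum(per$hasNearNative)
    rate <- function(best, k, denom)
        100 * sum(!is.na(best) & best <= k) / denom
    rates <- do.call(rbind, lapply(ks, function(k) data.frame(
        k = k,
        retrievalBefore = rate(per$bestBefore, k, nWith),
        retrievalAfter = rate(per$bestAfter, k, nWith),
        successBefore = rate(per$bestBefore, k, nAll),
        successAfter = rate(per$bestAfter, k, nAll))))
    topClass <- function(set, ranking, k) {
        pos <- integer(nDecoys(set)); pos[ranking] <- seq_len(nDecoys(set))
        nn <- which(isNearNative(labels(set)) & pos <= k)
        if (!length(nn)) return(NA_integer_)
        as.integer(labels(set)[nn[which.min(pos[nn])]])
    }
    qual <- do.call(rbind, lapply(ks, function(k) {
        up <- 0L; down <- 0L; considered <- 0L
        for (id in ids) {
            s <- sets[[id]]
            b <- topClass(s, order(initialRanks(s)), k)
            a <- topClass(s, consensus[[id]], k)
            if (!is.na(b) && !is.na(a)) {
                considered <- considered + 1L
                if (a > b) up <- up + 1L
                if (a < b) down <- down + 1L
            }
        }
        data.frame(k = k, considered = considered, upgraded = up,
                   downgraded = down)
    }))
    structure(list(perComplex = per, rates = rates, qualityUpgrades = qual),
              class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
    cat("Evaluation over", nrow(x$perComplex), "complex(es),",
        sum(x$perComplex$hasNearNative), "with a sampled near-native\n")
    print(x$rates, row.names = FALSE, digits = 4)
    invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of near-native ranks
#'
#' Two-sided paired signed-rank test on per-complex best near-native ranks
#' before vs after re-ranking (smaller rank = better).  Complexes with zero
#' difference are discarded (the standard convention of the signed-rank
#' test); with fewer than two non-zero pairs the comparison is undefined and
#' flagged as such.
#'
#' @param before,after paired numeric vectors of per-complex ranks.
#' @return List with `statistic`, `p.value`, `nNonZero`, `direction` (`"after
#'   better"`, `"before better"` or `"none"`), and `defined` (FALSE when fewer
#'   than 2 non-zero pairs).
#' @export
compareRankings <- function(before, after) {
    stopifnot(length(before) == length(after))
    keep <- !is.na(before) & !is.na(after)
    d <- after[keep] - before[keep]
    nz <- sum(d != 0)
    if (nz < 2L)
        return(list(statistic = NA_real_, p.value = NA_real_, nNonZero = nz,
                    direction = "none", defined = FALSE))
    wt <- suppressWarnings(
        stats::wilcox.test(after[keep], before[keep], paired = TRUE))
    dz <- d[d != 0]
    W <- sum(sign(dz) * rank(abs(dz)))   # signed-rank sum; < 0: ranks dropped
    dir <- if (W < 0) "after better" else if (W > 0) "before better"
           else "none"
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         nNonZero = nz, direction = dir, defined = TRUE)
}
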