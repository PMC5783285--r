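#' Rank clusters by their best-scoring member
#'
#' Model-selection scoring of one complex: decoys are clustered (single
#' linkage at the scoring cutoff, default 3.5 angstrom) and clusters are
#' ordered by the ranking position of their best member.  `r` is the 1-based
#' rank of the first cluster whose *top-ranked member* is near-native
#' (acceptable or better); if no cluster is topped by a near-native, `r` is
#' absent.
#'
#' @param set a labelled [DecoySet-class].
#' @param ranking integer permutation of decoy indices, best first (e.g. from
#'   [rankByProjection()]).
#' @param clustering a [Clustering-class] of the same decoys at the scoring
#'   cutoff.
#' @return A [ClusterRanking-class].
#' @export
clusterRank <- function(set, ranking, clustering) {
    n <- nDecoys(set)
    stopifnot(length(ranking) == n,
              length(clustering@assignment) == n)
    pos <- integer(n); pos[ranking] <- seq_len(n)
    k <- clustering@nClusters
    best <- vapply(seq_len(k), function(cl)
        min(pos[clustering@assignment == cl]), integer(1))
    ord <- order(best)                      # clusters, best member first
    nn <- isNearNative(labels(set))
    topIsNN <- vapply(ord, function(cl) {
        members <- which(clustering@assignment == cl)
        nn[members[which.min(pos[members])]]
    }, logical(1))
    r <- if (any(topIsNN)) which(topIsNN)[1L] else NA_integer_
    new("ClusterRanking", nClusters = as.integer(k),
        clusterOrder = as.integer(ord), r = as.integer(r))
}

#' @rdname ClusterRanking
#' @param object a `ClusterRanking`.
#' @export
setMethod("nClusters", "ClusterRanking", function(object) object@nClusters)

#' @rdname ClusterRanking
#' @export
nearNativeClusterRank <- function(object) object@r

setMethod("show", "ClusterRanking", function(object) {
    cat(sprintf("ClusterRanking: %d clusters, near-native cluster rank r = %s\n",
                object@nClusters,
                if (is.na(object@r)) "absent" else object@r))
    invisible(object)
})

#' Per-complex model-selection score
#'
#' The logarithmic cluster-rank score
#' \deqn{s_i = \frac{\log_{10}(n_c) - \log_{10}(r)}{\log_{10}(n_c)}}
#' ranges from 1 (the top-ranked cluster is topped by a near-native) down to 0
#' (only the last cluster is, or none is: then \eqn{s_i = 0}).  The log form
#' rewards improvements near the top of the list far more than equal-sized
#' improvements further down.  Degenerate case `n_c = 1`: 1 if the single
#' cluster's top decoy is near-native, else 0.
#'
#' @param cr a [ClusterRanking-class], or `n_c` given as a number with `r`
#'   supplied separately.
#' @param r near-native cluster rank (only when `cr` is numeric `n_c`).
#' @return Score in `[0, 1]`.
#' @examples
#' complexScore(ClusterRanking(nClusters = 10, r = 1))    # 1
#' complexScore(ClusterRanking(nClusters = 10, r = 10))   # 0
#' complexScore(ClusterRanking(nClusters = 100, r = 10))  # 0.5
#' @export
complexScore <- function(cr, r = NULL) {
    if (is(cr, "ClusterRanking")) {
        nc <- cr@nClusters; r <- cr@r
    } else {
        nc <- as.integer(cr); r <- as.integer(r)
    }
    if (is.na(nc) || nc < 1L) stop("n_c must be a positive integer")
    if (is.na(r)) return(0)
    if (nc == 1L) return(if (r == 1L) 1 else 0)
    (log10(nc) - log10(r)) / log10(nc)
}

#' @rdname ClusterRanking
#' @param nClusters number of clusters.
#' @param r near-native cluster rank, or `NA`.
#' @param clusterOrder optional explicit cluster order (default `1..n_c`).
#' @export
ClusterRanking <- function(nClusters, r = NA_integer_,
                           clusterOrder = seq_len(nClusters)) {
    new("ClusterRanking", nClusters = as.integer(nClusters),
        clusterOrder = as.integer(clusterOrder), r = as.integer(r))
}

#' Ensemble-relative model scores
#'
#' Each model's total score is \eqn{S = \sum_i (s_i - \bar{s}_i)} over the
#' complexes of its model-selection set, where \eqn{\bar{s}_i} is the mean
#' score for complex `i` across all models scored on that complex.  Scoring
#' relative to the ensemble mean favours models that do well on complexes the
#' rest of the ensemble finds difficult and penalises failures on easy ones.
#' Under protocol B different models see different selection sets;
#' \eqn{\bar{s}_i} is then the mean over the models whose selection set
#' contains complex `i`.
#'
#' @param sTable numeric matrix of per-complex scores `s_i`: rows = models,
#'   columns = complexes; `NA` where a model was not scored on a complex.
#' @return Numeric vector `S`, one per model (row).
#' @export
ensembleRelativeScores <- function(sTable) {
    sTable <- as.matrix(sTable)
    if (nrow(sTable) < 1L) stop("empty ensemble")
    sbar <- colMeans(sTable, na.rm = TRUE)
    rel <- sweep(sTable, 2L, sbar)
    S <- rowSums(rel, na.rm = TRUE)
    names(S) <- rownames(sTable)
    S
}

#' Select the top-n models of an ensemble
#'
#' Keeps the `n` models with the highest relative score `S`; ties are broken
#' by model creation index (ascending), so selection is deterministic.
#'
#' @param models list of candidate [RankingModel-class] objects.
#' @param S numeric score per model, aligned with `models`.
#' @param n ensemble size to keep, `n <= length(models)`.
#' @return The selected models, in decreasing-S order.  The chosen indices
#'   are attached as `attr(, "indices")`.
#' @export
selectTopModels <- function(models, S, n) {
    if (n > length(models))
        stop("n exceeds the number of candidate models")
    stopifnot(length(S) == length(models))
    ord <- order(-S, seq_along(S))[seq_len(n)]
    out <- models[ord]
    attr(out, "indices") <- ord
    out
}
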