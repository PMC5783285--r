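#' Build the pairwise preference graph of an ensemble of rankings
#'
#' A complete digraph over decoys where edge weight (a, b) counts the ballots
#' (ensemble rankings) that place decoy `a` above decoy `b`.
#'
#' @param rankings list of integer permutations of the same decoy indices
#'   (best first), or a matrix with one ranking per row.
#' @param decoyIds optional decoy names for the weight matrix dimnames.
#' @return A [PreferenceGraph-class].
#' @export
buildPreferenceGraph <- function(rankings, decoyIds = NULL) {
    if (is.matrix(rankings))
        rankings <- lapply(seq_len(nrow(rankings)), function(i) rankings[i, ])
    stopifnot(length(rankings) >= 1L)
    n <- length(rankings[[1L]])
    w <- matrix(0L, n, n)
    for (rk in rankings) {
        if (length(rk) != n || !identical(sort(as.integer(rk)), seq_len(n)))
            stop("all rankings must be permutations of the same decoy set")
        pos <- integer(n); pos[rk] <- seq_len(n)
        w <- w + outer(pos, pos, "<")
    }
    storage.mode(w) <- "integer"
    if (!is.null(decoyIds)) dimnames(w) <- list(decoyIds, decoyIds)
    new("PreferenceGraph", weights = w, nBallots = length(rankings))
}

#' @rdname PreferenceGraph
#' @param object a `PreferenceGraph`.
#' @export
preferenceWeights <- function(object) object@weights

setMethod("show", "PreferenceGraph", function(object) {
    cat(sprintf("PreferenceGraph: %d decoys, %d ballots\n",
                nrow(object@weights), object@nBallots))
    invisible(object)
})

#' Strongest (widest) path strengths between all decoy pairs
#'
#' The strength of a directed path is the minimum edge weight along it; the
#' strongest path from a to b maximizes that minimum over all paths.  Computed
#' with the Floyd--Warshall-style max--min relaxation used by the Schulze
#' method, O(n^3).
#'
#' @param graph a [PreferenceGraph-class], or a bare non-negative weight
#'   matrix.
#' @return Numeric matrix `strength[a, b]`; the diagonal is not meaningful.
#' @export
strongestPaths <- function(graph) {
    w <- if (is(graph, "PreferenceGraph")) graph@weights else as.matrix(graph)
    n <- nrow(w)
    s <- matrix(as.numeric(w), n, n, dimnames = dimnames(w))
    diag(s) <- 0
    for (k in seq_len(n)) {
        via <- pmin(matrix(s[, k], n, n), matrix(s[k, ], n, n, byrow = TRUE))
        s <- pmax(s, via)
    }
    diag(s) <- 0
    s
}

#' Schulze consensus ranking of an ensemble of rankings
#'
#' Decoy `a` is ranked above decoy `b` when the strongest-path strength
#' (a, b) exceeds (b, a); this pairwise relation is transitive, so a total
#' order follows.  Pairs with equal strengths are broken by lower mean rank
#' across the ensemble, then by initial rank.
#'
#' @param rankings list of integer permutations (best first), or a
#'   [PreferenceGraph-class] via `graph`.
#' @param initialRanks integer tie-break vector (the docking engine's
#'   ordering); defaults to decoy index.
#' @param graph optional precomputed [PreferenceGraph-class] (then `rankings`
#'   is only used for the mean-rank tie-break and may be omitted).
#' @return Integer permutation of decoy indices, best first.
#' @export
consensusRanking <- function(rankings = NULL, initialRanks = NULL,
                             graph = NULL) {
    if (is.null(graph)) graph <- buildPreferenceGraph(rankings)
    n <- nrow(graph@weights)
    s <- strongestPaths(graph)
    wins <- rowSums(s > t(s))
    meanRank <- if (!is.null(rankings)) {
        pos <- sapply(rankings, function(rk) {
            p <- integer(n); p[rk] <- seq_len(n); p
        })
        rowMeans(matrix(pos, nrow = n))
    } else rep(0, n)
    if (is.null(initialRanks)) initialRanks <- seq_len(n)
    order(-wins, meanRank, initialRanks)
}
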