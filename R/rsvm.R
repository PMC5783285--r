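#' @useDynLib DecoyRank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Build cross-category pairwise ranking constraints
#'
#' For every complex, one constraint is generated per ordered pair of decoys
#' in *different* CAPRI categories, with the higher-category decoy as the
#' "better" member.  Decoys of different complexes are never paired: scores
#' only matter relative to other decoys of the same complex.  Each constraint
#' contributes the difference vector `d_better - d_worse` as a training
#' example of the ranking SVM.
#'
#' @param sets list of labelled [DecoySet-class] objects (normalized
#'   features).  A complex whose decoys all share one category contributes no
#'   pairs.
#' @return A [PairConstraintSet-class].
#' @export
buildPairs <- function(sets) {
    if (inherits(sets, "DecoySet")) sets <- list(sets)
    cid <- character(0); bi <- integer(0); wi <- integer(0)
    diffs <- vector("list", length(sets))
    for (k in seq_along(sets)) {
        s <- sets[[k]]
        lab <- labels(s)
        f <- features(s)
        levs <- as.integer(lab)
        ## all ordered pairs with strictly higher category first
        pb <- integer(0); pw <- integer(0)
        for (lv in 2:4) {
            hi <- which(levs == lv)
            lo <- which(levs < lv)
            if (length(hi) && length(lo)) {
                pb <- c(pb, rep(hi, each = length(lo)))
                pw <- c(pw, rep(lo, times = length(hi)))
            }
        }
        if (length(pb)) {
            cid <- c(cid, rep(complexId(s), length(pb)))
            bi <- c(bi, pb); wi <- c(wi, pw)
            diffs[[k]] <- f[pb, , drop = FALSE] - f[pw, , drop = FALSE]
        }
    }
    diffs <- diffs[!vapply(diffs, is.null, logical(1))]
    D <- if (length(diffs)) do.call(rbind, diffs)
         else matrix(0, 0L, if (length(sets)) ncol(features(sets[[1L]])) else 0L)
    rownames(D) <- NULL
    new("PairConstraintSet", complexIds = cid, betterIdx = bi,
        worseIdx = wi, diffs = D)
}

#' @rdname PairConstraintSet
#' @param object a `PairConstraintSet`.
#' @export
nPairs <- function(object) nrow(object@diffs)

setMethod("show", "PairConstraintSet", function(object) {
    cat(sprintf("PairConstraintSet: %d pairs over %d complex(es), %d features\n",
                nPairs(object), length(unique(object@complexIds)),
                ncol(object@diffs)))
    invisible(object)
})

#' Train a ranking SVM on pairwise constraints
#'
#' Finds the weight vector `w` minimizing the soft-margin objective
#' \deqn{\tfrac12\|w\|^2 + c\sum_{ijk}\xi_{ijk}} subject to
#' \eqn{w\cdot(d_{ik}-d_{jk}) \ge 1-\xi_{ijk},\ \xi_{ijk}\ge 0} for every
#' cross-category pair: equivalently, an SVM classifier without intercept on
#' the pair difference vectors.  Large `c` pushes towards perfect training
#' rankings; small `c` favours a wide margin between CAPRI categories.  Solved
#' by exact dual coordinate descent (compiled); the problem is convex, so the
#' solution is checked against a dense QP only in tests.
#'
#' @param pairs a [PairConstraintSet-class] with at least one pair.
#' @param c positive soft-margin trade-off constant.
#' @param tolerance stopping tolerance on the largest projected-gradient
#'   violation of a sweep.
#' @param maxEpochs sweep budget; exceeding it without convergence is an
#'   error.
#' @return A [RankingModel-class].
#' @export
trainRankingSVM <- function(pairs, c, tolerance = 1e-6, maxEpochs = 50000L) {
    if (length(c) != 1L || !is.finite(c) || c <= 0)
        stop("c must be a single positive number")
    if (nPairs(pairs) < 1L)
        stop("at least one pairwise constraint is required")
    if (!all(is.finite(pairs@diffs)))
        stop("pair difference vectors must be finite")
    fit <- .dcd_solve(pairs@diffs, c, eps = tolerance,
                      max_epochs = as.integer(maxEpochs), seed = 1L)
    if (!fit$converged)
        stop(sprintf(paste0("ranking-SVM solver did not converge in %d ",
                            "epochs (objective %.6g); increase maxEpochs ",
                            "or tolerance"), maxEpochs, fit$objective))
    w <- as.numeric(fit$w)
    names(w) <- colnames(pairs@diffs)
    new("RankingModel", weights = w, c = as.numeric(c),
        trainingComplexIds = unique(pairs@complexIds),
        objective = fit$objective)
}

#' @rdname RankingModel
#' @export
setMethod("weights", "RankingModel", function(object, ...) object@weights)

setMethod("show", "RankingModel", function(object) {
    cat(sprintf(
        "RankingModel: %d weights, c = %g, objective = %.4g, %d complex(es)\n",
        length(object@weights), object@c, object@objective,
        length(object@trainingComplexIds)))
    invisible(object)
})

#' Serialize / deserialize a ranking model as JSON
#'
#' @param model a [RankingModel-class].
#' @param path file path.
#' @return `readRankingModel` returns the model; `writeRankingModel` returns
#'   `path` invisibly.
#' @export
writeRankingModel <- function(model, path) {
    jsonlite::write_json(
        list(weights = model@weights, names = names(model@weights),
             c = model@c, training_complex_ids = model@trainingComplexIds,
             objective = model@objective),
        path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeRankingModel
#' @export
readRankingModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    w <- as.numeric(x$weights)
    if (!is.null(x$names)) names(w) <- x$names
    new("RankingModel", weights = w, c = as.numeric(x$c),
        trainingComplexIds = as.character(x$training_complex_ids),
        objective = as.numeric(x$objective))
}

#' Rank decoys by projection onto a weight vector
#'
#' Decoys are ordered by decreasing projection `w . d` (best first); exact
#' ties are broken by the docking engine's initial rank (ascending), so the
#' all-zero weight vector reproduces the initial ordering.
#'
#' @param model a [RankingModel-class] (or a bare numeric weight vector).
#' @param set a [DecoySet-class] with normalized features.
#' @return Integer permutation of decoy row indices, best first.
#' @export
rankByProjection <- function(model, set) {
    w <- if (is(model, "RankingModel")) weights(model) else as.numeric(model)
    f <- features(set)
    if (ncol(f) != length(w))
        stop("weight length does not match feature width")
    proj <- as.numeric(f %*% w)
    order(-proj, initialRanks(set))
}

#' Fraction of swapped cross-category pairs of a ranking
#'
#' Among all pairs of decoys in different CAPRI categories, the fraction where
#' the worse-category decoy is ranked above the better one; 0 for a perfect
#' ranking, 1 for a fully reversed one.  A ranking SVM is trained to minimize
#' exactly this quantity.
#'
#' @param ranking integer permutation of decoy indices, best first.
#' @param labels ordered CAPRI factor of the same length.
#' @return Fraction in `[0, 1]`, or `NA` when there are no cross-category
#'   pairs (undefined).
#' @export
swappedPairFraction <- function(ranking, labels) {
    labels <- capriFactor(labels)
    if (length(ranking) != length(labels))
        stop("ranking and labels must have equal length")
    pos <- integer(length(ranking))
    pos[ranking] <- seq_along(ranking)           # position of each decoy
    levs <- as.integer(labels)
    swapped <- 0L; total <- 0L
    for (a in 2:4) for (b in seq_len(a - 1L)) {
        hi <- pos[levs == a]; lo <- pos[levs == b]
        if (length(hi) && length(lo)) {
            total <- total + length(hi) * length(lo)
            swapped <- swapped + sum(outer(hi, lo, ">"))
        }
    }
    if (total == 0L) return(NA_real_)
    swapped / total
}
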