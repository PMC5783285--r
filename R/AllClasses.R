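#' @import methods
#' @importFrom stats sd setNames dist rnorm runif
#' @importFrom utils read.delim write.table head
NULL

## Ordered CAPRI quality levels, worst to best.  "Near-native" means
## acceptable or better.
.capriLevels <- c("incorrect", "acceptable", "medium", "high")

#' CAPRI quality levels
#'
#' The four CAPRI pose-quality categories in increasing order of quality.
#' A decoy is called *near-native* when its category is `"acceptable"` or
#' better.
#'
#' @return Character vector of the four level names, worst first.
#' @examples
#' capriLevels()
#' @export
capriLevels <- function() .capriLevels

#' Coerce to an ordered CAPRI factor
#'
#' @param x character vector of category names, or an existing factor.
#' @return An ordered factor with levels `incorrect < acceptable < medium <
#'   high`.
#' @examples
#' capriFactor(c("incorrect", "high"))
#' @export
capriFactor <- function(x) {
    f <- factor(as.character(x), levels = .capriLevels, ordered = TRUE)
    if (anyNA(f) && !anyNA(x))
        stop("unknown CAPRI category: ",
             paste(setdiff(unique(as.character(x)), .capriLevels),
                   collapse = ", "))
    f
}

#' @rdname capriFactor
#' @param labels an ordered CAPRI factor.
#' @return `isNearNative` returns a logical vector: category is acceptable or
#'   better.
#' @export
isNearNative <- function(labels) {
    capriFactor(labels) >= "acceptable"
}

#' FeatureSchema: decoy descriptor column layout and z-score parameters
#'
#' Describes the ordered feature columns of a decoy table and, once fitted on
#' training data, the per-column mean and standard deviation used for z-score
#' normalization.  The default layout has 91 columns: 82 slots for externally
#' computed physicochemical descriptors plus 9 ligand-pose cluster-size
#' columns (single-linkage cutoffs 3.0--7.0 angstrom in 0.5 angstrom steps).
#'
#' @slot names ordered character vector of feature column names.
#' @slot means per-column mean (NA until fitted).
#' @slot sigmas per-column population standard deviation (NA until fitted);
#'   columns with sigma 0 are constant in the training pool and are mapped to
#'   zero on transformation.
#' @export
setClass("FeatureSchema",
    representation(names = "character", means = "numeric", sigmas = "numeric"),
    prototype(names = character(), means = numeric(), sigmas = numeric()))

setValidity("FeatureSchema", function(object) {
    n <- length(object@names)
    if (anyDuplicated(object@names))
        return("feature names must be unique")
    if (length(object@means) != n || length(object@sigmas) != n)
        return("means and sigmas must have one entry per feature name")
    if (any(object@sigmas < 0, na.rm = TRUE))
        return("sigmas must be non-negative")
    TRUE
})

#' DecoySet: one complex's docking decoys
#'
#' Container for the decoys of a single protein--protein complex: a feature
#' matrix (one row per decoy), CAPRI quality labels, the docking program's
#' original ordering, and optional per-decoy receptor/ligand C-alpha
#' coordinates used for RMSD clustering.
#'
#' @slot complexId single string identifying the complex.
#' @slot decoyIds unique decoy identifiers (rownames of `features`).
#' @slot features numeric matrix, `n_decoys x n_features`; may contain `NA`
#'   missing markers before imputation.
#' @slot labels ordered CAPRI factor, one per decoy.
#' @slot initialRanks integer permutation of `1..n_decoys`: the docking
#'   engine's original ranking (1 = best).
#' @slot receptorCoords list of `n_atoms x 3` matrices (one per decoy), or
#'   empty list when coordinates are absent.
#' @slot ligandCoords list of `n_atoms x 3` matrices (one per decoy), or
#'   empty list.
#' @slot metadata free-form list (e.g. near-native bookkeeping set by
#'   [truncateToTop()]).
#' @seealso [DecoySet()] constructor, [readDecoyTable()]
#' @export
setClass("DecoySet",
    representation(complexId = "character", decoyIds = "character",
                   features = "matrix", labels = "factor",
                   initialRanks = "integer",
                   receptorCoords = "list", ligandCoords = "list",
                   metadata = "list"),
    prototype(metadata = list(), receptorCoords = list(),
              ligandCoords = list()))

setValidity("DecoySet", function(object) {
    n <- length(object@decoyIds)
    if (length(object@complexId) != 1L || !nzchar(object@complexId))
        return("complexId must be a single non-empty string")
    if (n < 1L)
        return("a DecoySet needs at least one decoy")
    if (anyDuplicated(object@decoyIds))
        return("decoy ids must be unique within a complex")
    if (nrow(object@features) != n)
        return("features must have one row per decoy")
    if (length(object@labels) != n)
        return("labels must have one entry per decoy")
    if (!identical(levels(object@labels), .capriLevels) ||
        !is.ordered(object@labels))
        return("labels must be an ordered CAPRI factor")
    if (length(object@initialRanks) != n ||
        !identical(sort(object@initialRanks), seq_len(n)))
        return("initialRanks must be a permutation of 1..n_decoys")
    for (nm in c("receptorCoords", "ligandCoords")) {
        cc <- slot(object, nm)
        if (length(cc) != 0L && length(cc) != n)
            return(sprintf("%s must be empty or one matrix per decoy", nm))
        if (length(cc) && !all(vapply(cc, function(m)
                is.matrix(m) && ncol(m) == 3L, logical(1))))
            return(sprintf("%s entries must be n_atoms x 3 matrices", nm))
    }
    TRUE
})

#' RankingModel: a trained ranking-SVM weight vector
#'
#' @slot weights numeric weight vector, one entry per schema column.
#' @slot c positive soft-margin trade-off constant used in training.
#' @slot trainingComplexIds ids of the complexes whose decoy pairs were used.
#' @slot objective value of the primal objective 0.5*||w||^2 + c*sum(xi) at
#'   the solution.
#' @export
setClass("RankingModel",
    representation(weights = "numeric", c = "numeric",
                   trainingComplexIds = "character", objective = "numeric"))

setValidity("RankingModel", function(object) {
    if (!all(is.finite(object@weights)))
        return("weights must be finite")
    if (length(object@c) != 1L || object@c <= 0)
        return("c must be a single positive number")
    TRUE
})

#' PairConstraintSet: cross-category pairwise ranking constraints
#'
#' One row per ordered pair (better decoy, worse decoy) drawn from the same
#' complex but different CAPRI categories.  The stored difference vectors
#' `d_better - d_worse` are the training examples of the ranking SVM.
#'
#' @slot complexIds complex id of each pair.
#' @slot betterIdx,worseIdx decoy row indices within their complex.
#' @slot diffs numeric matrix of feature differences, one row per pair.
#' @export
setClass("PairConstraintSet",
    representation(complexIds = "character", betterIdx = "integer",
                   worseIdx = "integer", diffs = "matrix"))

setValidity("PairConstraintSet", function(object) {
    np <- nrow(object@diffs)
    if (length(object@complexIds) != np || length(object@betterIdx) != np ||
        length(object@worseIdx) != np)
        return("per-pair vectors must match the number of difference rows")
    TRUE
})

#' Clustering: single-linkage partition of a decoy set
#'
#' @slot cutoff distance cutoff in angstrom.
#' @slot assignment integer cluster id per decoy; ids are contiguous
#'   `1..nClusters`, numbered by first-member decoy index.
#' @slot nClusters number of clusters.
#' @export
setClass("Clustering",
    representation(cutoff = "numeric", assignment = "integer",
                   nClusters = "integer"))

setValidity("Clustering", function(object) {
    k <- object@nClusters
    if (length(k) != 1L || k < 1L)
        return("nClusters must be a positive integer")
    if (!identical(sort(unique(object@assignment)), seq_len(k)))
        return("cluster ids must be contiguous 1..nClusters")
    ## deterministic labelling: cluster id ordered by first member index
    first <- vapply(seq_len(k), function(i) which(object@assignment == i)[1L],
                    integer(1))
    if (is.unsorted(first))
        return("cluster ids must be ordered by first member index")
    TRUE
})

#' ClusterRanking: clusters ordered by their best-ranked member
#'
#' Produced by [clusterRank()]: the decoy clusters of one complex, ordered by
#' the ranking position of each cluster's best member.  `r` is the 1-based
#' rank of the first cluster whose top-ranked member decoy is near-native
#' (acceptable or better), or `NA` when no cluster is topped by a near-native.
#'
#' @slot nClusters number of clusters at the scoring cutoff.
#' @slot clusterOrder cluster ids, best cluster first.
#' @slot r rank of the first near-native-topped cluster (NA if none).
#' @export
setClass("ClusterRanking",
    representation(nClusters = "integer", clusterOrder = "integer",
                   r = "integer"))

setValidity("ClusterRanking", function(object) {
    if (length(object@nClusters) != 1L || object@nClusters < 1L)
        return("nClusters must be a positive integer")
    if (!is.na(object@r) && (object@r < 1L || object@r > object@nClusters))
        return("r must lie in 1..nClusters when present")
    TRUE
})

#' PreferenceGraph: pairwise ballot counts over decoys
#'
#' Complete weighted digraph over decoys: `weights[a, b]` counts the ensemble
#' rankings (ballots) that place decoy `a` above decoy `b`.  For total-order
#' ballots, `weights[a, b] + weights[b, a]` equals the ensemble size for every
#' pair `a != b`.
#'
#' @slot weights integer matrix of pairwise "ranked-higher" counts.
#' @slot nBallots ensemble size.
#' @export
setClass("PreferenceGraph",
    representation(weights = "matrix", nBallots = "integer"))

setValidity("PreferenceGraph", function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weights must be square")
    if (any(w < 0)) return("weights must be non-negative")
    if (nrow(w) > 1) {
        s <- w + t(w)
        diag(s) <- object@nBallots
        if (any(s != object@nBallots))
            return("weights[a,b] + weights[b,a] must equal nBallots")
    }
    TRUE
})

#' SplitPlan: repeated random complex splits for a training protocol
#'
#' Protocol `A` splits a base benchmark 2:1 into training and model-selection
#' sets, with a fixed held-out test set (e.g. a benchmark update); protocol
#' `B` splits all complexes 2:1:1 into training, model-selection and test
#' sets.
#'
#' @slot protocol `"A"` or `"B"`.
#' @slot repeats number of random splits.
#' @slot assignments list (one per repeat) of lists with character vectors
#'   `training`, `selection`, `test`.
#' @slot seed integer seed the plan was generated from.
#' @export
setClass("SplitPlan",
    representation(protocol = "character", repeats = "integer",
                   assignments = "list", seed = "integer"))

setValidity("SplitPlan", function(object) {
    if (!object@protocol %in% c("A", "B"))
        return("protocol must be 'A' or 'B'")
    if (length(object@assignments) != object@repeats)
        return("one assignment per repeat required")
    ok <- vapply(object@assignments, function(a)
        all(c("training", "selection", "test") %in% names(a)) &&
        !anyDuplicated(c(a$training, a$selection, a$test)), logical(1))
    if (!all(ok))
        return("each repeat needs disjoint training/selection/test sets")
    TRUE
})
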