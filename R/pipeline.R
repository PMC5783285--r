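#' Default regularization / ensemble-size metaparameter grid
#'
#' The soft-margin constant `c` is multiplicative, so it is sampled
#' logarithmically: 50 values spanning 1e-4 to 1e3 inclusive.  The ensemble
#' size `n` (models kept after selection) is sampled as the integers 1 to 50.
#' The full grid is 50 x 50.
#'
#' @param nC,nN number of grid points per axis.
#' @param cRange inclusive range of `c`.
#' @return List with numeric `c_values` and integer `n_values`.
#' @examples
#' g <- defaultMetaparameterGrid()
#' range(g$c_values)   # 1e-4, 1e3
#' @export
defaultMetaparameterGrid <- function(nC = 50L, nN = 50L,
                                     cRange = c(1e-4, 1e3)) {
    list(c_values = 10^seq(log10(cRange[1L]), log10(cRange[2L]),
                           length.out = nC),
         n_values = seq_len(nN))
}

#' Repeated random complex splits
#'
#' Protocol `A`: the base-benchmark complexes are split 2:1 into training and
#' model-selection sets (default 200 repeats) and the held-out update
#' complexes form a fixed test set.  Protocol `B`: all complexes are split
#' 2:1:1 into training, model-selection and test sets (default 800 repeats, so
#' each complex sits in roughly a quarter of the test sets).  Sizes are
#' floor-allocated by ratio with remainders assigned to the selection set
#' first, then test, then training (176 complexes under 2:1 gives 117/59; 8
#' under 2:1:1 gives 4/2/2).  The plan is fully reproducible from `seed`.
#'
#' @param complexIds ids of the base-benchmark complexes to split.
#' @param protocol `"A"` or `"B"`.
#' @param repeats number of random splits (defaults: 200 for A, 800 for B).
#' @param seed integer seed.
#' @param testIds protocol A only: ids of the fixed held-out test set.
#' @return A [SplitPlan-class].
#' @export
makeSplits <- function(complexIds, protocol = c("A", "B"), repeats = NULL,
                       seed = 1L, testIds = character()) {
    protocol <- match.arg(protocol)
    if (is.null(repeats)) repeats <- if (protocol == "A") 200L else 800L
    n <- length(complexIds)
    if (anyDuplicated(complexIds)) stop("complex ids must be unique")
    ratios <- if (protocol == "A") c(2, 1) else c(2, 1, 1)
    base <- floor(n * ratios / sum(ratios))
    if (any(base < 1L))
        stop("too few complexes to fill every role")
    rem <- n - sum(base)
    ## remainders: selection first, then test, then training
    pref <- if (protocol == "A") c(2L, 1L) else c(2L, 3L, 1L)
    for (i in seq_len(rem)) base[pref[i]] <- base[pref[i]] + 1L
    if (protocol == "A" && length(testIds) == 0L)
        stop("protocol A requires a held-out test set (testIds)")
    rng <- .substreamSeeds(seed, repeats)
    assignments <- lapply(seq_len(repeats), function(rp) {
        set.seed(rng[rp])
        perm <- sample(complexIds)
        if (protocol == "A") {
            list(training = perm[seq_len(base[1L])],
                 selection = perm[base[1L] + seq_len(base[2L])],
                 test = as.character(testIds))
        } else {
            list(training = perm[seq_len(base[1L])],
                 selection = perm[base[1L] + seq_len(base[2L])],
                 test = perm[base[1L] + base[2L] + seq_len(base[3L])])
        }
    })
    new("SplitPlan", protocol = protocol, repeats = as.integer(repeats),
        assignments = assignments, seed = as.integer(seed))
}

## deterministic 32-bit substream seeds derived from one master seed
.substreamSeeds <- function(seed, n) {
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, n)
}

setMethod("show", "SplitPlan", function(object) {
    a <- object@assignments[[1L]]
    cat(sprintf(
        "SplitPlan protocol %s: %d repeats (train %d / select %d / test %d)\n",
        object@protocol, object@repeats, length(a$training),
        length(a$selection), length(a$test)))
    invisible(object)
})

#' Impute, fit and apply z-score normalization across a decoy collection
#'
#' Convenience wrapper: pooled-mean imputation over the collection, z-score
#' parameters fitted on the pooled decoys (optionally restricted to
#' `trainingIds`), then applied to every set.
#'
#' @param sets named list of [DecoySet-class] objects (one docking method).
#' @param schema a [FeatureSchema-class].
#' @param trainingIds complex ids to fit the normalizer on (default: all).
#' @return List with `sets` (normalized) and the fitted `schema`.
#' @export
prepareDecoySets <- function(sets, schema, trainingIds = names(sets)) {
    sets <- imputeMissing(sets)
    names(sets) <- vapply(sets, complexId, character(1))
    schema <- fitNormalizer(sets[trainingIds], schema)
    sets <- lapply(sets, applyNormalizer, schema = schema)
    list(sets = sets, schema = schema)
}

#' Scoring-time clusterings for a decoy collection
#'
#' Single-linkage clustering of every complex's decoys at the scoring cutoff
#' (default 3.5 angstrom), from coordinates when present or from a supplied
#' per-complex distance matrix otherwise.
#'
#' @param sets named list of [DecoySet-class] objects.
#' @param cutoff scoring cutoff in angstrom.
#' @param distances optional named list of precomputed distance matrices for
#'   sets without coordinates.
#' @return Named list of [Clustering-class] objects.
#' @export
scoringClusterings <- function(sets, cutoff = defaultConfig()$scoringCutoff,
                               distances = NULL) {
    out <- lapply(sets, function(s) {
        id <- complexId(s)
        d <- if (!is.null(distances) && !is.null(distances[[id]]))
            distances[[id]] else ligandRMSDMatrix(s)
        singleLinkage(d, cutoff)
    })
    names(out) <- vapply(sets, complexId, character(1))
    out
}

#' Train ranking-SVM models over splits and the c grid
#'
#' For every repeat of the split plan and every value of `c`, a ranking SVM is
#' trained on the pooled cross-category pairs of that repeat's training
#' complexes and scored (per-complex cluster-rank score) on its
#' model-selection complexes.  The result indexes every model by (c, repeat)
#' together with the per-complex score table needed for ensemble selection.
#'
#' @param sets named list of normalized, labelled [DecoySet-class] objects.
#' @param plan a [SplitPlan-class] over `names(sets)`.
#' @param cValues numeric vector of soft-margin constants (e.g.
#'   `defaultMetaparameterGrid()$c_values`).
#' @param clusterings named list of scoring-cutoff [Clustering-class] objects
#'   (see [scoringClusterings()]).
#' @param tolerance,maxEpochs solver controls, see [trainRankingSVM()].
#' @param verbose print per-repeat progress to stderr.
#' @return A model bank: list with `models` (list over c of lists over
#'   repeats), `sTable` (list over c of repeats x complexes score matrices,
#'   `NA` outside each model's selection set), `plan`, `cValues`.
#' @export
trainModelBank <- function(sets, plan, cValues, clusterings,
                           tolerance = 1e-6, maxEpochs = 20000L,
                           verbose = FALSE) {
    ids <- names(sets)
    stopifnot(!is.null(ids), all(vapply(sets, complexId, character(1)) == ids))
    nC <- length(cValues)
    models <- lapply(seq_len(nC), function(i) vector("list", plan@repeats))
    sTab <- lapply(seq_len(nC), function(i)
        matrix(NA_real_, plan@repeats, length(ids),
               dimnames = list(NULL, ids)))
    for (rp in seq_len(plan@repeats)) {
        a <- plan@assignments[[rp]]
        pairs <- buildPairs(sets[a$training])
        if (nPairs(pairs) == 0L)
            stop("repeat ", rp, ": training complexes contribute no ",
                 "cross-category pairs")
        if (verbose)
            message(sprintf("repeat %d/%d: %d pairs", rp, plan@repeats,
                            nPairs(pairs)))
        for (ci in seq_len(nC)) {
            m <- trainRankingSVM(pairs, cValues[ci], tolerance = tolerance,
                                 maxEpochs = maxEpochs)
            models[[ci]][[rp]] <- m
            for (id in a$selection) {
                rk <- rankByProjection(m, sets[[id]])
                cr <- clusterRank(sets[[id]], rk, clusterings[[id]])
                sTab[[ci]][rp, id] <- complexScore(cr)
            }
        }
    }
    list(models = models, sTable = sTab, plan = plan,
         cValues = as.numeric(cValues))
}

#' Consensus rankings for one metaparameter grid cell
#'
#' For a given `c` (by index into the bank) and ensemble size `n`, selects the
#' top-`n` models by ensemble-relative score and Schulze-aggregates their
#' projections into a consensus ranking per test complex.  Under protocol B
#' only models whose *test* set contains the complex are candidates, so no
#' complex is ever ranked by a model that saw it during training or model
#' selection.
#'
#' @param bank model bank from [trainModelBank()].
#' @param sets named list of normalized [DecoySet-class] objects.
#' @param cIdx index into `bank$cValues`.
#' @param n ensemble size.
#' @param testIds complexes to rank (default: the union of the plan's test
#'   sets).
#' @return Named list per complex: `ranking` (consensus permutation, best
#'   first) and `modelRepeats` (the repeat indices of the models used).
#' @export
gridCellRankings <- function(bank, sets, cIdx, n, testIds = NULL) {
    plan <- bank$plan
    S <- ensembleRelativeScores(bank$sTable[[cIdx]])
    if (is.null(testIds))
        testIds <- unique(unlist(lapply(plan@assignments, `[[`, "test")))
    out <- lapply(testIds, function(id) {
        cand <- if (plan@protocol == "B")
            which(vapply(plan@assignments,
                         function(a) id %in% a$test, logical(1)))
        else seq_len(plan@repeats)
        if (length(cand) == 0L)
            stop("complex ", id, ": no candidate models (is it in any ",
                 "test set?)")
        ## effective ensemble size is capped by the candidates available:
        ## under protocol B a complex sits in ~repeats/4 test sets
        sel <- cand[order(-S[cand], cand)[seq_len(min(n, length(cand)))]]
        rks <- lapply(sel, function(rp)
            rankByProjection(bank$models[[cIdx]][[rp]], sets[[id]]))
        list(ranking = consensusRanking(rks, initialRanks(sets[[id]])),
             modelRepeats = sel)
    })
    names(out) <- testIds
    out
}

#' Evaluate every metaparameter grid cell on synthetic or held-out complexes
#'
#' Computes, for each (c, n) cell, each test complex's consensus ranking, its
#' cluster-rank score `s_i` and the consensus rank of its best near-native
#' decoy.
#'
#' @param bank model bank from [trainModelBank()].
#' @param sets named list of normalized [DecoySet-class] objects.
#' @param clusterings scoring-cutoff clusterings (see [scoringClusterings()]).
#' @param nValues integer ensemble sizes to evaluate.
#' @param testIds complexes to evaluate (default: the plan's test sets).
#' @return List with arrays `scores` and `bestNN`
#'   (`c x n x complex`), plus `rankings` (nested list
#'   `[[cIdx]][[nIdx]][[complex]]`) and `cValues`, `nValues`, `testIds`.
#' @export
evaluateGrid <- function(bank, sets, clusterings,
                         nValues = seq_len(bank$plan@repeats),
                         testIds = NULL) {
    if (is.null(testIds))
        testIds <- unique(unlist(lapply(bank$plan@assignments, `[[`, "test")))
    nC <- length(bank$cValues); nN <- length(nValues)
    dn <- list(NULL, NULL, testIds)
    scores <- array(NA_real_, c(nC, nN, length(testIds)), dimnames = dn)
    bestNN <- array(NA_real_, c(nC, nN, length(testIds)), dimnames = dn)
    rankings <- lapply(seq_len(nC), function(i) vector("list", nN))
    for (ci in seq_len(nC)) for (ni in seq_len(nN)) {
        cell <- gridCellRankings(bank, sets, ci, nValues[ni], testIds)
        rankings[[ci]][[ni]] <- cell
        for (id in testIds) {
            rk <- cell[[id]]$ranking
            cr <- clusterRank(sets[[id]], rk, clusterings[[id]])
            scores[ci, ni, id] <- complexScore(cr)
            bestNN[ci, ni, id] <- bestNearNativeRank(rk, labels(sets[[id]]))
        }
    }
    list(scores = scores, bestNN = bestNN, rankings = rankings,
         cValues = bank$cValues, nValues = as.integer(nValues),
         testIds = testIds)
}

#' Leave-one-out metaparameter selection
#'
#' For each test complex, the per-complex scores of *the remaining* complexes
#' are summed for every (c, n) grid cell and the argmax cell is assigned to
#' that complex; ties break to the smallest c, then the smallest n.  With a
#' single complex the leave-one-out sum is empty and the global argmax (sum
#' over all complexes) is used instead.
#'
#' @param gridScores `c x n x complex` array of per-complex scores (the
#'   `scores` element of [evaluateGrid()]).
#' @return Data frame: complex id, chosen `cIdx`, `nIdx`.
#' @export
looMetaparameters <- function(gridScores) {
    dims <- dim(gridScores)
    ids <- dimnames(gridScores)[[3L]]
    total <- apply(gridScores, c(1L, 2L), sum)
    pick <- function(mat) {
        best <- which(mat == max(mat), arr.ind = TRUE)
        best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
        best[1L, ]
    }
    out <- t(vapply(seq_len(dims[3L]), function(x) {
        loo <- if (dims[3L] > 1L) total - gridScores[, , x] else total
        pick(loo)
    }, integer(2)))
    data.frame(complex = ids, cIdx = out[, 1L], nIdx = out[, 2L],
               stringsAsFactors = FALSE)
}

#' Mode-average metaparameter selection (retrained-server mode)
#'
#' Picks the single (c, n) cell chosen most often by [looMetaparameters()]
#' across complexes (ties to smallest c then n): the cell a production server
#' retrained on the full benchmark would use for every new case.
#'
#' @param choices data frame from [looMetaparameters()].
#' @return Named integer vector with `cIdx` and `nIdx`.
#' @export
modeMetaparameters <- function(choices) {
    key <- paste(choices$cIdx, choices$nIdx)
    tab <- table(key)
    best <- names(tab)[tab == max(tab)]
    idx <- do.call(rbind, lapply(strsplit(best, " "), as.integer))
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    c(cIdx = idx[1L, 1L], nIdx = idx[1L, 2L])
}

#' Rank of the best near-native decoy under a ranking
#'
#' @param ranking integer permutation of decoy indices, best first.
#' @param labels ordered CAPRI factor.
#' @return Smallest ranking position holding a near-native decoy, or `NA`
#'   when the set contains none.
#' @export
bestNearNativeRank <- function(ranking, labels) {
    nn <- isNearNative(labels)
    if (!any(nn)) return(NA_real_)
    pos <- integer(length(ranking)); pos[ranking] <- seq_along(ranking)
    min(pos[nn])
}

#' Run the full re-ranking pipeline on a decoy collection
#'
#' End-to-end driver: normalization, scoring-cutoff clustering, repeated-split
#' ranking-SVM training over the `c` grid, per-cell consensus evaluation,
#' leave-one-out metaparameter selection, and final per-complex consensus
#' rankings at each complex's chosen (c, n).
#'
#' @param sets named list of labelled [DecoySet-class] objects (raw features;
#'   imputation and z-scoring happen inside).
#' @param schema a [FeatureSchema-class] matching the sets' feature columns.
#' @param protocol `"A"` or `"B"` (see [makeSplits()]).
#' @param repeats number of random splits.
#' @param cValues soft-margin grid values.
#' @param nValues ensemble sizes to evaluate.
#' @param seed integer seed for the split plan.
#' @param testIds protocol A: ids of the held-out test complexes.
#' @param scoringCutoff cluster-rank scoring cutoff (angstrom).
#' @param distances optional per-complex distance matrices when coordinates
#'   are absent.
#' @param metaparameters `"loo"` (default) or `"mode"` (retrained-server
#'   mode: one mode-average cell for all complexes).
#' @param tolerance,maxEpochs,verbose passed to [trainModelBank()].
#' @return List with `consensus` (named list: per-complex consensus
#'   permutation), `choices` (LOO metaparameter table), `grid` (full
#'   [evaluateGrid()] result), `bank`, `schema`, and `modelRepeats` (per
#'   complex, the repeats whose models voted).
#' @export
runPipeline <- function(sets, schema, protocol = c("B", "A"), repeats = 8L,
                        cValues = c(0.1, 1, 10),
                        nValues = c(1L, 2L, 4L), seed = 1L,
                        testIds = character(),
                        scoringCutoff = defaultConfig()$scoringCutoff,
                        distances = NULL, metaparameters = c("loo", "mode"),
                        tolerance = 1e-6, maxEpochs = 20000L,
                        verbose = FALSE) {
    protocol <- match.arg(protocol)
    metaparameters <- match.arg(metaparameters)
    names(sets) <- vapply(sets, complexId, character(1))
    prep <- prepareDecoySets(sets, schema)
    norm <- prep$sets
    clusterings <- scoringClusterings(norm, cutoff = scoringCutoff,
                                      distances = distances)
    baseIds <- if (protocol == "A") setdiff(names(sets), testIds)
               else names(sets)
    plan <- makeSplits(baseIds, protocol, repeats = repeats, seed = seed,
                       testIds = testIds)
    bank <- trainModelBank(norm, plan, cValues, clusterings,
                           tolerance = tolerance, maxEpochs = maxEpochs,
                           verbose = verbose)
    grid <- evaluateGrid(bank, norm, clusterings, nValues = nValues)
    choices <- looMetaparameters(grid$scores)
    if (metaparameters == "mode") {
        cell <- modeMetaparameters(choices)
        choices$cIdx <- cell[["cIdx"]]; choices$nIdx <- cell[["nIdx"]]
    }
    consensus <- list(); modelRepeats <- list()
    for (i in seq_len(nrow(choices))) {
        id <- choices$complex[i]
        cell <- grid$rankings[[choices$cIdx[i]]][[choices$nIdx[i]]][[id]]
        consensus[[id]] <- cell$ranking
        modelRepeats[[id]] <- cell$modelRepeats
    }
    list(consensus = consensus, choices = choices, grid = grid, bank = bank,
         schema = prep$schema, sets = norm, modelRepeats = modelRepeats)
}
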