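#' Construct a DecoySet
#'
#' @param complexId single string identifying the complex.
#' @param features numeric matrix, one row per decoy; `NA` marks missing
#'   descriptor values (imputed later with [imputeMissing()]).
#' @param labels CAPRI categories, as character or ordered factor.
#' @param initialRanks integer permutation of `1..n_decoys`; the docking
#'   engine's original ordering (1 = best).  Defaults to row order.
#' @param decoyIds decoy identifiers; default taken from rownames or
#'   generated as `d0001, d0002, ...`.
#' @param receptorCoords,ligandCoords optional lists of per-decoy
#'   `n_atoms x 3` C-alpha coordinate matrices (angstrom).
#' @param metadata free-form list.
#' @return A [DecoySet-class] object.
#' @examples
#' ds <- DecoySet("1ABC", matrix(rnorm(6), 3, 2,
#'                dimnames = list(NULL, c("f1", "f2"))),
#'                labels = c("incorrect", "acceptable", "incorrect"))
#' nDecoys(ds)
#' @export
DecoySet <- function(complexId, features, labels,
                     initialRanks = seq_len(nrow(features)),
                     decoyIds = NULL,
                     receptorCoords = list(), ligandCoords = list(),
                     metadata = list()) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (is.null(decoyIds))
        decoyIds <- rownames(features)
    if (is.null(decoyIds))
        decoyIds <- sprintf("d%04d", seq_len(nrow(features)))
    rownames(features) <- decoyIds
    new("DecoySet", complexId = as.character(complexId),
        decoyIds = as.character(decoyIds), features = features,
        labels = capriFactor(labels),
        initialRanks = as.integer(initialRanks),
        receptorCoords = receptorCoords, ligandCoords = ligandCoords,
        metadata = metadata)
}

#' @rdname DecoySet
#' @export
setMethod("complexId", "DecoySet", function(object) object@complexId)

#' @rdname DecoySet
#' @export
setMethod("decoyIds", "DecoySet", function(object) object@decoyIds)

#' @rdname DecoySet
#' @export
setMethod("features", "DecoySet", function(object) object@features)

#' @rdname DecoySet
#' @export
setReplaceMethod("features", "DecoySet", function(object, value) {
    object@features <- value
    validObject(object)
    object
})

#' @rdname DecoySet
#' @export
setMethod("labels", "DecoySet", function(object) object@labels)

#' @rdname DecoySet
#' @export
setMethod("initialRanks", "DecoySet", function(object) object@initialRanks)

#' @rdname DecoySet
#' @export
setMethod("receptorCoords", "DecoySet", function(object) object@receptorCoords)

#' @rdname DecoySet
#' @export
setMethod("ligandCoords", "DecoySet", function(object) object@ligandCoords)

#' @rdname DecoySet
#' @export
setMethod("hasCoordinates", "DecoySet", function(object)
    length(object@receptorCoords) > 0L && length(object@ligandCoords) > 0L)

#' @rdname DecoySet
#' @export
setMethod("nDecoys", "DecoySet", function(object) length(object@decoyIds))

#' Subset a DecoySet by decoy
#'
#' @param x a `DecoySet`.
#' @param i integer or logical index over decoys.  Initial ranks of the kept
#'   decoys are re-ranked to stay a permutation while preserving their order.
#' @param j,drop,... ignored.
#' @return A `DecoySet` with the selected decoys.
#' @export
setMethod("[", "DecoySet", function(x, i, j, ..., drop = FALSE) {
    idx <- seq_len(nDecoys(x))[i]
    new("DecoySet", complexId = x@complexId, decoyIds = x@decoyIds[idx],
        features = x@features[idx, , drop = FALSE],
        labels = x@labels[idx],
        initialRanks = as.integer(rank(x@initialRanks[idx],
                                       ties.method = "first")),
        receptorCoords = if (length(x@receptorCoords))
            x@receptorCoords[idx] else list(),
        ligandCoords = if (length(x@ligandCoords))
            x@ligandCoords[idx] else list(),
        metadata = x@metadata)
})

setMethod("show", "DecoySet", function(object) {
    nn <- sum(isNearNative(object@labels))
    cat(sprintf(
        "DecoySet %s: %d decoys, %d features, %d near-native, coords: %s\n",
        object@complexId, nDecoys(object), ncol(object@features), nn,
        if (hasCoordinates(object)) "yes" else "no"))
    invisible(object)
})

#' Does a decoy set contain a near-native pose?
#'
#' @param set a `DecoySet`.
#' @return `TRUE` when at least one decoy is of acceptable quality or better.
#' @export
hasNearNative <- function(set) any(isNearNative(labels(set)))
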