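#' Construct a FeatureSchema
#'
#' @param names ordered feature column names.
#' @param means,sigmas optional fitted z-score parameters (see
#'   [fitNormalizer()]).
#' @return A [FeatureSchema-class] object.
#' @examples
#' schema <- defaultFeatureSchema()
#' length(featureNames(schema))   # 91
#' @export
FeatureSchema <- function(names, means = rep(NA_real_, length(names)),
                          sigmas = rep(NA_real_, length(names))) {
    new("FeatureSchema", names = as.character(names),
        means = as.numeric(means), sigmas = as.numeric(sigmas))
}

#' Cluster-size feature cutoffs and column names
#'
#' Ligand-pose cluster sizes are computed by single-linkage clustering at
#' cutoffs 3.0 to 7.0 angstrom in 0.5 angstrom steps (9 cutoffs).
#'
#' @return `defaultClusterCutoffs`: numeric vector of the 9 cutoffs;
#'   `clusterSizeColumnNames`: the corresponding schema column names.
#' @export
defaultClusterCutoffs <- function() seq(3, 7, by = 0.5)

#' @rdname defaultClusterCutoffs
#' @param cutoffs cutoff values in angstrom.
#' @export
clusterSizeColumnNames <- function(cutoffs = defaultClusterCutoffs())
    sprintf("cluster_size_%.1fA", cutoffs)

#' Default 91-column feature schema
#'
#' 82 slots for externally computed physicochemical descriptors (placeholder
#' names `desc_01..desc_82`; descriptor computation is out of scope and any
#' names may be substituted) plus the 9 cluster-size columns, 91 in total.
#'
#' @param descriptorNames names for the external-descriptor slots (default 82
#'   placeholders).
#' @param cutoffs cluster-size cutoffs (default 3--7 angstrom by 0.5).
#' @return A [FeatureSchema-class].
#' @export
defaultFeatureSchema <- function(descriptorNames = sprintf("desc_%02d", 1:82),
                                 cutoffs = defaultClusterCutoffs()) {
    FeatureSchema(c(descriptorNames, clusterSizeColumnNames(cutoffs)))
}

#' @rdname FeatureSchema
#' @export
setMethod("featureNames", "FeatureSchema", function(object) object@names)

#' @rdname FeatureSchema
#' @export
setMethod("isFitted", "FeatureSchema", function(object)
    length(object@names) > 0L && !anyNA(object@means) && !anyNA(object@sigmas))

setMethod("show", "FeatureSchema", function(object) {
    cat(sprintf("FeatureSchema: %d columns, %s\n", length(object@names),
                if (isFitted(object)) "fitted (z-score params present)"
                else "not fitted"))
    invisible(object)
})

#' Read or write a schema (with normalization parameters) as JSON
#'
#' @param schema a `FeatureSchema`.
#' @param path file path.
#' @return `readSchema` returns a `FeatureSchema`; `writeSchema` returns
#'   `path` invisibly.
#' @export
writeSchema <- function(schema, path) {
    jsonlite::write_json(
        list(names = schema@names, means = schema@means,
             sigmas = schema@sigmas),
        path, digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    n <- length(x$names)
    FeatureSchema(x$names,
                  means = if (is.null(x$means)) rep(NA_real_, n)
                          else as.numeric(x$means),
                  sigmas = if (is.null(x$sigmas)) rep(NA_real_, n)
                           else as.numeric(x$sigmas))
}

#' Pipeline default constants
#'
#' Defaults used throughout the pipeline: decoy lists are truncated to the
#' docking program's top 500 poses (training cost grows quadratically in
#' decoys per complex), and model-selection scoring clusters decoys at a
#' 3.5 angstrom single-linkage cutoff.
#'
#' @return Named list with elements `truncateLimit` (500) and
#'   `scoringCutoff` (3.5, angstrom).
#' @examples
#' defaultConfig()
#' @export
defaultConfig <- function() list(truncateLimit = 500L, scoringCutoff = 3.5)
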