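## Reserved (non-feature) columns of a decoy feature table.
.reservedCols <- c("decoy_id", "initial_rank", "label",
                   "fnat", "lrmsd", "irmsd")

#' Read a decoy feature table
#'
#' Parses a TSV with one row per decoy.  Reserved columns: `decoy_id`,
#' `initial_rank`, and either `label` (CAPRI category names) or the raw
#' quality metrics `fnat`, `lrmsd`, `irmsd` from which labels are derived with
#' [capriCategorize()].  When both are present the explicit `label` column
#' wins.  All remaining columns must match the schema's feature names in
#' order.  Empty feature cells (or `NA`) are kept as missing markers for
#' [imputeMissing()].
#'
#' @param path path to the TSV file.
#' @param schema a [FeatureSchema-class]; its names define the expected
#'   feature columns.
#' @param complexId complex identifier; defaults to the file name without
#'   extension.
#' @param thresholds CAPRI thresholds used when labels are derived from
#'   fnat/lrmsd/irmsd.
#' @return A [DecoySet-class].
#' @seealso [writeDecoyTable()]
#' @export
readDecoyTable <- function(path, schema, complexId = NULL,
                           thresholds = capriThresholds()) {
    if (is.null(complexId))
        complexId <- sub("\\.[^.]*$", "", basename(path))
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                     colClasses = "character", na.strings = c("NA", ""))
    hdr <- colnames(df)
    featCols <- setdiff(hdr, .reservedCols)
    if (!"decoy_id" %in% hdr || !"initial_rank" %in% hdr)
        stop("malformed header in ", path,
             ": decoy_id and initial_rank columns are required")
    hasLabel <- "label" %in% hdr
    hasMetrics <- all(c("fnat", "lrmsd", "irmsd") %in% hdr)
    if (!hasLabel && !hasMetrics)
        stop("malformed header in ", path,
             ": need a label column or fnat/lrmsd/irmsd columns")
    if (!identical(featCols, featureNames(schema)))
        stop("malformed header in ", path,
             ": feature columns do not match schema (expected ",
             length(featureNames(schema)), " columns in schema order)")
    ids <- df$decoy_id
    if (anyDuplicated(ids))
        stop("duplicate decoy_id in ", path, ": ",
             ids[anyDuplicated(ids)])
    feat <- matrix(NA_real_, nrow(df), length(featCols),
                   dimnames = list(ids, featCols))
    for (j in featCols) {
        raw <- df[[j]]
        val <- suppressWarnings(as.numeric(raw))
        bad <- which(!is.na(raw) & is.na(val))
        if (length(bad))
            stop(sprintf("non-numeric feature cell in %s: row %d, column %s",
                         path, bad[1L], j))
        feat[, j] <- val
    }
    lab <- if (hasLabel) capriFactor(df$label)
           else capriCategorize(as.numeric(df$fnat), as.numeric(df$lrmsd),
                                as.numeric(df$irmsd), thresholds)
    DecoySet(complexId, feat, lab,
             initialRanks = as.integer(df$initial_rank), decoyIds = ids)
}

#' Write a decoy feature table
#'
#' Inverse of [readDecoyTable()]: writes decoy_id, initial_rank, label and the
#' feature columns as TSV.  Feature values are written with 17 significant
#' digits so that a read/write/read round trip is exact.
#'
#' @param set a [DecoySet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDecoyTable <- function(set, path) {
    feat <- features(set)
    fmt <- apply(feat, 2, function(x)
        ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
    if (nDecoys(set) == 1L) fmt <- matrix(fmt, nrow = 1L)
    df <- data.frame(decoy_id = decoyIds(set),
                     initial_rank = initialRanks(set),
                     label = as.character(labels(set)),
                     fmt, check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("decoy_id", "initial_rank", "label", colnames(feat))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

#' Impute missing descriptor values by the pooled column mean
#'
#' Every missing feature cell is replaced by the mean of that column computed
#' over *all* decoys of *all* sets in the collection.  Callers wanting
#' per-docking-method imputation group the sets by method before calling.
#' Non-missing cells are never altered.
#'
#' @param sets list of [DecoySet-class] objects sharing one schema.
#' @return List of `DecoySet`s with no missing feature values.
#' @export
imputeMissing <- function(sets) {
    if (inherits(sets, "DecoySet")) sets <- list(sets)
    stopifnot(length(sets) >= 1L)
    pooled <- do.call(rbind, lapply(sets, features))
    mu <- colMeans(pooled, na.rm = TRUE)
    if (anyNA(mu))
        stop("column(s) entirely missing across the collection: ",
             paste(colnames(pooled)[is.na(mu)], collapse = ", "))
    lapply(sets, function(s) {
        f <- features(s)
        idx <- which(is.na(f), arr.ind = TRUE)
        if (nrow(idx)) f[idx] <- mu[idx[, 2L]]
        features(s) <- f
        s
    })
}

#' Fit z-score normalization parameters on a training pool
#'
#' Per-column mean and population standard deviation are computed over all
#' decoys of all training sets pooled; the fitted parameters are stored in the
#' schema and later applied unchanged to held-out and new decoy sets (the
#' training mean/sigma, never the new set's own).  Constant columns
#' (sigma = 0) are flagged with a warning and transform to zeros.
#'
#' @param trainingSets list of imputed [DecoySet-class] objects.
#' @param schema the [FeatureSchema-class] to fit.
#' @return The schema with `means` and `sigmas` filled in.
#' @seealso [applyNormalizer()]
#' @export
fitNormalizer <- function(trainingSets, schema) {
    if (inherits(trainingSets, "DecoySet")) trainingSets <- list(trainingSets)
    if (length(trainingSets) == 0L)
        stop("empty training collection")
    pooled <- do.call(rbind, lapply(trainingSets, features))
    if (anyNA(pooled))
        stop("normalization requires imputed features (no missing values)")
    n <- nrow(pooled)
    mu <- colMeans(pooled)
    ## population sigma (divide by n), so a fitted pool has z-scores with
    ## mean 0 and sigma exactly 1
    sigma <- sqrt(colMeans(sweep(pooled, 2L, mu)^2))
    if (any(sigma == 0))
        warning("constant feature column(s) flagged (sigma = 0): ",
                paste(colnames(pooled)[sigma == 0], collapse = ", "))
    schema@means <- unname(mu)
    schema@sigmas <- unname(sigma)
    validObject(schema)
    schema
}

#' Apply fitted z-score normalization to a decoy set
#'
#' @param set a [DecoySet-class] with imputed features.
#' @param schema a fitted [FeatureSchema-class] (see [fitNormalizer()]).
#' @return The set with features transformed to z-scores; sigma-0 columns map
#'   to zero.
#' @export
applyNormalizer <- function(set, schema) {
    if (!isFitted(schema))
        stop("schema has no fitted normalization parameters")
    f <- features(set)
    if (ncol(f) != length(schema@names))
        stop("feature width does not match schema")
    z <- sweep(f, 2L, schema@means)
    denom <- ifelse(schema@sigmas == 0, 1, schema@sigmas)
    z <- sweep(z, 2L, denom, "/")
    z[, schema@sigmas == 0] <- 0
    features(set) <- z
    set
}

#' Truncate a decoy set to the docking program's top poses
#'
#' Keeps only decoys whose initial rank is at most `limit` (default 500, see
#' [defaultConfig()]): ranking-SVM training cost grows quadratically with
#' decoys per complex.  The returned set's metadata records whether any
#' near-native pose survived (`metadata$nearNativeRetained`); complexes where
#' the only near-natives fall below the cutoff are excluded from retrieval
#' statistics downstream.
#'
#' @param set a [DecoySet-class].
#' @param limit positive integer rank cutoff.
#' @return The truncated `DecoySet`.
#' @export
truncateToTop <- function(set, limit = defaultConfig()$truncateLimit) {
    if (length(limit) != 1L || limit < 1L)
        stop("limit must be a positive integer")
    keep <- initialRanks(set) <= limit
    out <- set[keep]
    out@metadata$nearNativeRetained <- hasNearNative(out)
    out
}
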