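#' Superpose a decoy's receptor onto a reference and carry the ligand along
#'
#' Computes the least-squares rigid-body transform (Kabsch rotation plus
#' translation, via SVD) that superposes the decoy receptor C-alpha
#' coordinates onto the reference receptor, and applies that transform to the
#' decoy's ligand coordinates.  Receptor atoms must correspond one-to-one.
#'
#' @param referenceReceptor,decoyReceptor `n_atoms x 3` matrices (angstrom),
#'   equal length, `n_atoms >= 3`.
#' @param decoyLigand `m x 3` ligand coordinates to transform.
#' @return The transformed ligand coordinates (`m x 3`).
#' @export
superposeReceptor <- function(referenceReceptor, decoyReceptor, decoyLigand) {
    X <- as.matrix(referenceReceptor); Y <- as.matrix(decoyReceptor)
    L <- as.matrix(decoyLigand)
    if (nrow(X) != nrow(Y))
        stop("receptor coordinate arrays must have equal length")
    if (nrow(X) < 3L)
        stop("at least 3 receptor atoms are required for superposition")
    cx <- colMeans(X); cy <- colMeans(Y)
    H <- crossprod(sweep(Y, 2L, cy), sweep(X, 2L, cx))
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # rotation: x' = R %*% y
    t(R %*% (t(L) - cy) + cx)
}

#' Pairwise ligand-RMSD distance matrix
#'
#' Each decoy's receptor is superposed onto a common reference receptor
#' (default: the first decoy's receptor) and the ligand C-alpha coordinates
#' are carried along; entry (i, j) is then the RMSD between the superposed
#' ligand coordinates of decoys i and j.
#'
#' @param set a [DecoySet-class] with coordinates.
#' @param referenceReceptor optional `n x 3` reference receptor; defaults to
#'   the first decoy's receptor.
#' @return Symmetric `n_decoys x n_decoys` matrix of ligand RMSD (angstrom),
#'   zero diagonal.
#' @export
ligandRMSDMatrix <- function(set, referenceReceptor = NULL) {
    if (!hasCoordinates(set))
        stop("decoy set has no coordinates")
    rec <- receptorCoords(set); lig <- ligandCoords(set)
    natoms <- nrow(lig[[1L]])
    if (!all(vapply(lig, nrow, integer(1)) == natoms))
        stop("all ligands must have the same atom count")
    if (is.null(referenceReceptor)) referenceReceptor <- rec[[1L]]
    sup <- mapply(function(r, l) superposeReceptor(referenceReceptor, r, l),
                  rec, lig, SIMPLIFY = FALSE)
    flat <- do.call(rbind, lapply(sup, as.vector))
    d <- as.matrix(dist(flat)) / sqrt(natoms)
    dimnames(d) <- list(decoyIds(set), decoyIds(set))
    d
}

#' Single-linkage clustering at a distance cutoff
#'
#' Two decoys share a cluster iff they are connected by a chain of pairwise
#' distances `<= cutoff` (inclusive): the clusters are the connected
#' components of the threshold graph.  Cluster ids are assigned in order of
#' each cluster's first member index, so the partition and labels are
#' invariant to decoy ordering up to relabelling.
#'
#' @param distances symmetric non-negative distance matrix.
#' @param cutoff positive distance cutoff (angstrom).
#' @return A [Clustering-class].
#' @export
singleLinkage <- function(distances, cutoff) {
    if (cutoff <= 0) stop("cutoff must be positive")
    d <- as.matrix(distances)
    if (nrow(d) != ncol(d) || any(d < 0) || any(abs(d - t(d)) > 1e-12))
        stop("distances must be a symmetric non-negative matrix")
    adj <- d <= cutoff
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    ## relabel so cluster ids follow first-member order
    first <- match(sort(unique(memb)), memb)
    relab <- match(memb, memb[sort(first)])
    new("Clustering", cutoff = as.numeric(cutoff),
        assignment = as.integer(relab), nClusters = max(relab))
}

#' @rdname Clustering
#' @export
setMethod("nClusters", "Clustering", function(object) object@nClusters)

#' @rdname Clustering
#' @export
setMethod("clusterAssignment", "Clustering", function(object)
    object@assignment)

setMethod("show", "Clustering", function(object) {
    cat(sprintf("Clustering: %d decoys in %d cluster(s) at %.1f A\n",
                length(object@assignment), object@nClusters, object@cutoff))
    invisible(object)
})

#' Cluster-size descriptor columns
#'
#' For each cutoff (default 3.0--7.0 angstrom by 0.5), decoys are clustered by
#' single linkage on the ligand-RMSD matrix and each decoy receives the size
#' of its own cluster; large clusters of similar poses are a classic signal of
#' a favourable energy funnel.  The 9 columns complete the default 91-column
#' schema.
#'
#' @param set a [DecoySet-class] with coordinates, or `distances` supplied.
#' @param cutoffs clustering cutoffs (angstrom).
#' @param distances optional precomputed distance matrix (used when
#'   coordinates are absent).
#' @return `n_decoys x length(cutoffs)` matrix, columns named per
#'   [clusterSizeColumnNames()].
#' @export
clusterSizeFeatures <- function(set, cutoffs = defaultClusterCutoffs(),
                                distances = NULL) {
    if (is.null(distances)) distances <- ligandRMSDMatrix(set)
    out <- vapply(cutoffs, function(ct) {
        cl <- singleLinkage(distances, ct)
        sizes <- tabulate(cl@assignment, nbins = cl@nClusters)
        as.numeric(sizes[cl@assignment])
    }, numeric(nrow(as.matrix(distances))))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
    dimnames(out) <- list(decoyIds(set), clusterSizeColumnNames(cutoffs))
    out
}

#' Cache a decoy distance matrix as TSV
#'
#' Distance matrices are expensive for large decoy sets; these helpers write
#' and re-read them as plain TSV (decoy ids in the first column and header),
#' the fallback input for scoring-time clustering when coordinates are
#' absent.
#'
#' @param distances symmetric matrix with decoy ids as dimnames.
#' @param path file path.
#' @return `readDistanceMatrix` returns the matrix; `writeDistanceMatrix`
#'   returns `path` invisibly.
#' @export
writeDistanceMatrix <- function(distances, path) {
    d <- as.matrix(distances)
    df <- data.frame(decoy_id = rownames(d),
                     apply(d, 2, function(x) sprintf("%.17g", x)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("decoy_id", colnames(d))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
}
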