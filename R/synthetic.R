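#' Specification for synthetic decoy sets
#'
#' Describes a synthetic benchmark emulating per-complex docking decoy tables:
#' a planted linear quality signal in the descriptor columns, geometrically
#' clustered ligand poses, CAPRI labels drawn from fixed category fractions,
#' and initial ranks produced by a deliberately imperfect "docking engine"
#' ordering.
#'
#' Latent quality bands per category (fixed): incorrect `[0, 0.25)`,
#' acceptable `[0.25, 0.5)`, medium `[0.5, 0.75)`, high `[0.75, 1]`.
#' Descriptor features are `quality * w*/||w*|| + N(0, noiseSigma)`; the
#' cluster-size schema columns are computed from the generated coordinates,
#' and the planted weight vector has zero entries there.  Initial ranks order
#' decoys by `quality + N(0, rankNoise)`: with the default `rankNoise = 0.5`
#' the engine's own ordering is informative but far from perfect, as real
#' docking rankings are.
#'
#' @param nComplexes number of complexes.
#' @param decoysPerComplex decoys per complex (default 500, the pipeline's
#'   truncation limit).
#' @param nFeatures total schema width (default 91; the last 9 columns are
#'   cluster sizes, the rest descriptor slots carrying the planted signal).
#' @param plantedWeights optional planted weight vector over the descriptor
#'   slots; default a fixed random unit vector drawn from the seed.
#' @param noiseSigma isotropic feature noise s.d. (default 0.1).
#' @param categoryFractions named proportions over the CAPRI categories
#'   (default: incorrect 0.95, acceptable 0.03, medium 0.015, high 0.005 —
#'   docking decoy sets are overwhelmingly incorrect).
#' @param nPoseClusters,clusterSpread,clusterSeparation ligand-pose geometry:
#'   number of pose clusters, intra-cluster spread and inter-cluster centre
#'   separation in angstrom (defaults 10, 1, 20; separation must exceed
#'   spread so single linkage at 3.5 angstrom recovers the planted clusters).
#' @param rankNoise s.d. of the noise added to quality when drawing initial
#'   ranks (default 0.5).
#' @param nLigandAtoms,nReceptorAtoms C-alpha counts of the point-cloud
#'   ligand/receptor (defaults 20, 30).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return A `SyntheticSpec` (classed list).
#' @export
syntheticSpec <- function(nComplexes = 20L, decoysPerComplex = 500L,
                          nFeatures = 91L, plantedWeights = NULL,
                          noiseSigma = 0.1,
                          categoryFractions = c(incorrect = 0.95,
                                                acceptable = 0.03,
                                                medium = 0.015,
                                                high = 0.005),
                          nPoseClusters = 10L, clusterSpread = 1,
                          clusterSeparation = 20, rankNoise = 0.5,
                          nLigandAtoms = 20L, nReceptorAtoms = 30L,
                          seed = 1L) {
    if (abs(sum(categoryFractions) - 1) > 1e-8)
        stop("category fractions must sum to 1")
    if (!all(names(categoryFractions) %in% capriLevels()))
        stop("category fractions must be named by CAPRI level")
    if (clusterSpread <= 0 || clusterSeparation <= clusterSpread)
        stop("need positive spread and separation > spread")
    nDesc <- nFeatures - 9L
    if (nDesc < 1L) stop("nFeatures must leave at least 1 descriptor slot")
    structure(list(nComplexes = as.integer(nComplexes),
                   decoysPerComplex = as.integer(decoysPerComplex),
                   nFeatures = as.integer(nFeatures), nDesc = nDesc,
                   plantedWeights = plantedWeights, noiseSigma = noiseSigma,
                   categoryFractions = categoryFractions,
                   nPoseClusters = as.integer(nPoseClusters),
                   clusterSpread = clusterSpread,
                   clusterSeparation = clusterSeparation,
                   rankNoise = rankNoise,
                   nLigandAtoms = as.integer(nLigandAtoms),
                   nReceptorAtoms = as.integer(nReceptorAtoms),
                   seed = as.integer(seed)),
              class = "SyntheticSpec")
}

## quality band per CAPRI category
.qualityBands <- matrix(c(0, 0.25, 0.25, 0.5, 0.5, 0.75, 0.75, 1),
                        nrow = 2, dimnames = list(c("lo", "hi"),
                                                  .capriLevels))

#' Generate synthetic decoy sets
#'
#' See [syntheticSpec()] for the generative model.  Returned sets carry raw
#' (un-normalized) features: the descriptor slots hold the planted linear
#' signal plus noise, and the final 9 columns hold true cluster sizes computed
#' from the generated ligand coordinates.  Every decoy's receptor+ligand pair
#' is additionally subjected to a random rigid motion, so receptor
#' superposition is exercised on the RMSD path.
#'
#' @param spec a `SyntheticSpec`.
#' @param schema optional [FeatureSchema-class]; default built to match
#'   `spec$nFeatures`.
#' @return Named list of [DecoySet-class] objects.  The planted unit weight
#'   vector (padded with zeros over the cluster-size columns) is attached as
#'   `attr(, "plantedWeights")`.
#' @examples
#' sets <- generateDecoySets(syntheticSpec(nComplexes = 2,
#'                           decoysPerComplex = 30, seed = 7))
#' sets[[1]]
#' @export
generateDecoySets <- function(spec, schema = NULL) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    if (is.null(schema))
        schema <- defaultFeatureSchema(
            descriptorNames = sprintf("desc_%02d", seq_len(spec$nDesc)))
    stopifnot(length(featureNames(schema)) == spec$nFeatures)
    set.seed(spec$seed)
    wStar <- spec$plantedWeights
    if (is.null(wStar)) wStar <- rnorm(spec$nDesc)
    stopifnot(length(wStar) == spec$nDesc)
    wStar <- wStar / sqrt(sum(wStar^2))
    n <- spec$decoysPerComplex
    ligTemplate <- matrix(rnorm(spec$nLigandAtoms * 3, sd = 3), ncol = 3)
    recTemplate <- matrix(rnorm(spec$nReceptorAtoms * 3, sd = 5), ncol = 3)
    ## pose-cluster centres on a line, `separation` apart
    centres <- cbind((seq_len(spec$nPoseClusters) - 1L) *
                     spec$clusterSeparation, 0, 0)
    sets <- lapply(seq_len(spec$nComplexes), function(k) {
        id <- sprintf("synth%03d", k)
        cat_n <- drop(stats::rmultinom(1L, n, spec$categoryFractions))
        labels <- rep(names(spec$categoryFractions), cat_n)
        quality <- runif(n, .qualityBands["lo", labels],
                         .qualityBands["hi", labels])
        desc <- quality %o% wStar +
            matrix(rnorm(n * spec$nDesc, sd = spec$noiseSigma), n)
        ## ligand poses: cluster membership independent of quality
        cl <- sample.int(spec$nPoseClusters, n, replace = TRUE)
        rec <- vector("list", n); lig <- vector("list", n)
        for (i in seq_len(n)) {
            jitter <- matrix(rnorm(3, sd = spec$clusterSpread / sqrt(3)),
                             nrow(ligTemplate), 3, byrow = TRUE)
            L <- ligTemplate + jitter
            L <- sweep(L, 2L, -centres[cl[i], ])
            ## random rigid motion of the whole decoy (receptor + ligand)
            R <- .randomRotation()
            tr <- rnorm(3, sd = 10)
            rec[[i]] <- sweep(recTemplate %*% R, 2L, -tr)
            lig[[i]] <- sweep(L %*% R, 2L, -tr)
        }
        initialRanks <- integer(n)
        noisy <- quality + rnorm(n, sd = spec$rankNoise)
        initialRanks[order(-noisy)] <- seq_len(n)
        ds <- DecoySet(id,
                       cbind(desc, matrix(0, n, 9L)), labels,
                       initialRanks = initialRanks,
                       decoyIds = sprintf("%s_d%04d", id, seq_len(n)),
                       receptorCoords = rec, ligandCoords = lig)
        colnames(ds@features) <- featureNames(schema)
        f <- features(ds)
        f[, spec$nDesc + seq_len(9L)] <- clusterSizeFeatures(ds)
        features(ds) <- f
        ds
    })
    names(sets) <- vapply(sets, complexId, character(1))
    attr(sets, "plantedWeights") <- c(wStar, rep(0, 9L))
    sets
}

## uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.randomRotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
}

#' Write synthetic decoy sets as TSV tables and PDB coordinate files
#'
#' One `<complex>.tsv` feature table per complex (see [writeDecoyTable()]),
#' plus, when coordinates are present, PDB-format C-alpha files
#' `<complex>_<decoy>.pdb` with receptor chain R and ligand chain L.
#'
#' @param sets named list of [DecoySet-class] objects.
#' @param dir output directory (created if needed).
#' @param writeCoordinates also write per-decoy PDB files (default FALSE; the
#'   files are numerous).
#' @param writeDistances also cache each complex's ligand-RMSD matrix as
#'   `<complex>_distances.tsv` (the scoring-time clustering input when
#'   coordinates are not shipped).
#' @return `dir`, invisibly.
#' @export
writeDecoySets <- function(sets, dir, writeCoordinates = FALSE,
                           writeDistances = FALSE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in sets) {
        writeDecoyTable(s, file.path(dir, paste0(complexId(s), ".tsv")))
        if (writeDistances && hasCoordinates(s))
            writeDistanceMatrix(ligandRMSDMatrix(s),
                                file.path(dir, paste0(complexId(s),
                                                      "_distances.tsv")))
        if (writeCoordinates && hasCoordinates(s)) {
            for (i in seq_len(nDecoys(s))) {
                path <- file.path(dir, sprintf("%s_%s.pdb", complexId(s),
                                               decoyIds(s)[i]))
                writePDBPose(receptorCoords(s)[[i]], ligandCoords(s)[[i]],
                             path)
            }
        }
    }
    invisible(dir)
}

#' Write / read a two-chain C-alpha pose in PDB format
#'
#' Minimal PDB ATOM records: receptor C-alphas on chain R, ligand C-alphas on
#' chain L.  `readPDBPose` parses such a file back into the two coordinate
#' matrices (any chain ids may be designated receptor/ligand).
#'
#' @param receptor,ligand `n x 3` coordinate matrices (angstrom).
#' @param path file path.
#' @param receptorChain,ligandChain chain identifiers.
#' @return `readPDBPose`: list with `receptor` and `ligand` matrices.
#' @export
writePDBPose <- function(receptor, ligand, path, receptorChain = "R",
                         ligandChain = "L") {
    fmt <- function(coords, chain, offset)
        sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                offset + seq_len(nrow(coords)), chain, seq_len(nrow(coords)),
                coords[, 1L], coords[, 2L], coords[, 3L])
    writeLines(c(fmt(receptor, receptorChain, 0L),
                 fmt(ligand, ligandChain, nrow(receptor)), "END"), path)
    invisible(path)
}

#' @rdname writePDBPose
#' @export
readPDBPose <- function(path, receptorChain = "R", ligandChain = "L") {
    lines <- readLines(path)
    atoms <- lines[startsWith(lines, "ATOM")]
    ca <- atoms[substr(atoms, 13, 16) == " CA "]
    chain <- substr(ca, 22, 22)
    coords <- cbind(as.numeric(substr(ca, 31, 38)),
                    as.numeric(substr(ca, 39, 46)),
                    as.numeric(substr(ca, 47, 54)))
    list(receptor = coords[chain == receptorChain, , drop = FALSE],
         ligand = coords[chain == ligandChain, , drop = FALSE])
}
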