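#' Default CAPRI classification thresholds
#'
#' The community CAPRI criteria classify a docked pose from its fraction of
#' native contacts (fnat), ligand RMSD and interface RMSD.  A pose is assigned
#' the *highest* category whose criteria it meets:
#' \itemize{
#'   \item high: fnat >= 0.5 and (L-RMSD <= 1 or I-RMSD <= 1)
#'   \item medium: fnat >= 0.3 and (L-RMSD <= 5 or I-RMSD <= 2)
#'   \item acceptable: fnat >= 0.1 and (L-RMSD <= 10 or I-RMSD <= 4)
#'   \item incorrect: otherwise
#' }
#' The thresholds are exposed as configuration so criterion variants can be
#' swapped in.
#'
#' @return Nested list: one element per non-incorrect category, each with
#'   `fnat`, `lrmsd`, `irmsd` thresholds.
#' @export
capriThresholds <- function() {
    list(acceptable = list(fnat = 0.1, lrmsd = 10, irmsd = 4),
         medium     = list(fnat = 0.3, lrmsd = 5,  irmsd = 2),
         high       = list(fnat = 0.5, lrmsd = 1,  irmsd = 1))
}

#' Classify docked poses with the CAPRI criteria
#'
#' Vectorized over poses.  Assigns the highest quality category whose
#' thresholds are met; see [capriThresholds()] for the defaults.
#'
#' @param fnat fraction of native residue--residue contacts, in `[0, 1]`.
#' @param lrmsd ligand RMSD (angstrom), `>= 0`.
#' @param irmsd interface RMSD (angstrom), `>= 0`.
#' @param thresholds threshold configuration, per [capriThresholds()].
#' @return Ordered CAPRI factor.
#' @examples
#' capriCategorize(fnat = c(0.8, 0.05, 0.2),
#'                 lrmsd = c(0.5, 2, 8), irmsd = c(0.5, 1, 3))
#' @export
capriCategorize <- function(fnat, lrmsd, irmsd,
                            thresholds = capriThresholds()) {
    n <- length(fnat)
    if (length(lrmsd) != n || length(irmsd) != n)
        stop("fnat, lrmsd and irmsd must have equal length")
    if (any(fnat < 0 | fnat > 1, na.rm = TRUE))
        stop("fnat must lie in [0, 1]")
    if (any(lrmsd < 0, na.rm = TRUE) || any(irmsd < 0, na.rm = TRUE))
        stop("RMSD values must be non-negative")
    out <- rep("incorrect", n)
    for (cat in c("acceptable", "medium", "high")) {  # ascending quality
        th <- thresholds[[cat]]
        hit <- fnat >= th$fnat & (lrmsd <= th$lrmsd | irmsd <= th$irmsd)
        out[which(hit)] <- cat
    }
    capriFactor(out)
}
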