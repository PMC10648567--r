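# Fingerprints and similarity.
#
# Similarity throughout the package is the average of the Morgan
# (circular, radius 2, folded to 2048 bits) and MACCS (166-key) Tanimoto
# coefficients, the composite used for the CBD-like screen.

#' Morgan (circular) fingerprint
#'
#' Radius-2 circular fingerprint (ECFP4 family), folded to 2048 bits.
#' Derived deterministically from the canonical structure, so notation
#' variants of one molecule share one fingerprint.
#' @param m a [Molecule-class].
#' @return logical vector of length 2048.
#' @export
morganFingerprint <- function(m) {
  stopifnot(is(m, "Molecule"))
  if (isEmptyMolecule(m)) return(logical(2048L))
  .obFingerprints(canonicalSmiles(m), "ECFP4")[1L, ]
}

#' MACCS key fingerprint
#'
#' The 166 predefined substructure presence keys.
#' @param m a [Molecule-class].
#' @return logical vector of length 166.
#' @export
maccsFingerprint <- function(m) {
  stopifnot(is(m, "Molecule"))
  if (isEmptyMolecule(m)) return(logical(166L))
  .obFingerprints(canonicalSmiles(m), "MACCS")[1L, ]
}

.tanimotoBits <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)  # identical (empty) fingerprints
  sum(a & b) / u
}

#' Tanimoto similarity of two bit vectors
#' @param a,b logical vectors of equal length.
#' @return similarity in \[0, 1\]; 1 iff the fingerprints are identical
#'   (two empty fingerprints count as identical).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  .tanimotoBits(as.logical(a), as.logical(b))
}

#' Average Morgan/MACCS Tanimoto similarity
#'
#' The screening similarity: the mean of the Morgan and MACCS Tanimoto
#' coefficients. Symmetric; equals 1 iff both fingerprints agree.
#' @param a,b [Molecule-class] objects.
#' @return similarity in \[0, 1\].
#' @examples
#' cbd <- parseSmiles(cbdSmiles())
#' avgTanimoto(cbd, cbd)  # 1
#' @export
avgTanimoto <- function(a, b) {
  stopifnot(is(a, "Molecule"), is(b, "Molecule"))
  (tanimoto(morganFingerprint(a), morganFingerprint(b)) +
     tanimoto(maccsFingerprint(a), maccsFingerprint(b))) / 2
}

# Batch similarity of many canonical SMILES against one reference,
# returning cbind(morgan, maccs, avg). Used by the library screen and
# the synthetic-data verifier.
.avgTanimotoBatch <- function(canSmiles, refCan) {
  if (!length(canSmiles))
    return(cbind(morgan = numeric(0), maccs = numeric(0), avg = numeric(0)))
  fpM <- .obFingerprints(c(refCan, canSmiles), "ECFP4")
  fpK <- .obFingerprints(c(refCan, canSmiles), "MACCS")
  refM <- fpM[1L, ]; refK <- fpK[1L, ]
  nM <- vapply(seq_along(canSmiles) + 1L,
               function(i) .tanimotoBits(fpM[i, ], refM), numeric(1))
  nK <- vapply(seq_along(canSmiles) + 1L,
               function(i) .tanimotoBits(fpK[i, ], refK), numeric(1))
  cbind(morgan = nM, maccs = nK, avg = (nM + nK) / 2)
}

#' The cannabidiol query fixture
#'
#' Stereochemistry-free SMILES of cannabidiol (CBD), the query ligand
#' and optimization seed shipped with the package.
#' @return a SMILES string.
#' @export
cbdSmiles <- function() {
  path <- system.file("extdata", "cbd.smi", package = "targan",
                      mustWork = TRUE)
  strsplit(readLines(path, n = 1L), "[ \t]+")[[1L]][1L]
}
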