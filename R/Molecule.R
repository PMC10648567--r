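#' Molecule: a parsed, canonicalized small molecule
#'
#' The central structure container. A `Molecule` records the SMILES as
#' given, OpenBabel's canonical SMILES, the kekulized heavy-atom graph,
#' and cached ring statistics. Parse failure never yields a `Molecule`:
#' [parseSmiles()] raises an error naming the offending input instead.
#' Stereochemistry is not modelled; notation variants of one structure
#' collapse to one canonical form.
#'
#' @slot smilesInput SMILES string as supplied.
#' @slot smilesCanonical OpenBabel canonical SMILES (empty only for the
#'   empty-scaffold sentinel, see [murckoScaffold()]).
#' @slot graph internal kekulized graph (element/charge/bond list).
#' @slot nAtoms heavy-atom count.
#' @slot nRings cyclomatic ring count.
#' @slot largestRingSize size of the largest smallest-ring, 0 if acyclic.
#' @slot scaffoldAtoms indices of Murcko-scaffold atoms when the object
#'   was produced by the GA machinery with a scaffold-aligned atom order;
#'   empty otherwise.
#' @seealso [parseSmiles()], [murckoScaffold()], [avgTanimoto()]
#' @export
setClass("Molecule",
         representation(smilesInput = "character",
                        smilesCanonical = "character",
                        graph = "list",
                        nAtoms = "integer",
                        nRings = "integer",
                        largestRingSize = "integer",
                        scaffoldAtoms = "integer"),
         prototype(smilesInput = "", smilesCanonical = "",
                   nAtoms = 0L, nRings = 0L, largestRingSize = 0L,
                   scaffoldAtoms = integer(0)))

setValidity("Molecule", function(object) {
  if (length(object@smilesCanonical) != 1L) return("one canonical SMILES required")
  if (object@nAtoms > 0L && !nzchar(object@smilesCanonical))
    return("non-empty molecule without canonical SMILES")
  if (object@nAtoms != .graphNAtoms(object@graph) && object@nAtoms > 0L)
    return("atom count does not match graph")
  TRUE
})

.moleculeFromGraph <- function(g, canonical, input = canonical,
                               scaffoldAtoms = integer(0)) {
  ri <- .ringInfo(g)
  new("Molecule", smilesInput = input, smilesCanonical = canonical,
      graph = g, nAtoms = .graphNAtoms(g), nRings = ri$nRings,
      largestRingSize = as.integer(ri$largest),
      scaffoldAtoms = as.integer(scaffoldAtoms))
}

#' Parse and canonicalize a SMILES string
#'
#' @param smiles a single non-empty SMILES string.
#' @return a [Molecule-class] object. Canonicalization is idempotent:
#'   re-parsing the canonical SMILES reproduces it.
#' @examples
#' m <- parseSmiles("c1ccccc1")
#' canonicalSmiles(m)
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("'smiles' must be a single non-empty string")
  mols <- parseSmilesBatch(smiles)
  if (is.null(mols[[1L]]))
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  mols[[1L]]
}

#' Parse a vector of SMILES
#'
#' Vectorized form of [parseSmiles()]. Unparseable entries come back as
#' `NULL` rather than raising, so callers screening libraries can report
#' offending records themselves.
#' @param smiles character vector of SMILES.
#' @return a list of [Molecule-class] or `NULL`, same length as `smiles`.
#' @export
parseSmilesBatch <- function(smiles) {
  out <- vector("list", length(smiles))
  if (!length(smiles)) return(out)
  can <- .obCanonical(smiles)
  graphs <- .obGraphs(smiles)
  for (i in seq_along(smiles)) {
    if (is.na(can[i]) || is.null(graphs[[i]])) next
    out[[i]] <- .moleculeFromGraph(graphs[[i]], can[i], input = smiles[i])
  }
  out
}

#' The empty-scaffold sentinel
#'
#' Acyclic molecules have no Murcko scaffold; [murckoScaffold()] returns
#' this zero-atom sentinel for them.
#' @return a `Molecule` with zero atoms and empty canonical SMILES.
#' @export
emptyMolecule <- function() {
  new("Molecule", smilesInput = "", smilesCanonical = "",
      graph = .emptyGraph(), nAtoms = 0L, nRings = 0L,
      largestRingSize = 0L, scaffoldAtoms = integer(0))
}

#' @rdname emptyMolecule
#' @param x a `Molecule`.
#' @export
isEmptyMolecule <- function(x) x@nAtoms == 0L

#' @describeIn Molecule-class canonical SMILES accessor.
#' @param x a `Molecule`.
#' @export
canonicalSmiles <- function(x) {
  stopifnot(is(x, "Molecule"))
  x@smilesCanonical
}

#' @describeIn Molecule-class heavy-atom count.
#' @export
numAtoms <- function(x) x@nAtoms

#' @describeIn Molecule-class ring (cyclomatic) count.
#' @export
numRings <- function(x) x@nRings

#' @describeIn Molecule-class largest smallest-ring size (0 if acyclic).
#' @export
largestRingSize <- function(x) x@largestRingSize

setMethod("show", "Molecule", function(object) {
  if (isEmptyMolecule(object)) {
    cat("Molecule: <empty scaffold>\n")
  } else {
    cat("Molecule:", object@smilesCanonical, "\n")
    cat("  atoms:", object@nAtoms, " rings:", object@nRings,
        " largest ring:", object@largestRingSize, "\n")
  }
  invisible(object)
})

#' Identity of two molecules by canonical structure
#'
#' @param a,b `Molecule` objects.
#' @return `TRUE` iff the canonical SMILES agree.
#' @export
sameStructure <- function(a, b) {
  identical(canonicalSmiles(a), canonicalSmiles(b))
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them, with all side chains
#' removed; atoms attached to the framework by a double or triple bond
#' (exocyclic carbonyls and the like) are retained. Acyclic molecules
#' yield the empty-scaffold sentinel. The operation is idempotent.
#'
#' @param m a [Molecule-class].
#' @return a `Molecule` holding the canonicalized scaffold.
#' @examples
#' canonicalSmiles(murckoScaffold(parseSmiles("Cc1ccccc1")))  # benzene
#' @export
murckoScaffold <- function(m) {
  stopifnot(is(m, "Molecule"))
  if (isEmptyMolecule(m)) return(emptyMolecule())
  keep <- .murckoKeepSet(m@graph)
  if (!any(keep)) return(emptyMolecule())
  sub <- .inducedSubgraph(m@graph, keep)
  can <- .obCanonicalFromGraphs(list(sub))
  if (is.na(can[1L]))
    stop("scaffold extraction produced an unparseable fragment for '",
         m@smilesCanonical, "'")
  .moleculeFromGraph(sub, can[1L])
}
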