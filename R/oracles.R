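# Scoring oracles.
#
# Two pluggable contracts stand between the pipeline and any external
# predictor: an affinity oracle (drug SMILES + target -> pIC50) and a
# docking oracle (molecule + target id -> kcal/mol, lower is stronger).
# The shipped implementations are deterministic surrogates driven by a
# SurrogateSpec, so the whole workflow runs and is testable offline.
# Adapters for external predictors implement the same function
# signatures; see the methods vignette.

#' SurrogateSpec: deterministic parameterization of both surrogates
#'
#' Fully determines the surrogate affinity and docking oracles. The
#' affinity surrogate scores a drug against a target as
#' `baseline + effect * Tanimoto(morgan(drug), plantedFeatures[target])`;
#' targets absent from `plantedFeatures` score at baseline. The docking
#' surrogate derives a per-target heteroatom-composition requirement key
#' from `seed` and scores the satisfied fraction on a \[-12, 0\] kcal/mol
#' scale.
#'
#' @slot seed integer seed from which per-target docking keys derive.
#' @slot baseline affinity baseline (pIC50 units).
#' @slot effect affinity effect magnitude multiplying the similarity.
#' @slot plantedFeatures named list, target accession -> logical Morgan
#'   bit vector (the planted high-affinity feature set).
#' @export
setClass("SurrogateSpec",
         representation(seed = "integer", baseline = "numeric",
                        effect = "numeric", plantedFeatures = "list"),
         prototype(seed = 1L, baseline = 2.0, effect = 4.0,
                   plantedFeatures = list()))

setValidity("SurrogateSpec", function(object) {
  if (!is.finite(object@baseline) || !is.finite(object@effect))
    return("baseline/effect must be finite")
  if (length(object@plantedFeatures) &&
      is.null(names(object@plantedFeatures)))
    return("plantedFeatures must be named by target accession")
  TRUE
})

setMethod("show", "SurrogateSpec", function(object) {
  cat("SurrogateSpec: baseline", object@baseline, "effect", object@effect,
      "| planted targets:", length(object@plantedFeatures),
      "| seed", object@seed, "\n")
  invisible(object)
})

#' Build a SurrogateSpec
#'
#' @param seed integer seed.
#' @param baseline,effect affinity model parameters (pIC50 units).
#' @param plantedTargets character vector of target accessions carrying
#'   the planted high-affinity feature set.
#' @param featureMolecule [Molecule-class] whose Morgan fingerprint is
#'   the planted feature set (typically the query ligand).
#' @return a [SurrogateSpec-class].
#' @export
surrogateSpec <- function(seed = 1L, baseline = 2.0, effect = 4.0,
                          plantedTargets = character(0),
                          featureMolecule = NULL) {
  planted <- list()
  if (length(plantedTargets)) {
    stopifnot(is(featureMolecule, "Molecule"))
    fp <- morganFingerprint(featureMolecule)
    planted <- stats::setNames(rep(list(fp), length(plantedTargets)),
                               plantedTargets)
  }
  new("SurrogateSpec", seed = as.integer(seed), baseline = baseline,
      effect = effect, plantedFeatures = planted)
}

#' Surrogate binding-affinity oracle
#'
#' Returns a deterministic pIC50 scoring function with signature
#' `function(drugSmiles, targetId, targetSequence = NULL)`. Planted
#' (drug, target) pairs -- the query ligand and its structural
#' neighbours against targets named in the spec -- score above the 4.0
#' pIC50 cutoff; unrelated drugs and unknown targets fall back toward
#' the baseline. Drug SMILES are canonicalized internally, so notation
#' variants of one structure score identically.
#'
#' @param spec a [SurrogateSpec-class].
#' @return the oracle function.
#' @export
surrogateAffinity <- function(spec) {
  stopifnot(is(spec, "SurrogateSpec"))
  force(spec)
  function(drugSmiles, targetId, targetSequence = NULL) {
    stopifnot(is.character(drugSmiles), length(drugSmiles) == 1L)
    feats <- spec@plantedFeatures[[targetId]]
    if (is.null(feats)) return(spec@baseline)
    can <- .obCanonical(drugSmiles)
    if (is.na(can))
      stop("affinity oracle: unparseable drug SMILES '", drugSmiles, "'")
    fp <- .obFingerprints(can, "ECFP4")[1L, ]
    spec@baseline + spec@effect * .tanimotoBits(fp, feats)
  }
}

# Per-target docking requirement key: counts of N and O atoms the
# surrogate rewards. Derived deterministically from (spec seed, target).
.dockingKey <- function(spec, targetId) {
  h <- sum(utf8ToInt(targetId) * seq_along(utf8ToInt(targetId)))
  s <- (abs(spec@seed) %% 10000L * 1009L + h) %% 2147483647L
  list(nN = 1L + s %% 2L, nO = 3L + (s %/% 7L) %% 2L)
}

#' Surrogate docking oracle
#'
#' Returns a deterministic docking scoring function with signature
#' `function(mol, targetId)` where `mol` is a [Molecule-class] (or a
#' SMILES string). For each target a heteroatom-composition requirement
#' key (a nitrogen count and an oxygen count) is derived from the spec
#' seed; the score is `-12 * (satisfied fraction)` kcal/mol, bounded in
#' \[-12, 0\] with its optimum of -12 kcal/mol attained by any molecule
#' meeting the full key ([surrogateDockingOptimum()]). Structurally
#' identical molecules score identically regardless of input notation.
#'
#' @param spec a [SurrogateSpec-class].
#' @return the oracle function.
#' @export
surrogateDocking <- function(spec) {
  stopifnot(is(spec, "SurrogateSpec"))
  force(spec)
  function(mol, targetId) {
    if (is.character(mol)) mol <- parseSmiles(mol)
    stopifnot(is(mol, "Molecule"))
    key <- .dockingKey(spec, targetId)
    nN <- sum(mol@graph$elem == "N")
    nO <- sum(mol@graph$elem == "O")
    frac <- (min(nN, key$nN) / key$nN + min(nO, key$nO) / key$nO) / 2
    -12 * frac
  }
}

#' @describeIn surrogateDocking the closed-form optimum of the surrogate
#'   docking score for a target: -12 kcal/mol, reached by any molecule
#'   satisfying the target's full requirement key.
#' @param spec a [SurrogateSpec-class].
#' @param targetId target accession.
#' @return list with the optimum `score` and the requirement `key`.
#' @export
surrogateDockingOptimum <- function(spec, targetId) {
  list(score = -12, key = .dockingKey(spec, targetId))
}
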