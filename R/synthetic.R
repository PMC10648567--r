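# Synthetic study-data generator.
#
# Emulates the annotated drug-target-disease corpus the identification
# stage consumes: a drug library containing a planted cluster of
# query-similar molecules (scaffold-preserving edits of the query,
# verified above the 0.4 average-Tanimoto threshold) plus structurally
# unrelated decoys (verified below it), random-sequence protein
# targets, interaction edges wiring the planted neighbours to a set of
# planted high-affinity targets (plus noise), a phenotype table tagging
# a subset of those targets with the disease label, the surrogate
# oracle spec that realises the planted affinity structure, and a
# ground-truth manifest. Every similarity claim is verified at
# generation time, not hoped for.

#' ScenarioConfig: knobs of the synthetic study scenario
#'
#' Defaults are the package's standard study conditions: 100 drugs of
#' which 10 are planted near-neighbours of the query, 50 targets of
#' which 8 carry planted above-cutoff affinity for the query cluster,
#' 3 of those tagged with the disease phenotype; neighbours are 1-2
#' substituent edits away from the query.
#'
#' @slot nDrugs library size.
#' @slot nPlantedSimilar planted near-neighbour count.
#' @slot nTargets target count.
#' @slot nPlantedAffinityTargets targets with planted high affinity.
#' @slot nDiseaseTagged planted affinity targets carrying the disease
#'   phenotype.
#' @slot editDepth maximum substituent edits applied to make each
#'   neighbour (>= 1).
#' @slot phenotype disease phenotype string planted in the table.
#' @slot seed integer seed; the full bundle is a function of it.
#' @export
setClass("ScenarioConfig",
         representation(nDrugs = "integer", nPlantedSimilar = "integer",
                        nTargets = "integer",
                        nPlantedAffinityTargets = "integer",
                        nDiseaseTagged = "integer", editDepth = "integer",
                        phenotype = "character", seed = "integer"),
         prototype(nDrugs = 100L, nPlantedSimilar = 10L, nTargets = 50L,
                   nPlantedAffinityTargets = 8L, nDiseaseTagged = 3L,
                   editDepth = 2L, phenotype = "Alzheimer disease, type 2",
                   seed = 1L))

setValidity("ScenarioConfig", function(object) {
  if (object@nPlantedSimilar > object@nDrugs)
    return("more planted neighbours than drugs")
  if (object@nPlantedAffinityTargets > object@nTargets)
    return("more planted affinity targets than targets")
  if (object@nDiseaseTagged > object@nPlantedAffinityTargets)
    return("more disease-tagged than planted affinity targets")
  if (object@editDepth < 1L) return("editDepth must be >= 1")
  TRUE
})

#' @rdname ScenarioConfig-class
#' @param nDrugs,nPlantedSimilar,nTargets,nPlantedAffinityTargets,nDiseaseTagged,editDepth,phenotype,seed
#'   see slots.
#' @export
scenarioConfig <- function(nDrugs = 100L, nPlantedSimilar = 10L,
                           nTargets = 50L, nPlantedAffinityTargets = 8L,
                           nDiseaseTagged = 3L, editDepth = 2L,
                           phenotype = "Alzheimer disease, type 2",
                           seed = 1L) {
  new("ScenarioConfig", nDrugs = as.integer(nDrugs),
      nPlantedSimilar = as.integer(nPlantedSimilar),
      nTargets = as.integer(nTargets),
      nPlantedAffinityTargets = as.integer(nPlantedAffinityTargets),
      nDiseaseTagged = as.integer(nDiseaseTagged),
      editDepth = as.integer(editDepth), phenotype = phenotype,
      seed = as.integer(seed))
}

# decoy grammar: small heterocyclic cores decorated with substituents,
# deliberately disjoint from the query's characteristic substructures
# (no resorcinol, no long alkyl chain, no cyclohexene)
.decoyCores <- c("c1ccncc1", "c1cnc[nH]c1=O", "c1cncnc1", "c1cc[nH]c1",
                 "c1ccon1", "c1ccsc1", "C1CNCCN1", "C1COCCN1",
                 "O=C1CCCN1", "c1cnn(C)c1", "O=c1cc[nH]c(=O)[nH]1",
                 "C1CSCCN1")
.decoySubs <- c("F", "Cl", "N", "O", "C#N", "C(=O)N", "S(C)(=O)=O",
                "OC", "NC", "C(F)(F)F", "C(=O)OC")

.randomDecoySmiles <- function() {
  core <- sample(.decoyCores, 1L)
  nsub <- sample(0:2, 1L)
  smi <- core
  if (nsub > 0L) {
    for (s in sample(.decoySubs, nsub, replace = TRUE)) {
      # attach by simple SMILES concatenation onto a fresh ring-atom
      # written as a branch on the first atom
      smi <- paste0(smi, ".", s)
    }
    # merge the fragments through a carbon linker instead of keeping
    # disconnected components
    parts <- strsplit(smi, ".", fixed = TRUE)[[1L]]
    smi <- paste0("C(", paste(parts, collapse = ")("), ")")
  }
  smi
}

#' Generate a complete synthetic scenario
#'
#' Builds the drug library, targets, edges, disease tables, surrogate
#' oracle spec and ground-truth manifest described in
#' [ScenarioConfig-class]. Similarity separation is enforced by direct
#' computation: every planted neighbour must exceed average Tanimoto
#' 0.4 against the query (and Morgan Tanimoto 0.5, which keeps its
#' planted pIC50 strictly above the 4.0 cutoff), every decoy must fall
#' below 0.4 (and 0.45 Morgan); candidates violating the margins are
#' regenerated up to a bounded retry budget, after which generation
#' fails rather than emit an unseparated scenario.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param querySmiles query ligand SMILES (default: the CBD fixture).
#' @return list with elements `dataset` ([InteractionDataset-class]),
#'   `disease` ([DiseaseTable-class]), `oracleSpec`
#'   ([SurrogateSpec-class]), `truth` (list: `plantedSimilarIds`,
#'   `expectedCandidateTargets`, `expectedFinalTargets`), `querySmiles`,
#'   and `config`.
#' @export
generateScenario <- function(cfg = scenarioConfig(),
                             querySmiles = cbdSmiles()) {
  stopifnot(is(cfg, "ScenarioConfig"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    oldSeed <- get(".Random.seed", globalenv())
  else oldSeed <- NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(cfg@seed)

  query <- parseSmiles(querySmiles)
  queryCan <- canonicalSmiles(query)
  scaffold <- murckoScaffold(query)

  ## planted neighbours: scaffold-preserving substituent edits
  neighbours <- character(0)
  tries <- 0L
  while (length(neighbours) < cfg@nPlantedSimilar) {
    tries <- tries + 1L
    if (tries > 60L * cfg@nPlantedSimilar)
      stop("could not generate separated near-neighbours; ",
           "scenario configuration looks infeasible")
    m <- query
    for (e in seq_len(sample.int(cfg@editDepth, 1L)))
      m <- mutateMolecule(m, scaffold)
    can <- canonicalSmiles(m)
    if (can == queryCan || can %in% neighbours) next
    sim <- .avgTanimotoBatch(can, queryCan)
    if (sim[, "avg"] > 0.4 && sim[, "morgan"] > 0.5)
      neighbours <- c(neighbours, can)
  }

  ## decoys: unrelated grammar, verified dissimilar
  nDecoys <- cfg@nDrugs - cfg@nPlantedSimilar
  decoys <- character(0)
  tries <- 0L
  while (length(decoys) < nDecoys) {
    tries <- tries + 1L
    if (tries > 80L * max(1L, nDecoys))
      stop("could not generate separated decoys; ",
           "scenario configuration looks infeasible")
    can <- .obCanonical(.randomDecoySmiles())
    if (is.na(can) || can %in% decoys || can == queryCan) next
    sim <- .avgTanimotoBatch(can, queryCan)
    if (sim[, "avg"] < 0.4 && sim[, "morgan"] < 0.45)
      decoys <- c(decoys, can)
  }

  drugs <- data.frame(
    drug_id = sprintf("D%04d", seq_len(cfg@nDrugs)),
    smiles = c(neighbours, decoys),
    canonical = c(neighbours, decoys))
  plantedIds <- drugs$drug_id[seq_len(cfg@nPlantedSimilar)]

  ## targets: random 50-mer amino-acid sequences
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  targets <- data.frame(
    accession = sprintf("T%04d", seq_len(cfg@nTargets)),
    sequence = vapply(seq_len(cfg@nTargets), function(i)
      paste(sample(aa, 50L, replace = TRUE), collapse = ""), ""))
  plantedTargets <- targets$accession[seq_len(cfg@nPlantedAffinityTargets)]

  ## edges: every planted target is reached by >= 1 neighbour; extra
  ## neighbour edges and decoy noise edges on top
  edges <- data.frame(drug_id = character(0), accession = character(0))
  if (length(plantedIds)) {
    for (i in seq_along(plantedTargets)) {
      supp <- unique(c(plantedIds[1L + (i - 1L) %% length(plantedIds)],
                       sample(plantedIds, sample(1:3, 1L))))
      edges <- rbind(edges, data.frame(drug_id = supp,
                                       accession = plantedTargets[i]))
    }
  }
  nNoise <- 2L * cfg@nDrugs
  noise <- data.frame(
    drug_id = sample(drugs$drug_id, nNoise, replace = TRUE),
    accession = sample(targets$accession, nNoise, replace = TRUE))
  edges <- unique(rbind(edges, noise))
  rownames(edges) <- NULL

  ## disease tables: the first nDiseaseTagged planted targets carry the
  ## disease phenotype; a couple of non-affinity targets carry it too
  ## (they must be rejected by the affinity filter), and the remainder
  ## get unrelated phenotypes
  xref <- data.frame(accession = targets$accession,
                     gene_symbol = sprintf("GENE%04d",
                                           seq_len(cfg@nTargets)))
  diseaseTagged <- plantedTargets[seq_len(cfg@nDiseaseTagged)]
  otherPheno <- c("Diabetes mellitus, type 2", "Hypertension, essential",
                  "Asthma, susceptibility to", "Obesity, severe")
  assoc <- data.frame(gene_symbol = character(0), phenotype = character(0))
  gs <- function(acc) xref$gene_symbol[match(acc, xref$accession)]
  if (length(diseaseTagged))
    assoc <- rbind(assoc, data.frame(gene_symbol = gs(diseaseTagged),
                                     phenotype = cfg@phenotype))
  nonPlanted <- setdiff(targets$accession, plantedTargets)
  lure <- head(nonPlanted, 2L)
  if (length(lure))
    assoc <- rbind(assoc, data.frame(gene_symbol = gs(lure),
                                     phenotype = cfg@phenotype))
  rest <- setdiff(targets$accession, c(diseaseTagged, lure))
  if (length(rest))
    assoc <- rbind(assoc, data.frame(
      gene_symbol = gs(rest),
      phenotype = sample(otherPheno, length(rest), replace = TRUE)))
  assoc <- assoc[order(assoc$gene_symbol), , drop = FALSE]
  rownames(assoc) <- NULL

  spec <- surrogateSpec(seed = cfg@seed, baseline = 2.0, effect = 4.0,
                        plantedTargets = plantedTargets,
                        featureMolecule = query)

  ds <- interactionDataset(drugs, targets, edges)
  dt <- diseaseTable(assoc, xref)

  truth <- list(
    plantedSimilarIds = plantedIds,
    expectedCandidateTargets =
      sort(unique(edges$accession[edges$drug_id %in% plantedIds])),
    expectedFinalTargets = sort(intersect(
      diseaseTagged,
      unique(edges$accession[edges$drug_id %in% plantedIds]))))

  list(dataset = ds, disease = dt, oracleSpec = spec, truth = truth,
       querySmiles = querySmiles, config = cfg)
}

#' Write a scenario bundle to disk
#'
#' Emits `drugs.smi`, `targets.fasta`, `interactions.tsv`,
#' `disease.tsv`, `xref.tsv`, `oracle_spec.yaml` and `truth.tsv` in the
#' formats the identification stage consumes.
#' @param bundle list from [generateScenario()].
#' @param dir output directory (created if needed).
#' @return named character vector of the seven file paths.
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  ds <- bundle$dataset; dt <- bundle$disease
  paths <- c(
    drugs = file.path(dir, "drugs.smi"),
    targets = file.path(dir, "targets.fasta"),
    interactions = file.path(dir, "interactions.tsv"),
    disease = file.path(dir, "disease.tsv"),
    xref = file.path(dir, "xref.tsv"),
    oracle = file.path(dir, "oracle_spec.yaml"),
    truth = file.path(dir, "truth.tsv"))
  writeDrugLibrary(ds@drugs, paths[["drugs"]])
  writeTargetSequences(ds@targets, paths[["targets"]])
  .writeTsv(ds@edges, paths[["interactions"]])
  .writeTsv(dt@associations, paths[["disease"]])
  .writeTsv(dt@xref, paths[["xref"]])
  writeOracleSpec(bundle$oracleSpec, bundle$querySmiles, paths[["oracle"]])
  truth <- bundle$truth
  .writeTsv(data.frame(
    kind = c(rep("planted_similar", length(truth$plantedSimilarIds)),
             rep("expected_candidate", length(truth$expectedCandidateTargets)),
             rep("expected_final", length(truth$expectedFinalTargets))),
    id = c(truth$plantedSimilarIds, truth$expectedCandidateTargets,
           truth$expectedFinalTargets)), paths[["truth"]])
  paths
}

#' Read a scenario bundle back from disk
#'
#' Inverse of [writeBundle()]; the ground-truth manifest is optional.
#' @param dir bundle directory.
#' @return list with `dataset`, `disease`, `oracleSpec`, `truth` (NULL
#'   when absent) and `querySmiles`.
#' @export
readBundle <- function(dir) {
  ds <- readInteractionDataset(dir)
  dt <- readDiseaseTable(dir)
  spec <- readOracleSpec(file.path(dir, "oracle_spec.yaml"))
  y <- yaml::read_yaml(file.path(dir, "oracle_spec.yaml"))
  truthPath <- file.path(dir, "truth.tsv")
  truth <- NULL
  if (file.exists(truthPath)) {
    tt <- .readTsvChecked(truthPath, c("kind", "id"))
    truth <- list(
      plantedSimilarIds = tt$id[tt$kind == "planted_similar"],
      expectedCandidateTargets = tt$id[tt$kind == "expected_candidate"],
      expectedFinalTargets = tt$id[tt$kind == "expected_final"])
  }
  list(dataset = ds, disease = dt, oracleSpec = spec, truth = truth,
       querySmiles = y$feature_smiles)
}
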