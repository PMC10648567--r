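# Stage 1: similarity screen, affinity filter, disease intersection.

# tiny hand-built dataset used by several blocks
tinyDataset <- function() {
  drugs <- data.frame(
    drug_id = c("Dcbd", "Doliv", "Dpyr"),
    smiles = c(cbdSmiles(), "CCCCCc1cc(O)cc(O)c1", "c1ccncc1"))
  targets <- data.frame(accession = c("T1", "T2"),
                        sequence = c(strrep("A", 50), strrep("M", 50)))
  edges <- data.frame(drug_id = c("Doliv", "Doliv", "Dpyr"),
                      accession = c("T1", "T2", "T2"))
  interactionDataset(drugs, targets, edges)
}

test_that("similarity screen applies a strict threshold and self-exclusion", {
  ds <- tinyDataset()
  cbd <- fxCbd()
  sim <- findSimilarDrugs(cbd, ds, 0.4)
  expect_identical(sim$drug_id, "Doliv")     # query excluded, decoy below
  expect_true(all(sim$similarity > 0.4))
  # threshold 1.0: nothing strictly exceeds it
  expect_identical(nrow(findSimilarDrugs(cbd, ds, 1.0)), 0L)
  # boundary strictness: a drug at exactly the threshold is excluded
  sOliv <- avgTanimoto(cbd, parseSmiles("CCCCCc1cc(O)cc(O)c1"))
  expect_false("Doliv" %in% findSimilarDrugs(cbd, ds, sOliv)$drug_id)
  expect_true("Doliv" %in% findSimilarDrugs(cbd, ds, sOliv - 1e-9)$drug_id)
  # a library containing only the query yields nothing
  only <- interactionDataset(
    data.frame(drug_id = "Dq", smiles = cbdSmiles()),
    data.frame(accession = "T1", sequence = strrep("A", 50)),
    data.frame(drug_id = character(0), accession = character(0)))
  expect_identical(nrow(findSimilarDrugs(cbd, only, 0.4)), 0L)
})

test_that("candidate targets are the union over similar drugs' edges", {
  ds <- tinyDataset()
  expect_identical(collectCandidateTargets("Doliv", ds), c("T1", "T2"))
  expect_identical(collectCandidateTargets(c("Doliv", "Dpyr"), ds),
                   c("T1", "T2"))
  expect_identical(collectCandidateTargets(character(0), ds), character(0))
  # drug with no edges contributes nothing
  expect_identical(collectCandidateTargets("Dcbd", ds), character(0))
})

test_that("affinity filter is strict at the cutoff and records evidence", {
  ds <- tinyDataset()
  cbd <- fxCbd()
  sim <- data.frame(drug_id = "Doliv", similarity = 0.5)
  mkOracle <- function(queryScore, suppScore) {
    qcan <- canonicalSmiles(cbd)
    function(smiles, targetId, seq = NULL)
      if (identical(smiles, qcan)) queryScore else suppScore
  }
  # both strictly above: retained, with evidence satisfying the filter
  out <- filterByAffinity(cbd, c("T1", "T2"), sim, ds,
                          mkOracle(5.0, 4.5), cutoff = 4.0)
  expect_setequal(out$accession, c("T1", "T2"))  # Doliv supports both
  expect_true(all(out$pic50_query > 4.0))
  expect_true(all(out$best_support_pic50 > 4.0))
  # query below cutoff: excluded despite a strong supporter
  expect_identical(
    nrow(filterByAffinity(cbd, "T1", sim, ds, mkOracle(3.9, 6.0))), 0L)
  # exactly 4.0 is excluded ("higher than", strict)
  expect_identical(
    nrow(filterByAffinity(cbd, "T1", sim, ds, mkOracle(4.0, 6.0))), 0L)
  expect_identical(
    nrow(filterByAffinity(cbd, "T1", sim, ds, mkOracle(5.0, 4.0))), 0L)
  # oracle failure names the pair
  bad <- function(smiles, targetId, seq = NULL) stop("boom")
  expect_error(filterByAffinity(cbd, "T1", sim, ds, bad), "T1")
})

test_that("all-supporters mode is stricter than any-supporter mode", {
  ds <- tinyDataset()
  cbd <- fxCbd()
  sim <- data.frame(drug_id = c("Doliv", "Dpyr"), similarity = c(0.5, 0.45))
  pyrCan <- targan:::.obCanonical("c1ccncc1")
  oracle <- function(smiles, targetId, seq = NULL) {
    # pyridine supporter scores low, everything else high
    if (identical(smiles, pyrCan)) 3 else 6
  }
  anyMode <- filterByAffinity(cbd, "T2", sim, ds, oracle, supportMode = "any")
  allMode <- filterByAffinity(cbd, "T2", sim, ds, oracle, supportMode = "all")
  expect_identical(anyMode$accession, "T2")
  expect_identical(nrow(allMode), 0L)
})

test_that("disease mapping is case-insensitive substring with xref gating", {
  dt <- diseaseTable(
    data.frame(gene_symbol = c("G1", "G2", "G3"),
               phenotype = c("Alzheimer disease 2", "ALZHEIMER, late onset",
                             "Diabetes mellitus")),
    data.frame(accession = c("T1", "T2"), gene_symbol = c("G1", "G3")))
  cands <- data.frame(accession = c("T1", "T2", "T9"),
                      pic50_query = c(5, 5, 5),
                      best_support_drug = "D", best_support_similarity = 0.5,
                      best_support_pic50 = 5, n_support = 1L)
  out <- mapToDisease(cands, dt, "Alzheimer")
  expect_identical(out$accession, "T1")      # T2 maps to Diabetes, T9 unmapped
  expect_identical(out$gene_symbol, "G1")
  out2 <- mapToDisease(cands, dt, "alzheimer")
  expect_identical(out2$accession, "T1")
  expect_identical(nrow(mapToDisease(cands, dt, "Parkinson")), 0L)
})

test_that("raising thresholds never enlarges the identified set", {
  b <- fxScenario(1L)
  oracle <- surrogateAffinity(b$oracleSpec)
  run <- function(st, ac) runTargetIdentification(
    b$querySmiles, b$dataset, b$disease, oracle,
    pipelineConfig(similarityThreshold = st, affinityCutoff = ac))
  base <- run(0.4, 4.0)$accession
  expect_true(all(run(0.5, 4.0)$accession %in% base))
  expect_true(all(run(0.4, 5.0)$accession %in% base))
  expect_true(all(run(0.6, 5.5)$accession %in% base))
})

test_that("full pipeline recovers exactly the planted targets and reports deterministically", {
  b <- fxScenario(1L)
  oracle <- surrogateAffinity(b$oracleSpec)
  rep1 <- runTargetIdentification(b$querySmiles, b$dataset, b$disease,
                                  oracle, pipelineConfig())
  expect_setequal(rep1$accession, b$truth$expectedFinalTargets)
  # no phenotype matches: empty table, no error
  none <- runTargetIdentification(b$querySmiles, b$dataset, b$disease,
                                  oracle,
                                  pipelineConfig(phenotypeQuery = "Martian"))
  expect_identical(nrow(none), 0L)
  # byte-identical reports across repeated runs
  f1 <- tempfile(); f2 <- tempfile()
  writeTargetReport(rep1, f1)
  rep2 <- runTargetIdentification(b$querySmiles, b$dataset, b$disease,
                                  oracle, pipelineConfig())
  writeTargetReport(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed input tables fail with file and line diagnostics", {
  d <- tempfile(); dir.create(d)
  writeLines(c("drug_id\taccession", "D1\tT1", "brokenline"),
             file.path(d, "interactions.tsv"))
  expect_error(
    targan:::.readTsvChecked(file.path(d, "interactions.tsv"),
                             c("drug_id", "accession")),
    ":3:")
  writeLines("onlysmiles", file.path(d, "drugs.smi"))
  expect_error(readDrugLibrary(file.path(d, "drugs.smi")), ":1:")
  expect_error(readInteractionDataset(tempfile()), "not found")
})
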