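# Synthetic-data generator: separation guarantees, determinism,
# round-tripping.

test_that("similarity separation holds by verification over the whole library", {
  b <- fxScenario(1L)
  d <- drugTable(b$dataset)
  query <- parseSmiles(b$querySmiles)
  planted <- b$truth$plantedSimilarIds
  sims <- targan:::.avgTanimotoBatch(d$canonical,
                                     canonicalSmiles(query))[, "avg"]
  expect_true(all(sims[d$drug_id %in% planted] > 0.4))
  expect_true(all(sims[!d$drug_id %in% planted] < 0.4))
})

test_that("the planted affinity structure clears the cutoff on both sides", {
  b <- fxScenario(1L)
  aff <- surrogateAffinity(b$oracleSpec)
  d <- drugTable(b$dataset)
  planted <- b$truth$plantedSimilarIds
  plantedTargets <- names(b$oracleSpec@plantedFeatures)
  for (acc in plantedTargets) {
    expect_gt(aff(b$querySmiles, acc), 4.0)
    for (id in planted[1:3])
      expect_gt(aff(d$canonical[d$drug_id == id], acc), 4.0)
    # decoys stay at or below the cutoff even against planted targets
    decoys <- head(d$canonical[!d$drug_id %in% planted], 3L)
    for (smi in decoys) expect_lte(aff(smi, acc), 4.0)
  }
})

test_that("identical seeds give byte-identical bundles", {
  d1 <- tempfile(); d2 <- tempfile()
  writeBundle(generateScenario(scenarioConfig(seed = 4L)), d1)
  writeBundle(generateScenario(scenarioConfig(seed = 4L)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("a written bundle reads back equal and reproduces the pipeline", {
  b <- fxScenario(1L)
  dir <- tempfile()
  paths <- writeBundle(b, dir)
  expect_length(paths, 7L)
  expect_true(all(file.exists(paths)))
  b2 <- readBundle(dir)
  expect_identical(drugTable(b2$dataset)$canonical,
                   drugTable(b$dataset)$canonical)
  expect_identical(targetTable(b2$dataset), targetTable(b$dataset))
  expect_identical(edgeTable(b2$dataset), edgeTable(b$dataset))
  expect_identical(b2$truth$expectedFinalTargets,
                   b$truth$expectedFinalTargets)
  rep1 <- runTargetIdentification(b$querySmiles, b$dataset, b$disease,
                                  surrogateAffinity(b$oracleSpec),
                                  pipelineConfig())
  rep2 <- runTargetIdentification(b2$querySmiles, b2$dataset, b2$disease,
                                  surrogateAffinity(b2$oracleSpec),
                                  pipelineConfig())
  expect_identical(rep1, rep2)
})

test_that("zero planted neighbours yields an empty identification", {
  b <- generateScenario(scenarioConfig(nDrugs = 20L, nPlantedSimilar = 0L,
                                       nTargets = 10L,
                                       nPlantedAffinityTargets = 2L,
                                       nDiseaseTagged = 1L, seed = 2L))
  expect_identical(b$truth$expectedFinalTargets, character(0))
  rep <- runTargetIdentification(b$querySmiles, b$dataset, b$disease,
                                 surrogateAffinity(b$oracleSpec),
                                 pipelineConfig())
  expect_identical(nrow(rep), 0L)
})

test_that("an empty scenario writes valid headered files", {
  b <- generateScenario(scenarioConfig(nDrugs = 0L, nPlantedSimilar = 0L,
                                       nTargets = 0L,
                                       nPlantedAffinityTargets = 0L,
                                       nDiseaseTagged = 0L, seed = 6L))
  dir <- tempfile()
  paths <- writeBundle(b, dir)
  expect_true(all(file.exists(paths)))
  b2 <- readBundle(dir)
  expect_identical(nrow(drugTable(b2$dataset)), 0L)
  expect_identical(nrow(edgeTable(b2$dataset)), 0L)
})
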