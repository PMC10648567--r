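# Molecule parsing, canonicalization and scaffold extraction.

test_that("canonicalization collapses notation variants and is idempotent", {
  a <- parseSmiles("c1ccccc1")
  b <- parseSmiles("C1=CC=CC=C1")
  expect_identical(canonicalSmiles(a), canonicalSmiles(b))
  expect_true(sameStructure(a, b))
  # re-parsing the canonical form reproduces it
  expect_identical(canonicalSmiles(parseSmiles(canonicalSmiles(a))),
                   canonicalSmiles(a))
  cbd1 <- fxCbd()
  cbd2 <- parseSmiles(canonicalSmiles(cbd1))
  expect_identical(canonicalSmiles(cbd1), canonicalSmiles(cbd2))
})

test_that("parse failure raises and names the offending input", {
  expect_error(parseSmiles("C1CC"), "C1CC")
  expect_error(parseSmiles(""), "non-empty")
  expect_error(parseSmiles("not a smiles"), "not a smiles")
  bad <- parseSmilesBatch(c("CCO", "C1CC", "c1ccccc1"))
  expect_null(bad[[2L]])
  expect_s4_class(bad[[1L]], "Molecule")
})

test_that("ring statistics are correct on known structures", {
  expect_equal(numRings(parseSmiles("CCO")), 0L)
  expect_equal(largestRingSize(parseSmiles("CCO")), 0L)
  expect_equal(numRings(parseSmiles("c1ccccc1")), 1L)
  expect_equal(largestRingSize(parseSmiles("C1CCCCCCC1")), 8L)
  expect_equal(numRings(parseSmiles("c1ccc2ccccc2c1")), 2L)
  expect_equal(largestRingSize(parseSmiles("c1ccc2ccccc2c1")), 6L)
  expect_equal(numAtoms(fxCbd()), 23L)
  expect_equal(numRings(fxCbd()), 2L)
})

test_that("Murcko scaffold matches the reference-toolkit decomposition", {
  # expectations computed with an independent cheminformatics toolkit
  # before the build and re-expressed in this package's canonical form
  refScaffold <- function(smiles) canonicalSmiles(parseSmiles(smiles))
  expect_identical(canonicalSmiles(murckoScaffold(parseSmiles("Cc1ccccc1"))),
                   refScaffold("c1ccccc1"))
  expect_identical(canonicalSmiles(murckoScaffold(fxCbd())),
                   refScaffold("C1=CC(c2ccccc2)CCC1"))
  # exocyclic double bonds to the framework are retained
  expect_identical(
    canonicalSmiles(murckoScaffold(parseSmiles("O=C1CCCCC1"))),
    refScaffold("O=C1CCCCC1"))
  expect_identical(
    canonicalSmiles(murckoScaffold(parseSmiles("O=C(c1ccccc1)c1ccccc1"))),
    refScaffold("O=C(c1ccccc1)c1ccccc1"))
  # side chains vanish entirely
  expect_identical(
    canonicalSmiles(murckoScaffold(parseSmiles("CC(=O)Oc1ccccc1C(=O)O"))),
    refScaffold("c1ccccc1"))
})

test_that("acyclic molecules yield the empty-scaffold sentinel", {
  s <- murckoScaffold(parseSmiles("CCO"))
  expect_true(isEmptyMolecule(s))
  expect_identical(canonicalSmiles(s), "")
  expect_true(isEmptyMolecule(murckoScaffold(parseSmiles("C"))))
})

test_that("murckoScaffold is idempotent over generated molecules", {
  for (m in randomTestMolecules(12L, seed = 9L)) {
    s <- murckoScaffold(m)
    if (isEmptyMolecule(s)) next
    expect_true(sameStructure(murckoScaffold(s), s), label = canonicalSmiles(m))
  }
})
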