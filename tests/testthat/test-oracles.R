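# Surrogate oracles: determinism, planted structure, bounds.

test_that("planted pairs score above 4 and decoys at baseline", {
  spec <- surrogateSpec(seed = 3L, plantedTargets = c("T1", "T2"),
                        featureMolecule = fxCbd())
  aff <- surrogateAffinity(spec)
  expect_gt(aff(cbdSmiles(), "T1"), 4)
  # a dissimilar decoy against a planted target stays at or below cutoff
  expect_lte(aff("c1ccncc1", "T1"), 4)
  # unknown target: baseline only, no error
  expect_identical(aff(cbdSmiles(), "T999"), 2.0)
})

test_that("affinity oracle is deterministic and notation-invariant", {
  spec <- surrogateSpec(seed = 3L, plantedTargets = "T1",
                        featureMolecule = fxCbd())
  aff <- surrogateAffinity(spec)
  expect_identical(aff(cbdSmiles(), "T1"), aff(cbdSmiles(), "T1"))
  expect_identical(aff("c1ccccc1", "T1"), aff("C1=CC=CC=C1", "T1"))
  expect_error(aff("C1CC", "T1"), "unparseable")
})

test_that("docking oracle is bounded, deterministic and structure-keyed", {
  spec <- surrogateSpec(seed = 5L)
  dock <- surrogateDocking(spec)
  mols <- randomTestMolecules(6L, seed = 11L)
  for (m in mols) {
    s <- dock(m, "T0001")
    expect_true(is.finite(s))
    expect_gte(s, -12); expect_lte(s, 0)
  }
  expect_identical(dock(parseSmiles("c1ccccc1"), "T0001"),
                   dock(parseSmiles("C1=CC=CC=C1"), "T0001"))
})

test_that("docking optimum is attained exactly at the requirement key", {
  spec <- surrogateSpec(seed = 5L)
  dock <- surrogateDocking(spec)
  opt <- surrogateDockingOptimum(spec, "T0001")
  expect_identical(opt$score, -12)
  # 2 N and 4 O meets every drawable requirement key
  rich <- parseSmiles("NC(N)COC(O)C(O)CO")
  expect_identical(dock(rich, "T0001"), -12)
  # no heteroatoms satisfies nothing; partial satisfaction lies between
  expect_identical(dock(parseSmiles("C1CCCCC1"), "T0001"), 0)
  partial <- dock(parseSmiles("OCCN"), "T0001")
  expect_gt(partial, -12); expect_lt(partial, 0)
})

test_that("oracle spec round-trips through its YAML serialization", {
  spec <- surrogateSpec(seed = 9L, plantedTargets = c("T1", "T7"),
                        featureMolecule = fxCbd())
  path <- tempfile(fileext = ".yaml")
  writeOracleSpec(spec, cbdSmiles(), path)
  spec2 <- readOracleSpec(path)
  expect_identical(spec2@baseline, spec@baseline)
  expect_identical(names(spec2@plantedFeatures), names(spec@plantedFeatures))
  aff1 <- surrogateAffinity(spec); aff2 <- surrogateAffinity(spec2)
  expect_identical(aff1(cbdSmiles(), "T1"), aff2(cbdSmiles(), "T1"))
})
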