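# Drug-likeness properties: plogP arithmetic, ring penalty, QED,
# synthetic accessibility, and the combined profile.

test_that("plogp reproduces the published property-table arithmetic", {
  expect_equal(round(plogp(4.44, 3.58, 0), 2), 0.86)
  expect_equal(round(plogp(2.94, 3.80, 0), 2), -0.86)
  expect_identical(plogp(0, 0, 0), 0)
  expect_error(plogp(1, 1, -1), "ringPenalty")
})

test_that("ring penalty follows max(0, largest ring - 6)", {
  expect_equal(ringPenalty(parseSmiles("c1ccccc1")), 0L)
  expect_equal(ringPenalty(parseSmiles("C1CCCCCCC1")), 2L)
  expect_equal(ringPenalty(parseSmiles("CCO")), 0L)
  expect_equal(ringPenalty(parseSmiles("C1CCCCCC1")), 1L)
})

test_that("profile identity plogp == logp - sascore - ring_penalty holds on generated molecules", {
  mols <- randomTestMolecules(100L, seed = 17L)
  tab <- targan:::.profileTable(mols)
  expect_true(all(abs(tab$plogp - (tab$logp - tab$sascore - tab$ring_penalty))
                  < 1e-9))
  expect_true(all(tab$qed >= 0 & tab$qed <= 1))
  expect_true(all(tab$sascore >= 1 & tab$sascore <= 10))
  expect_true(all(tab$ring_penalty >= 0L))
})

test_that("QED agrees with the reference implementation on fixtures", {
  # reference values computed before the build: CBD 0.5108, benzene
  # 0.4426, aspirin 0.5623 (full-precision toolkit values); our property
  # inputs come from a different toolkit, hence a small tolerance
  expect_lt(abs(qedScore(fxCbd()) - 0.5108), 0.05)
  expect_lt(abs(qedScore(parseSmiles("c1ccccc1")) - 0.4426), 0.05)
  expect_lt(abs(qedScore(parseSmiles("CC(=O)Oc1ccccc1C(=O)O")) - 0.5623),
            0.05)
})

test_that("synthetic accessibility is in range and orders simple before complex", {
  saBenzene <- saScore(parseSmiles("c1ccccc1"))
  saCbd <- saScore(fxCbd())
  saWeird <- saScore(parseSmiles("FC(F)(F)C1(SS1)C(Cl)(Cl)Cl"))
  for (s in c(saBenzene, saCbd, saWeird)) {
    expect_gte(s, 1); expect_lte(s, 10)
  }
  expect_lt(saBenzene, saCbd)
  expect_lt(saCbd, saWeird)
})

test_that("drugLikeness returns a consistent, deterministic profile", {
  p1 <- drugLikeness(fxCbd())
  p2 <- drugLikeness(parseSmiles(cbdSmiles()))
  expect_s4_class(p1, "PropertyProfile")
  expect_equal(p1@qed, p2@qed)
  expect_equal(p1@plogp, p1@logp - p1@sascore - p1@ringPenalty,
               tolerance = 1e-12)
  # CBD: logP above 5 (reference toolkit: 5.85) but clean filters
  expect_gt(p1@logp, 5)
  expect_lt(abs(p1@logp - 5.85), 0.1)
  expect_true(p1@painsPass && p1@brenkPass && p1@nihPass && p1@zincPass)
})
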