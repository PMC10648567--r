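# Structural-alert catalogs and the filter engine.

test_that("catalogs load with the four families and a version", {
  cats <- loadAlertCatalogs()
  expect_named(cats, c("pains", "brenk", "nih", "zinc"))
  expect_true(all(vapply(cats, nrow, integer(1)) >= 10L))
  expect_match(attr(cats, "version"), "targan")
})

test_that("control molecules get the verdicts confirmed with the reference matcher", {
  # catechol is a canonical interference motif (confirmed against the
  # full public catalogs with an independent matcher before the build);
  # propane and the CBD fixture are clean under the shipped subsets
  fr <- runFilters(parseSmiles("Oc1ccccc1O"))
  expect_false(overallPass(fr))
  expect_true("catechol" %in% fr@matches$pains)
  expect_true(overallPass(runFilters(parseSmiles("CCC"))))
  expect_true(overallPass(runFilters(fxCbd())))
  # reactive motifs land in their catalog
  expect_false(filterVerdicts(runFilters(
    parseSmiles("O=[N+]([O-])c1ccccc1")))[["brenk"]])
  expect_false(filterVerdicts(runFilters(parseSmiles("O=C1CCN1")))[["nih"]])
  expect_false(filterVerdicts(runFilters(
    parseSmiles("C[Si](C)(C)C")))[["zinc"]])
})

test_that("overall verdict is the conjunction of per-catalog verdicts", {
  for (m in randomTestMolecules(8L, seed = 23L)) {
    fr <- runFilters(m)
    expect_identical(overallPass(fr), all(filterVerdicts(fr)),
                     label = canonicalSmiles(m))
    expect_identical(overallPass(fr), !any(lengths(fr@matches) > 0L))
  }
})

test_that("batched matching agrees with molecule-by-molecule SMARTS search", {
  mols <- randomTestMolecules(50L, seed = 31L)
  cats <- loadAlertCatalogs()
  tab <- targan:::.profileTable(mols)
  for (i in seq_along(mols)) {
    can <- canonicalSmiles(mols[[i]])
    refs <- targan:::.obMolRefs(can)
    for (catg in names(cats)) {
      hit <- FALSE
      for (j in seq_len(nrow(cats[[catg]]))) {
        if (targan:::.obSmartsCount(refs, cats[[catg]]$smarts[j]) > 0L) {
          hit <- TRUE
          break
        }
      }
      expect_identical(tab[[paste0(catg, "_pass")]][i], !hit,
                       label = paste(can, catg))
    }
  }
})

test_that("a missing catalog directory is a configuration error", {
  expect_error(loadAlertCatalogs(tempfile()), "missing")
})
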