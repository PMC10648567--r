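# Shared fixtures, memoised for the whole test run.

.fx <- new.env(parent = emptyenv())

fxCbd <- function() {
  if (is.null(.fx$cbd)) .fx$cbd <- parseSmiles(cbdSmiles())
  .fx$cbd
}

fxScaffold <- function() {
  if (is.null(.fx$scaffold)) .fx$scaffold <- murckoScaffold(fxCbd())
  .fx$scaffold
}

fxScenario <- function(seed = 1L) {
  key <- paste0("scenario", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generateScenario(scenarioConfig(seed = seed))
  .fx[[key]]
}

# The package's standard GA convergence scenario (documented in the
# methods vignette): population 50, 20 generations, surrogate docking
# against target T0001, seeded.
fxGaRun <- function() {
  if (is.null(.fx$gaRun)) {
    spec <- surrogateSpec(seed = 1L)
    .fx$gaSpec <- spec
    .fx$gaRun <- evolve(fxCbd(), "T0001",
                        gaConfig(populationSize = 50L, generations = 20L,
                                 seed = 7L),
                        surrogateDocking(spec))
  }
  .fx$gaRun
}

fxGaSpec <- function() { fxGaRun(); .fx$gaSpec }

# Mixed bag of valid molecules from the synthetic grammars: scaffold-
# preserving mutants of the query plus heterocyclic decoys.
randomTestMolecules <- function(n, seed = 42L) {
  withr::with_seed(seed, {
    out <- list()
    scaffold <- fxScaffold()
    m <- fxCbd()
    while (length(out) < n) {
      if (length(out) %% 2L == 0L) {
        m <- mutateMolecule(fxCbd(), scaffold)
        out[[length(out) + 1L]] <- m
      } else {
        can <- targan:::.obCanonical(targan:::.randomDecoySmiles())
        if (!is.na(can)) out[[length(out) + 1L]] <- parseSmiles(can)
      }
    }
    out
  })
}
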