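# targan

Ligand-based target fishing and scaffold-constrained analog
optimization for a query ligand, with cannabidiol (CBD) as the shipped
query fixture.

Given a drug–target interaction corpus and a disease–gene phenotype
table, the package answers two questions a discovery scientist asks of
a repurposing candidate:

1. **Which disease-associated proteins might this ligand bind?**
   Drugs similar to the query (average of Morgan- and MACCS-fingerprint
   Tanimoto similarities, `s̄ > 0.4`) are pulled from the library; their
   annotated targets are scored with a binding-affinity model, and a
   target is kept when both the query and a supporting neighbour score
   `pIC50 > 4.0`; survivors are intersected with the disease phenotype
   table (e.g. "Alzheimer").
2. **Can the ligand be improved for each target?** A genetic algorithm
   evolves analogs that preserve the query's Murcko scaffold while
   minimizing a docking score, subject to `QED ≥ 0.5`, `SAScore ≤ 6.0`,
   `logP ≤ 5.0` and four structural-alert catalogs (PAINS, Brenk, NIH,
   ZINC), optimizing the penalized logP

   `plogP = logP − SAScore − RingPenalty`,  `RingPenalty = max(0, largest ring − 6)`

   as a tie-breaking objective among feasible analogs.

Affinity prediction and docking are pluggable oracle contracts;
deterministic surrogates (plus a synthetic-data generator with planted
ground truth) make the full workflow runnable and testable offline.

## Worked example

```r
library(targan)

# --- stage 0: a synthetic study corpus with planted ground truth ----
bundle <- generateScenario(scenarioConfig(seed = 5))
bundle$truth$expectedFinalTargets
#> [1] "T0001" "T0002" "T0003"

# --- stage 1: identify disease-linked targets of CBD ----------------
report <- runTargetIdentification(
  bundle$querySmiles, bundle$dataset, bundle$disease,
  surrogateAffinity(bundle$oracleSpec), pipelineConfig())
report[, c("accession", "gene_symbol", "pic50_query", "phenotype")]
#>   accession gene_symbol pic50_query                 phenotype
#> 1     T0001    GENE0001           6 Alzheimer disease, type 2
#> 2     T0002    GENE0002           6 Alzheimer disease, type 2
#> 3     T0003    GENE0003           6 Alzheimer disease, type 2
```

The three reported accessions are exactly the planted disease-tagged,
affinity-positive targets: the query scores pIC50 6.0 against each
(above the 4.0 cutoff), a similar drug supports each, and their genes
carry the "Alzheimer" phenotype.

```r
# --- stage 2: evolve CBD analogs for one target ---------------------
hof <- evolve(bundle$querySmiles, "T0001",
              gaConfig(populationSize = 30, generations = 10, seed = 5),
              surrogateDocking(bundle$oracleSpec))
writeLines(renderAnalogReport(hof)[1:3])
#> No.  QED  SAScore  plogP  logP  Filters(PAINS, BRENK, NIH, ZINC)  DockingScore  SMILES
#> No.1 0.51 4.28     0.14   4.42  Pass                              -12.00        COCC(Oc1cc(O)c(c(c1)O)C1C=C(C)CC(C1C(C)C)N)Cl
#> No.2 0.51 4.32     0.02   4.34  Pass                              -12.00        COCC(Oc1cc(O)c(c(c1)O)C1C=C(C)CC(C1C(=C)C)N)Cl
```

Every analog keeps CBD's Murcko scaffold (the resorcinol ring fused to
the cyclohexene, visible inside each SMILES), satisfies the whole
drug-likeness box, passes all four alert catalogs, and reaches the
surrogate docking optimum of −12 kcal/mol — whereas CBD itself starts
infeasible (logP ≈ 5.85 > 5) and scores 0 against this target's
requirement key:

```r
p <- drugLikeness(parseSmiles(cbdSmiles()))
p
#> PropertyProfile: QED 0.51 | SAScore 2.43 | logP 5.85 | ring penalty 0 | plogP 3.41
#>   filters: PAINS=Pass BRENK=Pass NIH=Pass ZINC=Pass
```

A command-line front end wraps the same functions
(`inst/scripts/targan.R`, subcommands `simulate`, `identify`,
`optimize`, `props`); every command writes a YAML run manifest with
input checksums and the seed.

## Scope notes

- The affinity and docking surrogates are deterministic stand-ins with
  planted structure; they are **not** emulations of any external
  predictor's numbers, and corpus-scale results that depend on licensed
  databases are out of scope by design.
- The SA-score fragment table and the four alert catalogs are reduced,
  clearly-labelled stand-ins for reference data that cannot be
  redistributed here; see `vignettes/targan-methods.Rmd` for exactly
  what that implies.
- No stereochemistry or 3D structure anywhere.
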