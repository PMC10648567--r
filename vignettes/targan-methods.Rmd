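---
title: "targan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{targan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

targan implements a two-stage in-silico workflow around a query ligand —
the shipped fixture is cannabidiol (CBD), a non-psychoactive cannabis
constituent with reported relevance to Alzheimer's disease:

1. **Target fishing.** Given an annotated drug–target interaction corpus
   and a disease–gene phenotype table, find protein targets that the
   query plausibly binds: screen the library for structurally similar
   drugs, score the query and those neighbours against the neighbours'
   annotated targets with a binding-affinity model, keep targets where
   both clear a pIC50 cutoff, and intersect with the disease phenotype.
2. **Analog optimization.** For each identified target, evolve analogs of
   the query with a genetic algorithm that preserves the query's Murcko
   scaffold, minimizes a docking score, and enforces a drug-likeness
   constraint box plus structural-alert filters.

Both stages are built against pluggable oracle contracts, with
deterministic surrogates standing in for the external affinity predictor
and docking engine, and a synthetic-data generator standing in for the
licensed databases. That makes the entire workflow executable and
testable offline, with planted ground truth.

# Stage 1: similarity-gated target identification

**Similarity.** Molecular similarity is the average of two Tanimoto
coefficients: one over Morgan (circular, radius 2) fingerprints folded
to 2048 bits, one over the 166 MACCS keys. A drug is query-like when
this average is *strictly* greater than the threshold (default 0.4).
The query itself, if present in the library, is excluded by
canonical-structure comparison.

**Affinity.** Every candidate target (the union of the neighbours'
interaction edges — candidates come only from the neighbours' targets,
not the whole table) is scored by the affinity oracle. A target
survives iff the query scores strictly above the pIC50 cutoff (default
4.0) **and** at least one linked neighbour does too. The phrase "in
both the query and its neighbours" admits a stricter reading — *all*
linked neighbours above the cutoff — which is available as
`supportMode = "all"`; the permissive `"any"` default keeps recall
sensible when a target is reached by several neighbours of varying
similarity. Both the query score and the best supporting score are
recorded in the report as machine-checkable evidence.

**Disease intersection.** Accessions map to gene symbols through a
cross-reference table; a target matches the disease when any phenotype
string of its gene contains the query phrase as a case-insensitive
substring. Substring matching is deliberate: real phenotype strings
vary ("Alzheimer disease, type 2", "ALZHEIMER, late onset").
Accessions absent from the cross-reference are treated as unmatched,
never as errors.

Report rows are ordered by descending query pIC50 and then accession,
so repeated runs are byte-identical.

# Drug-likeness machinery

**logP** is the Wildman–Crippen atom-contribution estimate computed by
OpenBabel. **QED** follows the published desirability model: eight
properties (MW, logP, H-bond acceptors and donors, TPSA, rotatable
bonds, aromatic rings, structural-alert count) are each passed through
a fitted asymmetric double sigmoid and combined as a geometric mean
under the published mean weights. The acceptor definition, alert list
and all sigmoid parameters are the published constants; two alert
patterns that count disconnected components (three ester groups, four
fluorines) are implemented as explicit multiplicity checks because the
SMARTS engine matches one component at a time.

**Synthetic accessibility** keeps the Ertl–Schuffenhauer structure —
a fragment-frequency score over radius-0..2 atom environments, minus
size, ring-complexity and macrocycle penalties, plus a symmetry
correction, mapped onto [1, 10] — but its fragment table is built from
a small reference corpus of 89 common drug-like molecules shipped with
the package (`sa_corpus_synthetic.smi`), not from the original
million-compound PubChem table, which cannot be redistributed here.
The frequency-centring constant (+2.3) was fixed once by minimizing the
RMSE against reference scores on that corpus (RMSE 0.65, r 0.66) and is
not a tuning knob. Consequence: scores are internally comparable and
respect the ≤ 6.0 feasibility cutoff in a meaningful way, but they are
not numerically interchangeable with scores from the original table.
Stereocentres contribute no penalty because the package does not model
stereochemistry at all (fingerprints, scaffolds and GA operators are
stereo-free; the CBD fixture is the stereo-free SMILES).

**Penalized logP** is `plogP = logP − SAScore − RingPenalty`. The ring
penalty is `max(0, largest ring − 6)`: the penalized-logP literature's
standard definition, consistent with the observation that published
analog tables show `plogP = logP − SAScore` exactly when no ring
exceeds six atoms.

**Alert filters.** Four SMARTS catalogs — PAINS, Brenk, NIH, ZINC — are
shipped as plain-text `SMARTS<TAB>name` files. They are *curated
representative subsets* (12–17 patterns each) of the public
collections, centred on reactivity and assay-interference motifs; the
full published sets cannot be redistributed from this environment. Two
consequences are documented rather than hidden: a molecule passing
these subsets might still hit a rarer alert in the full catalogs; and
lead-likeness flags such as "aliphatic long chain" (which the full
Brenk set raises against CBD itself) are deliberately out, matching a
workflow in which CBD-scaffold analogs are expected to be able to pass.
A molecule passes a catalog when zero alerts match; the overall verdict
is the conjunction over the four catalogs.

# Stage 2: scaffold-constrained genetic algorithm

**Representation.** Individuals are full molecules whose atom order is
normalized so the seed's Murcko-scaffold atoms occupy positions
`1..k`. The Murcko scaffold is computed on the package's own kekulized
graph: iteratively prune terminal atoms (leaving rings plus linkers),
then restore atoms attached to the framework by a double or triple
bond; acyclic molecules have no scaffold and are rejected as seeds.

**Operators.** Mutation draws one of four edits uniformly: append a
substituent atom from {C, N, O, S, F, Cl} by a single bond anywhere
with free valence; delete a terminal non-scaffold atom; swap a
non-scaffold heavy atom's element (valence permitting); or change the
order of an acyclic bond between two non-scaffold atoms. Because no
edit touches scaffold atoms or scaffold bonds, and no edit can create a
ring, the scaffold is preserved *by construction*; it is additionally
re-verified structurally, and children OpenBabel cannot parse are
discarded within a bounded retry budget (default 10), after which the
parent is returned unchanged. Crossover inherits, per scaffold
position, the complete substituent set of one uniformly drawn parent;
since every atom's valence then equals one parent's, children are valid
by construction. Incompatible parents degrade to mutation of the first
parent.

**Selection.** Constraint domination with a total order: feasible
individuals (QED ≥ 0.5, SAScore ≤ 6.0, logP ≤ 5.0, all four alert
catalogs clean, scaffold preserved) always outrank infeasible ones;
infeasibles rank by the sum of normalized constraint shortfalls;
feasibles rank by docking score, with ties broken by higher plogP,
higher QED, then canonical SMILES. Tournament selection (size 3),
elitism (2), and a hall of fame of the best unique feasible analogs
(default size 8, chosen to exceed the largest per-target analog count
the workflow is expected to report). The docking oracle is consulted
for every individual in every generation — the optimization loop's
feedback is never batched or subsampled. Note the seed itself need not
be feasible: CBD's logP estimate is ≈ 5.85, so the GA's first task is
to trade lipophilicity for polar substituents; constraint domination
handles this without any special casing.

The GA's mechanics (operator set, rates, selection scheme, stopping
after a fixed generation count) are this package's design choices,
chosen to be conventional and fully seeded: a run is a pure function of
`GAConfig@seed`.

# Surrogate oracles

Both oracles are deterministic pure functions of (canonical structure,
target, spec); adapters for external predictors implement the same
function signatures (`function(drugSmiles, targetId, targetSequence)`
and `function(mol, targetId)`) and can be swapped in without touching
the pipeline. External adapters are documented interfaces only, not
shipped integrations, and numeric reproduction of any external
predictor's outputs is explicitly not attempted.

**Affinity:** `pIC50 = baseline + effect × Tanimoto(morgan(drug),
features(target))`, with `baseline = 2`, `effect = 4`, and the planted
feature set equal to the query's Morgan fingerprint for the designated
targets; unknown targets score at baseline. Planted pairs therefore sit
above the 4.0 cutoff exactly when the drug's Morgan similarity to the
query exceeds 0.5 — a margin the data generator *verifies* when
planting neighbours.

**Docking:** each target gets a requirement key derived arithmetically
from the spec seed — a nitrogen count in {1, 2} and an oxygen count in
{3, 4} — and a molecule scores `−12 × (satisfied fraction)` kcal/mol,
bounded in [−12, 0] (the span mirrors realistic docking ranges). The
optimum, −12, is attained by any molecule meeting the full key, which
is always reachable under the scaffold constraint by appending polar
atoms; `surrogateDockingOptimum()` exposes it in closed form so
convergence tests compare against a known answer. A fingerprint-overlap
surrogate was rejected: its optimum is effectively unreachable for a
desk-scale GA, which would make a convergence criterion vacuous. The
key's pull toward N/O-rich analogs also points the search in the same
direction as the feasibility box (polar groups lower logP), which is
both convenient and chemically sensible for a seed that starts
lipophilic.

# The synthetic-data generator

`generateScenario()` emulates the study corpus at desk scale. Defaults
— the package's standard study conditions — are 100 drugs (10 planted
near-neighbours, 90 decoys), 50 random-sequence 50-mer protein targets
(8 with planted affinity, of which 3 disease-tagged), neighbour edit
depth 1–2, and two "lure" targets that carry the disease phenotype but
no planted affinity (they must be rejected by the affinity filter, not
the phenotype join).

Near-neighbours are scaffold-preserving mutations of the query,
accepted only after *verifying* average Tanimoto > 0.4 and Morgan
Tanimoto > 0.5 against the query; decoys come from a disjoint
heterocyclic fragment grammar and are accepted only below 0.4 (and
0.45 Morgan). Generation fails loudly when the margins cannot be met
within a bounded retry budget — separation holds by verification, not
hope. Protein sequences are uniform-random 50-mers: the surrogate
affinity oracle keys on target identity, not sequence content, so
sequence realism buys nothing. One seeded RNG drives the whole
scenario; the previous RNG state is restored on exit.

What the generator does *not* emulate, and what passing tests therefore
do not show: real database scale (tens of thousands of drugs),
correlated target families, realistic affinity landscapes (the
surrogate's similarity-linear pIC50 is far smoother than any learned
predictor), assay noise, or phenotype curation artifacts. The planted
recovery results certify the pipeline's logic — thresholds, joins,
evidence bookkeeping — not real-data performance, and the published
corpus-scale counts (74 similar molecules, 3646 candidate targets, six
disease targets) are not reproducible from synthetic data by design.

# Numerical and degenerate-input choices

- Thresholds are strict everywhere ("higher than"): similarity exactly
  0.4 and pIC50 exactly 4.0 are excluded.
- Property values are reported at two decimals in rendered reports;
  internal computation is full precision.
- Canonicalization is OpenBabel's; the empty scaffold is represented by
  a zero-atom sentinel molecule, and operations on it are errors only
  where the scaffold constraint would be undefined (GA seeding).
- Single-atom molecules (e.g. methane) are parsed and fingerprinted
  through a dedicated path because the standard SDF round trip treats
  bond-less records as invalid.
- Two empty fingerprints count as identical (similarity 1); this can
  only arise for sub-heavy-atom edge cases, not for library molecules.
- Ring statistics use the cyclomatic count and per-edge smallest rings;
  bridgehead/spiro complexity in the SA score is approximated as
  ring-subgraph atoms of degree > 2.

# Problem sizes used by the shipped tests

The test suite and acceptance checks run the standard scenario
(100 × 50) for five seeds, a brute-force cross-check at the same size,
and the standard GA convergence run — population 50, 20 generations,
seed 7, target `T0001` — which reaches the surrogate optimum well
before generation 20. The stochastic single-substituent property runs
ten independent seeds at the same GA size. These sizes are the
package's chosen desk-scale study conditions; scaling the GA to its
defaults (population 100, 50 generations) changes runtime, not
behaviour.

# Known limitations

- No stereochemistry, no 3D: conformers, docking geometry and
  BBB-permeability prediction are out of scope.
- The SA score and alert catalogs are reduced stand-ins (see above);
  absolute SA values and filter verdicts on exotic chemistry should not
  be compared against full-catalog implementations.
- Fingerprints come from OpenBabel's ECFP/MACCS implementations;
  similarity values differ from other toolkits' by up to ~0.1 even
  though threshold behaviour is robust (cross-toolkit agreement is
  tested on fixtures within a tolerance band).
- The GA explores substituent space only: it never rebuilds rings, so
  analog diversity is narrower than graph-rewriting generators. That is
  the point of scaffold preservation, but worth keeping in mind when
  interpreting hall-of-fame diversity.
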