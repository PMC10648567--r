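# Stage 2: scaffold-constrained genetic optimization of analogs.
#
# Individuals are molecules sharing the seed's Murcko scaffold. The
# operators edit only side-chain atoms, so the scaffold is preserved by
# construction (and re-verified structurally); children that OpenBabel
# refuses to parse degrade to their parent. Selection uses constraint
# domination: feasible individuals (drug-likeness box + alert filters)
# always outrank infeasible ones, infeasible ones rank by violation,
# feasible ones by docking score.

.gaElements <- c("C", "N", "O", "S", "F", "Cl")

#' GAConfig: genetic-algorithm settings
#'
#' @slot populationSize individuals per generation (default 100).
#' @slot generations generational loop count (default 50).
#' @slot crossoverProb probability a child is produced by crossover
#'   rather than copied from its first parent (default 0.6).
#' @slot mutationProb probability a child is mutated (default 0.4).
#' @slot eliteCount individuals carried over unchanged (default 2).
#' @slot hallOfFameSize archive of best unique feasible analogs
#'   (default 8).
#' @slot tournamentSize selection tournament size (default 3).
#' @slot mutationRetries bounded retry budget per mutation (default 10).
#' @slot seed integer RNG seed; the whole run is a pure function of it.
#' @export
setClass("GAConfig",
         representation(populationSize = "integer", generations = "integer",
                        crossoverProb = "numeric", mutationProb = "numeric",
                        eliteCount = "integer", hallOfFameSize = "integer",
                        tournamentSize = "integer",
                        mutationRetries = "integer", seed = "integer"),
         prototype(populationSize = 100L, generations = 50L,
                   crossoverProb = 0.6, mutationProb = 0.4,
                   eliteCount = 2L, hallOfFameSize = 8L,
                   tournamentSize = 3L, mutationRetries = 10L, seed = 1L))

setValidity("GAConfig", function(object) {
  if (object@crossoverProb < 0 || object@crossoverProb > 1 ||
      object@mutationProb < 0 || object@mutationProb > 1)
    return("probabilities must lie in [0,1]")
  if (object@eliteCount >= object@populationSize)
    return("eliteCount must be smaller than populationSize")
  if (object@populationSize < 2L) return("populationSize must be >= 2")
  TRUE
})

#' @rdname GAConfig-class
#' @param populationSize,generations,crossoverProb,mutationProb,eliteCount,hallOfFameSize,tournamentSize,mutationRetries,seed
#'   see slots.
#' @export
gaConfig <- function(populationSize = 100L, generations = 50L,
                     crossoverProb = 0.6, mutationProb = 0.4,
                     eliteCount = 2L, hallOfFameSize = 8L,
                     tournamentSize = 3L, mutationRetries = 10L, seed = 1L) {
  new("GAConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations), crossoverProb = crossoverProb,
      mutationProb = mutationProb, eliteCount = as.integer(eliteCount),
      hallOfFameSize = as.integer(hallOfFameSize),
      tournamentSize = as.integer(tournamentSize),
      mutationRetries = as.integer(mutationRetries), seed = as.integer(seed))
}

#' Individual: one evaluated GA solution
#'
#' @slot mol the [Molecule-class].
#' @slot profile its [PropertyProfile-class].
#' @slot dockingScore oracle docking score, kcal/mol (lower = stronger).
#' @slot feasible all constraints met: QED >= 0.5, SAScore <= 6,
#'   logP <= 5, all four alert catalogs clean, scaffold preserved.
#' @slot violation sum of normalized constraint shortfalls (0 iff
#'   feasible).
#' @slot generationBorn generation index at creation (0 = initial).
#' @export
setClass("Individual",
         representation(mol = "Molecule", profile = "PropertyProfile",
                        dockingScore = "numeric", feasible = "logical",
                        violation = "numeric", generationBorn = "integer"))

setMethod("show", "Individual", function(object) {
  cat(sprintf("Individual: %s\n  docking %.2f | %s | violation %.3f\n",
              canonicalSmiles(object@mol), object@dockingScore,
              if (object@feasible) "feasible" else "infeasible",
              object@violation))
  invisible(object)
})

#' @describeIn Individual-class docking-score accessor.
#' @param x an `Individual`.
#' @export
dockingScore <- function(x) x@dockingScore

#' @describeIn Individual-class feasibility accessor.
#' @export
isFeasible <- function(x) x@feasible

## ---- scaffold-aligned representation ----

# Align a molecule's atom order so scaffold atoms occupy 1..k. Errors if
# the molecule's Murcko scaffold does not equal `scaffold`.
.alignToScaffold <- function(m, scaffold) {
  if (length(m@scaffoldAtoms))
    return(m)  # already aligned by construction
  keep <- .murckoKeepSet(m@graph)
  if (!any(keep))
    stop("molecule has an empty Murcko scaffold; the scaffold ",
         "constraint is undefined")
  own <- murckoScaffold(m)
  if (!sameStructure(own, scaffold))
    stop("molecule scaffold (", canonicalSmiles(own),
         ") differs from the seed scaffold (",
         canonicalSmiles(scaffold), ")")
  g <- .reorderAtoms(m@graph, which(keep))
  out <- .moleculeFromGraph(g, m@smilesCanonical, input = m@smilesInput,
                            scaffoldAtoms = seq_len(sum(keep)))
  out
}

# TRUE iff atoms 1..k of g (with their mutual bonds) are structurally
# identical to refGraph.
.scaffoldIntact <- function(g, k, refGraph) {
  if (.graphNAtoms(g) < k) return(FALSE)
  if (!identical(g$elem[seq_len(k)], refGraph$elem)) return(FALSE)
  sel <- g$bonds[, 1L] <= k & g$bonds[, 2L] <= k
  b1 <- g$bonds[sel, , drop = FALSE]
  b2 <- refGraph$bonds
  if (nrow(b1) != nrow(b2)) return(FALSE)
  key <- function(b) sort(sprintf("%d-%d-%d", pmin(b[, 1L], b[, 2L]),
                                  pmax(b[, 1L], b[, 2L]), b[, 3L]))
  identical(key(b1), key(b2))
}

## ---- edit operators (graph level) ----

# One random scaffold-preserving edit; returns the edited graph or NULL
# when the drawn operator has no applicable site.
.editGraphOnce <- function(g, k) {
  n <- .graphNAtoms(g)
  op <- sample(4L, 1L)
  if (op == 1L) {                                   # append substituent atom
    free <- which(.freeValence(g) > 0L)
    if (!length(free)) return(NULL)
    at <- free[sample.int(length(free), 1L)]
    el <- sample(.gaElements, 1L)
    g$elem <- c(g$elem, el)
    g$charge <- c(g$charge, 0L)
    g$bonds <- rbind(g$bonds, c(at, n + 1L, 1L))
    return(g)
  }
  if (op == 2L) {                                   # delete terminal atom
    deg <- tabulate(as.vector(g$bonds[, 1:2]), n)
    cand <- which(deg == 1L & seq_len(n) > k)
    if (!length(cand)) return(NULL)
    at <- cand[sample.int(length(cand), 1L)]
    keep <- setdiff(seq_len(n), at)
    return(.stripSubgraphAttr(.inducedSubgraph(g, keep)))
  }
  if (op == 3L) {                                   # swap heavy-atom element
    cand <- which(seq_len(n) > k)
    if (!length(cand)) return(NULL)
    at <- cand[sample.int(length(cand), 1L)]
    used <- .usedValence(g)[at]
    ok <- .gaElements[.maxValence[.gaElements] >= used &
                        .gaElements != g$elem[at]]
    if (!length(ok)) return(NULL)
    g$elem[at] <- sample(ok, 1L)
    g$charge[at] <- 0L
    return(g)
  }
  # op 4: change the order of an acyclic side-chain bond
  if (!nrow(g$bonds)) return(NULL)
  ri <- .ringInfo(g)
  cand <- which(g$bonds[, 1L] > k & g$bonds[, 2L] > k & !ri$ringBonds)
  if (!length(cand)) return(NULL)
  b <- cand[sample.int(length(cand), 1L)]
  free <- .freeValence(g)
  cur <- g$bonds[b, 3L]
  slack <- min(free[g$bonds[b, 1L]], free[g$bonds[b, 2L]])
  orders <- setdiff(seq_len(min(3L, cur + slack)), cur)
  if (!length(orders)) return(NULL)
  g$bonds[b, 3L] <- orders[sample.int(length(orders), 1L)]
  g
}

.stripSubgraphAttr <- function(g) { attr(g, "origin") <- NULL; g }

#' Scaffold-preserving mutation
#'
#' Applies one randomly chosen edit -- append a substituent atom
#' (C/N/O/S/F/Cl), delete a terminal non-scaffold atom, swap a
#' non-scaffold heavy atom's element, or change an acyclic side-chain
#' bond order -- then validates the child (OpenBabel re-parse, valence
#' accounting, structural scaffold identity). On repeated failure the
#' input is returned unchanged. Consumes the R RNG stream, so results
#' are reproducible under `set.seed()`.
#'
#' @param m a [Molecule-class] whose Murcko scaffold equals
#'   `seedScaffold`.
#' @param seedScaffold the seed's scaffold ([murckoScaffold()]).
#' @param retries bounded retry budget (default 10).
#' @return a [Molecule-class]; scaffold equal to `seedScaffold`.
#' @export
mutateMolecule <- function(m, seedScaffold, retries = 10L) {
  stopifnot(is(m, "Molecule"), is(seedScaffold, "Molecule"))
  m <- .alignToScaffold(m, seedScaffold)
  k <- length(m@scaffoldAtoms)
  ref <- m@graph
  refScaffold <- .stripSubgraphAttr(.inducedSubgraph(ref, seq_len(k)))
  for (i in seq_len(max(0L, retries))) {
    child <- .editGraphOnce(ref, k)
    if (is.null(child)) next
    if (!.scaffoldIntact(child, k, refScaffold)) next
    can <- .obCanonicalFromGraphs(list(child))
    if (is.na(can[1L])) next
    return(.moleculeFromGraph(child, can[1L], scaffoldAtoms = seq_len(k)))
  }
  m
}

# Side-chain decomposition of an aligned graph: list of components,
# each list(atoms = indices > k, attach = scaffold atom, bond rows).
.sideChains <- function(g, k) {
  n <- .graphNAtoms(g)
  if (n <= k) return(list())
  side <- setdiff(seq_len(n), seq_len(k))
  sub <- .inducedSubgraph(g, side)
  comp <- .componentsOf(sub)
  origin <- attr(sub, "origin")
  out <- list()
  for (ci in sort(unique(comp))) {
    atoms <- origin[comp == ci]
    attach <- NA_integer_
    for (b in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds[b, 1L]; a2 <- g$bonds[b, 2L]
      if (a1 <= k && a2 %in% atoms) attach <- a1
      if (a2 <= k && a1 %in% atoms) attach <- a2
    }
    out[[length(out) + 1L]] <- list(atoms = atoms, attach = attach)
  }
  out
}

# Copy the side-chain components `comps` (from donor graph `g`) onto
# `base` (scaffold-only or partial child graph); returns extended graph.
.graftChains <- function(base, g, comps) {
  for (cp in comps) {
    offset <- .graphNAtoms(base)
    map <- stats::setNames(offset + seq_along(cp$atoms), cp$atoms)
    base$elem <- c(base$elem, g$elem[cp$atoms])
    base$charge <- c(base$charge, g$charge[cp$atoms])
    for (b in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds[b, 1L]; a2 <- g$bonds[b, 2L]
      in1 <- a1 %in% cp$atoms; in2 <- a2 %in% cp$atoms
      if (in1 && in2) {
        base$bonds <- rbind(base$bonds,
                            c(map[[as.character(a1)]],
                              map[[as.character(a2)]], g$bonds[b, 3L]))
      } else if (in1 && a2 == cp$attach) {
        base$bonds <- rbind(base$bonds,
                            c(a2, map[[as.character(a1)]], g$bonds[b, 3L]))
      } else if (in2 && a1 == cp$attach) {
        base$bonds <- rbind(base$bonds,
                            c(a1, map[[as.character(a2)]], g$bonds[b, 3L]))
      }
    }
  }
  base
}

#' Scaffold-preserving crossover
#'
#' Both parents must carry the common seed scaffold. For every scaffold
#' attachment position the child inherits the substituent set of one
#' parent, drawn uniformly; per-position inheritance keeps every atom's
#' valence identical to one parent's, so children are valid by
#' construction. When the parents cannot be decomposed against a common
#' scaffold alignment the operator degrades to [mutateMolecule()] on the
#' first parent.
#'
#' @param a,b parent [Molecule-class] objects.
#' @param seedScaffold the seed's scaffold.
#' @param retries retry budget passed to the mutation fallback.
#' @return a [Molecule-class] carrying `seedScaffold`.
#' @export
crossoverMolecules <- function(a, b, seedScaffold, retries = 10L) {
  stopifnot(is(a, "Molecule"), is(b, "Molecule"))
  a2 <- tryCatch(.alignToScaffold(a, seedScaffold), error = function(e) NULL)
  b2 <- tryCatch(.alignToScaffold(b, seedScaffold), error = function(e) NULL)
  k <- if (!is.null(a2)) length(a2@scaffoldAtoms) else 0L
  compatible <- !is.null(a2) && !is.null(b2) &&
    length(b2@scaffoldAtoms) == k &&
    identical(a2@graph$elem[seq_len(k)], b2@graph$elem[seq_len(k)])
  if (!compatible) return(mutateMolecule(a, seedScaffold, retries))
  scaffold <- .stripSubgraphAttr(.inducedSubgraph(a2@graph, seq_len(k)))
  if (!.scaffoldIntact(b2@graph, k, scaffold))
    return(mutateMolecule(a, seedScaffold, retries))
  chainsA <- .sideChains(a2@graph, k)
  chainsB <- .sideChains(b2@graph, k)
  child <- scaffold
  for (pos in seq_len(k)) {
    fromA <- sample(c(TRUE, FALSE), 1L)
    donor <- if (fromA) a2@graph else b2@graph
    comps <- Filter(function(cp) !is.na(cp$attach) && cp$attach == pos,
                    if (fromA) chainsA else chainsB)
    child <- .graftChains(child, donor, comps)
  }
  can <- .obCanonicalFromGraphs(list(child))
  if (is.na(can[1L])) return(mutateMolecule(a, seedScaffold, retries))
  .moleculeFromGraph(child, can[1L], scaffoldAtoms = seq_len(k))
}

## ---- evaluation and ordering ----

.constraintViolation <- function(p) {
  pmax(0, (0.5 - p$qed) / 0.5) +
    pmax(0, (p$sascore - 6) / 4) +
    pmax(0, (p$logp - 5) / 5) +
    (!p$pains_pass) + (!p$brenk_pass) + (!p$nih_pass) + (!p$zinc_pass)
}

# Batch evaluation: molecules -> data.frame of profile columns plus
# docking/feasible/violation. Scaffold preservation is certified by the
# caller (operators guarantee it structurally).
.evaluateBatch <- function(mols, oracle, targetId) {
  p <- .profileTable(mols)
  p$docking <- vapply(mols, function(m) {
    s <- oracle(m, targetId)
    if (!is.finite(s))
      stop("docking oracle returned a non-finite score for ",
           canonicalSmiles(m))
    s
  }, numeric(1))
  p$violation <- .constraintViolation(p)
  p$feasible <- p$violation == 0
  p$smiles <- vapply(mols, canonicalSmiles, "")
  p
}

#' Evaluate one individual
#'
#' Fills the drug-likeness profile, alert verdicts, docking score,
#' feasibility and violation for a molecule. Deterministic.
#' @param m a [Molecule-class].
#' @param oracle docking oracle, see [surrogateDocking()].
#' @param targetId target accession passed to the oracle.
#' @param generation generation tag stored on the individual.
#' @return an [Individual-class].
#' @export
evaluateIndividual <- function(m, oracle, targetId, generation = 0L) {
  stopifnot(is(m, "Molecule"))
  t <- .evaluateBatch(list(m), oracle, targetId)
  new("Individual", mol = m, profile = drugLikeness(m),
      dockingScore = t$docking, feasible = t$feasible,
      violation = t$violation, generationBorn = as.integer(generation))
}

# ordering keys used both by compareIndividuals and the vectorized loop:
# feasible first; infeasible by violation; feasible by docking, then
# higher plogp, higher qed, then canonical SMILES (total order).
.orderKeys <- function(t) {
  list(infeasible = !t$feasible,
       violation = ifelse(t$feasible, 0, t$violation),
       docking = ifelse(t$feasible, t$docking, 0),
       negPlogp = ifelse(t$feasible, -t$plogp, 0),
       negQed = ifelse(t$feasible, -t$qed, 0),
       smiles = t$smiles)
}

.orderPopulation <- function(t) {
  k <- .orderKeys(t)
  order(k$infeasible, k$violation, k$docking, k$negPlogp, k$negQed,
        k$smiles)
}

#' Constraint-domination ordering of two individuals
#'
#' Feasible beats infeasible; two infeasibles order by smaller
#' violation; two feasibles by lower docking score, ties by higher
#' penalized logP, then higher QED, then canonical SMILES -- a total
#' order.
#' @param x,y evaluated [Individual-class] objects.
#' @return -1 if `x` ranks first, 1 if `y` does, 0 if equal on all keys.
#' @export
compareIndividuals <- function(x, y) {
  stopifnot(is(x, "Individual"), is(y, "Individual"))
  key <- function(i) list(!i@feasible,
                          if (i@feasible) 0 else i@violation,
                          if (i@feasible) i@dockingScore else 0,
                          if (i@feasible) -i@profile@plogp else 0,
                          if (i@feasible) -i@profile@qed else 0)
  kx <- key(x); ky <- key(y)
  for (j in seq_along(kx)) {
    if (kx[[j]] < ky[[j]]) return(-1L)
    if (kx[[j]] > ky[[j]]) return(1L)
  }
  sx <- canonicalSmiles(x@mol); sy <- canonicalSmiles(y@mol)
  if (sx < sy) return(-1L)
  if (sx > sy) return(1L)
  0L
}

## ---- hall of fame ----

#' HallOfFame: archive of the best unique feasible analogs
#'
#' Members are unique by canonical structure, all feasible, ordered best
#' docking score first (ties resolved by the [compareIndividuals()]
#' total order, so the ordering is stable).
#' @slot individuals list of [Individual-class].
#' @slot size maximum archive size.
#' @slot history per-generation data frame: generation, best feasible
#'   docking score so far (NA until a feasible individual appears),
#'   number of feasible individuals in the population.
#' @export
setClass("HallOfFame",
         representation(individuals = "list", size = "integer",
                        history = "data.frame"))

setMethod("show", "HallOfFame", function(object) {
  cat("HallOfFame:", length(object@individuals), "analog(s) (max",
      object@size, ")\n")
  for (i in seq_along(object@individuals)) {
    ind <- object@individuals[[i]]
    cat(sprintf("  %d. %-40s docking %6.2f  plogP %6.2f\n", i,
                canonicalSmiles(ind@mol), ind@dockingScore,
                ind@profile@plogp))
  }
  invisible(object)
})

setMethod("length", "HallOfFame", function(x) length(x@individuals))

#' @describeIn HallOfFame-class members as a data frame (one analog per
#'   row: smiles, docking score, QED, SAScore, logP, ring penalty,
#'   plogP, filter verdicts, generation born).
#' @param x a `HallOfFame`.
#' @export
hallOfFameTable <- function(x) {
  stopifnot(is(x, "HallOfFame"))
  if (!length(x@individuals)) {
    return(data.frame(smiles = character(0), docking = numeric(0),
                      qed = numeric(0), sascore = numeric(0),
                      logp = numeric(0), ring_penalty = integer(0),
                      plogp = numeric(0), filters_pass = logical(0),
                      generation_born = integer(0)))
  }
  do.call(rbind, lapply(x@individuals, function(ind) {
    p <- ind@profile
    data.frame(smiles = canonicalSmiles(ind@mol),
               docking = ind@dockingScore, qed = p@qed,
               sascore = p@sascore, logp = p@logp,
               ring_penalty = p@ringPenalty, plogp = p@plogp,
               filters_pass = p@painsPass && p@brenkPass && p@nihPass &&
                 p@zincPass,
               generation_born = ind@generationBorn)
  }))
}

#' @describeIn HallOfFame-class best (lowest) docking score among
#'   members; `NA` when empty.
#' @export
bestDockingScore <- function(x) {
  if (!length(x@individuals)) return(NA_real_)
  min(vapply(x@individuals, function(i) i@dockingScore, numeric(1)))
}

#' @describeIn HallOfFame-class per-generation convergence history.
#' @export
gaHistory <- function(x) x@history

.hofUpdate <- function(members, t, mols, generation, size) {
  newRows <- which(t$feasible)
  for (i in newRows) {
    smi <- t$smiles[i]
    if (smi %in% names(members)) next
    p <- t[i, ]
    members[[smi]] <- new(
      "Individual", mol = mols[[i]],
      profile = new("PropertyProfile", qed = p$qed, sascore = p$sascore,
                    logp = p$logp, ringPenalty = p$ring_penalty,
                    plogp = p$plogp, painsPass = p$pains_pass,
                    brenkPass = p$brenk_pass, nihPass = p$nih_pass,
                    zincPass = p$zinc_pass),
      dockingScore = p$docking, feasible = TRUE, violation = 0,
      generationBorn = as.integer(generation))
  }
  if (length(members) > 1L) {
    tab <- data.frame(
      feasible = TRUE,
      violation = 0,
      docking = vapply(members, function(m) m@dockingScore, numeric(1)),
      plogp = vapply(members, function(m) m@profile@plogp, numeric(1)),
      qed = vapply(members, function(m) m@profile@qed, numeric(1)),
      smiles = names(members))
    members <- members[.orderPopulation(tab)]
  }
  if (length(members) > size) members <- members[seq_len(size)]
  members
}

## ---- the generational loop ----

#' Initialize a scaffold-preserving population
#'
#' The first individual is the seed itself; the rest are single-mutation
#' variants. All individuals carry the seed's Murcko scaffold and are
#' chemically valid. Errors if the seed has no scaffold (acyclic).
#' @param seedMol seed [Molecule-class] (or SMILES string).
#' @param cfg a [GAConfig-class].
#' @return list of [Molecule-class] of length `populationSize`;
#'   reproducible under `set.seed()`.
#' @export
initializePopulation <- function(seedMol, cfg = gaConfig()) {
  if (is.character(seedMol)) seedMol <- parseSmiles(seedMol)
  scaffold <- murckoScaffold(seedMol)
  if (isEmptyMolecule(scaffold))
    stop("seed molecule is acyclic: the scaffold constraint is undefined")
  seed <- .alignToScaffold(seedMol, scaffold)
  pop <- vector("list", cfg@populationSize)
  pop[[1L]] <- seed
  for (i in seq_len(cfg@populationSize - 1L) + 1L)
    pop[[i]] <- mutateMolecule(seed, scaffold, cfg@mutationRetries)
  pop
}

#' Evolve scaffold-constrained analogs of a seed molecule
#'
#' Generational GA: tournament selection, scaffold-preserving crossover
#' and mutation, elitism, and a hall-of-fame archive of the best unique
#' feasible analogs. The docking oracle is consulted for every
#' individual in every generation; drug-likeness constraints and alert
#' filters enter through constraint domination. The entire run is a
#' deterministic function of `cfg@seed`.
#'
#' @param seedMol seed [Molecule-class] or SMILES string (must have a
#'   non-empty Murcko scaffold).
#' @param targetId target accession passed to the docking oracle.
#' @param cfg a [GAConfig-class].
#' @param oracle docking oracle, see [surrogateDocking()].
#' @param verbose print per-generation summaries.
#' @return a [HallOfFame-class]; empty (with a warning) when no
#'   feasible individual was ever found.
#' @export
evolve <- function(seedMol, targetId, cfg = gaConfig(), oracle,
                   verbose = FALSE) {
  stopifnot(is(cfg, "GAConfig"), is.function(oracle))
  if (is.character(seedMol)) seedMol <- parseSmiles(seedMol)
  scaffold <- murckoScaffold(seedMol)
  if (isEmptyMolecule(scaffold))
    stop("seed molecule is acyclic: the scaffold constraint is undefined")

  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    oldSeed <- get(".Random.seed", globalenv())
  else oldSeed <- NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(cfg@seed)

  pop <- initializePopulation(seedMol, cfg)
  t <- .evaluateBatch(pop, oracle, targetId)
  members <- .hofUpdate(list(), t, pop, 0L, cfg@hallOfFameSize)
  history <- data.frame(generation = 0L,
                        best_feasible_docking =
                          if (any(t$feasible)) min(t$docking[t$feasible])
                        else NA_real_,
                        n_feasible = sum(t$feasible))

  for (gen in seq_len(cfg@generations)) {
    ord <- .orderPopulation(t)
    elites <- pop[ord[seq_len(cfg@eliteCount)]]
    elitesT <- t[ord[seq_len(cfg@eliteCount)], , drop = FALSE]

    tournament <- function() {
      idx <- sample.int(length(pop), cfg@tournamentSize, replace = TRUE)
      sub <- t[idx, , drop = FALSE]
      idx[.orderPopulation(sub)[1L]]
    }
    nOff <- cfg@populationSize - cfg@eliteCount
    offspring <- vector("list", nOff)
    for (i in seq_len(nOff)) {
      p1 <- pop[[tournament()]]
      child <- if (stats::runif(1) < cfg@crossoverProb) {
        crossoverMolecules(p1, pop[[tournament()]], scaffold,
                           cfg@mutationRetries)
      } else p1
      if (stats::runif(1) < cfg@mutationProb)
        child <- mutateMolecule(child, scaffold, cfg@mutationRetries)
      offspring[[i]] <- child
    }
    offT <- .evaluateBatch(offspring, oracle, targetId)
    pop <- c(elites, offspring)
    t <- rbind(elitesT, offT)
    members <- .hofUpdate(members, t, pop, gen, cfg@hallOfFameSize)
    bestSoFar <- if (length(members))
      min(vapply(members, function(m) m@dockingScore, numeric(1)))
    else NA_real_
    history <- rbind(history,
                     data.frame(generation = gen,
                                best_feasible_docking = bestSoFar,
                                n_feasible = sum(t$feasible)))
    if (verbose)
      message(sprintf(
        "generation %3d: best feasible docking %s, %d/%d feasible",
        gen, ifelse(is.na(bestSoFar), "none", sprintf("%.2f", bestSoFar)),
        sum(t$feasible), nrow(t)))
  }
  if (!length(members))
    warning("no feasible individual found; hall of fame is empty")
  rownames(history) <- NULL
  new("HallOfFame", individuals = unname(members),
      size = cfg@hallOfFameSize, history = history)
}
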