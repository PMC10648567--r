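# Drug-likeness properties: QED, synthetic accessibility, logP, the
# large-ring penalty and penalized logP.
#
# QED follows the published desirability model (see qed-constants.R):
# eight physicochemical properties are mapped through fitted asymmetric
# double sigmoids and combined as a weighted geometric mean. logP is the
# Wildman-Crippen atom-contribution estimate computed by OpenBabel. The
# synthetic-accessibility score keeps the Ertl-Schuffenhauer structure
# (fragment-frequency term plus size/ring-complexity penalties, scaled
# to [1,10]) but draws its fragment-frequency table from a small
# reference corpus shipped with the package rather than the original
# PubChem-derived table; see the methods vignette for what that implies.

#' PropertyProfile: drug-likeness summary of one molecule
#'
#' @slot qed quantitative estimate of drug-likeness, in \[0, 1\].
#' @slot sascore synthetic-accessibility score, in \[1, 10\] (higher is
#'   harder to synthesize).
#' @slot logp Wildman-Crippen octanol-water partition estimate.
#' @slot ringPenalty `max(0, largest ring size - 6)`.
#' @slot plogp penalized logP: `logp - sascore - ringPenalty`.
#' @slot painsPass,brenkPass,nihPass,zincPass alert-catalog verdicts.
#' @export
setClass("PropertyProfile",
         representation(qed = "numeric", sascore = "numeric",
                        logp = "numeric", ringPenalty = "integer",
                        plogp = "numeric", painsPass = "logical",
                        brenkPass = "logical", nihPass = "logical",
                        zincPass = "logical"))

setValidity("PropertyProfile", function(object) {
  if (object@qed < 0 || object@qed > 1) return("qed outside [0,1]")
  if (object@sascore < 1 || object@sascore > 10) return("sascore outside [1,10]")
  if (object@ringPenalty < 0L) return("negative ring penalty")
  if (abs(object@plogp - (object@logp - object@sascore - object@ringPenalty)) > 1e-9)
    return("plogp inconsistent with logp - sascore - ringPenalty")
  TRUE
})

setMethod("show", "PropertyProfile", function(object) {
  cat(sprintf(paste0("PropertyProfile: QED %.2f | SAScore %.2f | logP %.2f",
                     " | ring penalty %d | plogP %.2f\n"),
              object@qed, object@sascore, object@logp,
              object@ringPenalty, object@plogp))
  v <- c(PAINS = object@painsPass, BRENK = object@brenkPass,
         NIH = object@nihPass, ZINC = object@zincPass)
  cat("  filters:", paste(sprintf("%s=%s", names(v),
                                  ifelse(v, "Pass", "Fail")), collapse = " "), "\n")
  invisible(object)
})

#' Penalized logP
#'
#' `plogP = logP - SAScore - RingPenalty`: the optimization objective
#' that discourages abnormally large ring systems and synthetic
#' inaccessibility.
#' @param logp octanol-water partition estimate.
#' @param sascore synthetic-accessibility score.
#' @param ringPenalty non-negative large-ring penalty.
#' @return the penalized logP value.
#' @examples
#' plogp(4.44, 3.58, 0)  # 0.86
#' @export
plogp <- function(logp, sascore, ringPenalty) {
  stopifnot(is.numeric(logp), is.numeric(sascore), is.numeric(ringPenalty),
            all(ringPenalty >= 0))
  logp - sascore - ringPenalty
}

#' Large-ring penalty
#'
#' `max(0, size of largest ring - 6)`; zero for acyclic molecules and
#' for ring systems of six-membered or smaller rings.
#' @param m a [Molecule-class].
#' @return non-negative integer.
#' @examples
#' ringPenalty(parseSmiles("C1CCCCCCC1"))  # cyclooctane: 2
#' @export
ringPenalty <- function(m) {
  stopifnot(is(m, "Molecule"))
  max(0L, largestRingSize(m) - 6L)
}

## ---- QED ----

.ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p[["C"]] + p[["D"]] / 2) / p[["E"]])
  e2 <- 1 + exp(-(x - p[["C"]] - p[["D"]] / 2) / p[["F"]])
  (p[["A"]] + p[["B"]] / e1 * (1 - 1 / e2)) / p[["DMAX"]]
}

# Batch QED-property matrix for canonical SMILES.
.qedPropertyMatrix <- function(canSmiles) {
  refs <- .obMolRefs(canSmiles)
  props <- .obProps(canSmiles)
  hba <- integer(length(canSmiles))
  for (p in .qedAcceptorSmarts)
    hba <- hba + .obSmartsCount(refs, p)
  rotb <- .obSmartsCount(refs, .rotorSmarts)
  arom <- .obSmartsCount(refs, "a1aaaa1") + .obSmartsCount(refs, "a1aaaaa1") +
    .obSmartsCount(refs, "a1aaaaaa1")
  alerts <- integer(length(canSmiles))
  for (p in .qedAlertSmarts)
    alerts <- alerts + (.obSmartsCount(refs, p) > 0L)
  for (sp in .qedAlertMultiplicity)
    alerts <- alerts + (.obSmartsCount(refs, sp$smarts) >= sp$n)
  cbind(MW = props$MW, ALOGP = props$logP, HBA = hba, HBD = props$HBD,
        PSA = props$TPSA, ROTB = rotb, AROM = arom, ALERTS = alerts)
}

.qedFromProperties <- function(pm) {
  w <- .qedWeights
  d <- vapply(names(w), function(k) {
    pmin(pmax(.ads(pm[, k], .qedAdsParams[[k]]), 1e-9), 1)
  }, numeric(nrow(pm)))
  d <- matrix(d, nrow = nrow(pm))
  as.vector(exp((log(d) %*% w) / sum(w)))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Desirability-weighted combination of molecular weight, logP,
#' hydrogen-bond acceptors and donors, polar surface area, rotatable
#' bonds, aromatic rings, and structural-alert count, using the
#' published mean weights.
#' @param m a [Molecule-class].
#' @return QED in \[0, 1\].
#' @export
qedScore <- function(m) {
  stopifnot(is(m, "Molecule"))
  .qedFromProperties(.qedPropertyMatrix(canonicalSmiles(m)))
}

## ---- synthetic accessibility ----

# Fragment-frequency table from the shipped reference corpus, built
# lazily once per session. Scores are log10 relative frequencies,
# centred so that ubiquitous fragments contribute ~ +3 and fragments
# absent from the corpus -4 (the floor for unknown chemistry).
.saFragmentTable <- function() {
  tab <- .targanEnv$saTable
  if (!is.null(tab)) return(tab)
  path <- system.file("extdata", "sa_corpus_synthetic.smi",
                      package = "targan", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  smiles <- vapply(strsplit(lines, "[ \t]+"), `[`, "", 1L)
  mols <- parseSmilesBatch(smiles)
  frags <- unlist(lapply(mols[!vapply(mols, is.null, logical(1))],
                         function(m) .atomEnvironments(m@graph, 2L)))
  counts <- table(frags)
  # centring constant calibrated once against reference scores on this
  # corpus (minimum RMSE); see the methods vignette
  score <- log10(as.numeric(counts) / length(smiles)) + 2.3
  score <- pmin(pmax(score, -4), 4)
  names(score) <- names(counts)
  .targanEnv$saTable <- score
  score
}

.saScoreFromGraph <- function(g) {
  tab <- .saFragmentTable()
  frags <- .atomEnvironments(g, 2L)
  sc <- tab[frags]
  sc[is.na(sc)] <- -4
  score1 <- mean(sc)

  n <- .graphNAtoms(g)
  ri <- .ringInfo(g)
  sizePenalty <- n^1.005 - n
  macroPenalty <- if (ri$largest > 8L) log10(2) else 0
  # ring-complexity: bridgehead/spiro atoms approximated as ring atoms
  # whose degree within the ring subgraph exceeds two
  ringDeg <- integer(n)
  if (.graphNBonds(g) > 0L) {
    for (b in which(ri$ringBonds)) {
      ringDeg[g$bonds[b, 1L]] <- ringDeg[g$bonds[b, 1L]] + 1L
      ringDeg[g$bonds[b, 2L]] <- ringDeg[g$bonds[b, 2L]] + 1L
    }
  }
  nJunction <- sum(ringDeg > 2L)
  ringPenaltyTerm <- log10(nJunction + 1)
  score2 <- -(sizePenalty + macroPenalty + ringPenaltyTerm)

  nUnique <- length(unique(frags))
  score3 <- if (n > nUnique) log(n / nUnique) * 0.5 else 0

  raw <- score1 + score2 + score3
  smin <- -4; smax <- 2.5
  sa <- 11 - (raw - smin + 1) / (smax - smin) * 9
  if (sa > 8) sa <- 8 + log(sa + 1 - 9)
  min(max(sa, 1), 10)
}

#' Synthetic-accessibility score
#'
#' Fragment-frequency score with size, ring-complexity and macrocycle
#' penalties, scaled to \[1, 10\] (1 easy, 10 hard). The fragment table
#' is derived from the package's synthetic reference corpus, so values
#' are internally comparable but not numerically interchangeable with
#' scores from the original PubChem-derived table.
#' @param m a [Molecule-class].
#' @return score in \[1, 10\].
#' @export
saScore <- function(m) {
  stopifnot(is(m, "Molecule"))
  .saScoreFromGraph(m@graph)
}

#' Wildman-Crippen logP
#'
#' Atom-contribution octanol-water partition estimate (computed by
#' OpenBabel).
#' @param m a [Molecule-class].
#' @return logP estimate.
#' @export
crippenLogP <- function(m) {
  stopifnot(is(m, "Molecule"))
  .obProps(canonicalSmiles(m))$logP
}

## ---- combined profile ----

# Batch profile table; rows align with `mols`. Cached per canonical
# SMILES. Columns: qed, sascore, logp, ring_penalty, plogp, and the four
# *_pass verdicts.
.profileTable <- function(mols) {
  n <- length(mols)
  cols <- c("qed", "sascore", "logp", "ring_penalty", "plogp",
            "pains_pass", "brenk_pass", "nih_pass", "zinc_pass")
  out <- as.data.frame(matrix(NA, n, length(cols),
                              dimnames = list(NULL, cols)))
  if (!n) return(out)
  can <- vapply(mols, canonicalSmiles, "")
  need <- integer(0)
  for (i in seq_len(n)) {
    hit <- .cacheGet(paste0("prof|", can[i]))
    if (is.null(hit)) need <- c(need, i) else out[i, ] <- hit
  }
  if (length(need)) {
    first <- need[!duplicated(can[need])]
    ucan <- can[first]
    pm <- .qedPropertyMatrix(ucan)
    qed <- .qedFromProperties(pm)
    hits <- .alertMatchBatch(ucan)
    pass <- vapply(.alertCatalogNames,
                   function(catg) rowSums(hits[[catg]]) == 0L,
                   logical(length(ucan)))
    pass <- matrix(pass, nrow = length(ucan),
                   dimnames = list(NULL, .alertCatalogNames))
    for (j in seq_along(first)) {
      m <- mols[[first[j]]]
      sas <- .saScoreFromGraph(m@graph)
      rp <- max(0L, largestRingSize(m) - 6L)
      row <- c(qed = qed[j], sascore = sas, logp = pm[j, "ALOGP"],
               ring_penalty = rp, plogp = pm[j, "ALOGP"] - sas - rp,
               pains_pass = pass[j, "pains"], brenk_pass = pass[j, "brenk"],
               nih_pass = pass[j, "nih"], zinc_pass = pass[j, "zinc"])
      .cacheSet(paste0("prof|", ucan[j]), row)
    }
    for (i in need) out[i, ] <- .cacheGet(paste0("prof|", can[i]))
  }
  for (v in c("pains_pass", "brenk_pass", "nih_pass", "zinc_pass"))
    out[[v]] <- as.logical(out[[v]])
  out$ring_penalty <- as.integer(out$ring_penalty)
  out
}

#' Full drug-likeness profile of a molecule
#'
#' Computes QED, the synthetic-accessibility score, logP, the large-ring
#' penalty, penalized logP and the four structural-alert verdicts in one
#' pass. Deterministic for a given structure.
#' @param m a [Molecule-class].
#' @return a [PropertyProfile-class].
#' @export
drugLikeness <- function(m) {
  stopifnot(is(m, "Molecule"))
  t <- .profileTable(list(m))
  new("PropertyProfile", qed = t$qed, sascore = t$sascore, logp = t$logp,
      ringPenalty = t$ring_penalty, plogp = t$plogp,
      painsPass = t$pains_pass, brenkPass = t$brenk_pass,
      nihPass = t$nih_pass, zincPass = t$zinc_pass)
}
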