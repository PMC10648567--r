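# Stage 1: ligand-based target fishing.
#
# Three steps: (1) screen the annotated drug library for molecules
# similar to the query (average Morgan/MACCS Tanimoto strictly above the
# threshold), (2) score the query and its neighbours against the
# neighbours' annotated targets with the affinity oracle and keep
# targets strictly above the pIC50 cutoff for the query AND for at
# least one supporting neighbour, (3) intersect the survivors with the
# disease phenotype table through the accession-to-gene cross-reference.

#' InteractionDataset: drugs, targets and drug-target edges
#'
#' @slot drugs data frame with columns `drug_id`, `smiles`, `canonical`.
#' @slot targets data frame with columns `accession`, `sequence`.
#' @slot edges data frame with columns `drug_id`, `accession`.
#' @export
setClass("InteractionDataset",
         representation(drugs = "data.frame", targets = "data.frame",
                        edges = "data.frame"))

setValidity("InteractionDataset", function(object) {
  d <- object@drugs; t <- object@targets; e <- object@edges
  if (!all(c("drug_id", "smiles", "canonical") %in% names(d)))
    return("drugs needs drug_id/smiles/canonical")
  if (!all(c("accession", "sequence") %in% names(t)))
    return("targets needs accession/sequence")
  if (!all(c("drug_id", "accession") %in% names(e)))
    return("edges needs drug_id/accession")
  if (anyDuplicated(d$drug_id)) return("duplicate drug ids")
  if (anyDuplicated(t$accession)) return("duplicate target accessions")
  if (nrow(e)) {
    if (!all(e$drug_id %in% d$drug_id))
      return("edge references unknown drug id")
    if (!all(e$accession %in% t$accession))
      return("edge references unknown target accession")
  }
  TRUE
})

#' Construct an InteractionDataset
#'
#' @param drugs data frame with `drug_id` and `smiles` (canonical forms
#'   are computed; unparseable SMILES raise an error naming the drug).
#' @param targets data frame with `accession` and `sequence`.
#' @param edges data frame with `drug_id` and `accession`.
#' @return an [InteractionDataset-class].
#' @export
interactionDataset <- function(drugs, targets, edges) {
  drugs <- as.data.frame(drugs); targets <- as.data.frame(targets)
  edges <- as.data.frame(edges)
  if (is.null(drugs$canonical)) {
    can <- .obCanonical(drugs$smiles)
    if (anyNA(can))
      stop("unparseable SMILES for drug(s): ",
           paste(drugs$drug_id[is.na(can)], collapse = ", "))
    drugs$canonical <- can
  }
  new("InteractionDataset",
      drugs = drugs[, c("drug_id", "smiles", "canonical")],
      targets = targets[, c("accession", "sequence")],
      edges = edges[, c("drug_id", "accession")])
}

#' @describeIn InteractionDataset-class drug table accessor.
#' @param x an `InteractionDataset`.
#' @export
drugTable <- function(x) x@drugs

#' @describeIn InteractionDataset-class target table accessor.
#' @export
targetTable <- function(x) x@targets

#' @describeIn InteractionDataset-class edge table accessor.
#' @export
edgeTable <- function(x) x@edges

setMethod("show", "InteractionDataset", function(object) {
  cat("InteractionDataset:", nrow(object@drugs), "drugs,",
      nrow(object@targets), "targets,", nrow(object@edges), "edges\n")
  invisible(object)
})

#' DiseaseTable: gene-phenotype associations plus accession cross-reference
#'
#' @slot associations data frame with columns `gene_symbol`, `phenotype`.
#' @slot xref data frame with columns `accession`, `gene_symbol`
#'   (one gene symbol per accession).
#' @export
setClass("DiseaseTable",
         representation(associations = "data.frame", xref = "data.frame"))

setValidity("DiseaseTable", function(object) {
  if (!all(c("gene_symbol", "phenotype") %in% names(object@associations)))
    return("associations needs gene_symbol/phenotype")
  if (!all(c("accession", "gene_symbol") %in% names(object@xref)))
    return("xref needs accession/gene_symbol")
  if (anyDuplicated(object@xref$accession))
    return("xref must map each accession to one gene symbol")
  TRUE
})

#' Construct a DiseaseTable
#' @param associations data frame of `gene_symbol`, `phenotype`.
#' @param xref data frame of `accession`, `gene_symbol`.
#' @return a [DiseaseTable-class].
#' @export
diseaseTable <- function(associations, xref) {
  new("DiseaseTable", associations = as.data.frame(associations),
      xref = as.data.frame(xref))
}

setMethod("show", "DiseaseTable", function(object) {
  cat("DiseaseTable:", nrow(object@associations), "gene-phenotype rows,",
      nrow(object@xref), "accession cross-references\n")
  invisible(object)
})

#' PipelineConfig: thresholds for the identification stage
#'
#' Defaults follow the workflow's published cutoffs: average-fingerprint
#' similarity strictly above 0.4 and pIC50 strictly above 4.0.
#'
#' @slot similarityThreshold average-Tanimoto threshold (strict).
#' @slot affinityCutoff pIC50 cutoff (strict).
#' @slot phenotypeQuery case-insensitive substring matched against
#'   phenotype strings.
#' @slot supportMode `"any"` (default: at least one supporting
#'   neighbour above the cutoff) or `"all"` (every linked neighbour).
#' @slot seed integer seed recorded for reproducibility.
#' @export
setClass("PipelineConfig",
         representation(similarityThreshold = "numeric",
                        affinityCutoff = "numeric",
                        phenotypeQuery = "character",
                        supportMode = "character",
                        seed = "integer"),
         prototype(similarityThreshold = 0.4, affinityCutoff = 4.0,
                   phenotypeQuery = "Alzheimer", supportMode = "any",
                   seed = 1L))

setValidity("PipelineConfig", function(object) {
  if (!is.finite(object@similarityThreshold) ||
      !is.finite(object@affinityCutoff))
    return("thresholds must be finite")
  if (!object@supportMode %in% c("any", "all"))
    return("supportMode must be 'any' or 'all'")
  TRUE
})

#' @rdname PipelineConfig-class
#' @param similarityThreshold,affinityCutoff,phenotypeQuery,supportMode,seed
#'   see slots.
#' @export
pipelineConfig <- function(similarityThreshold = 0.4, affinityCutoff = 4.0,
                           phenotypeQuery = "Alzheimer",
                           supportMode = c("any", "all"), seed = 1L) {
  new("PipelineConfig", similarityThreshold = similarityThreshold,
      affinityCutoff = affinityCutoff, phenotypeQuery = phenotypeQuery,
      supportMode = match.arg(supportMode), seed = as.integer(seed))
}

#' Find query-like drugs in the library
#'
#' Screens every drug for average Morgan/MACCS Tanimoto similarity to
#' the query strictly above the threshold. The query itself, when
#' present in the library, is excluded by canonical-structure match.
#'
#' @param query a [Molecule-class].
#' @param ds an [InteractionDataset-class].
#' @param threshold strict lower similarity bound (default 0.4).
#' @return data frame of `drug_id`, `similarity`, sorted by descending
#'   similarity (ties broken by drug id for reproducibility).
#' @export
findSimilarDrugs <- function(query, ds, threshold = 0.4) {
  stopifnot(is(query, "Molecule"), is(ds, "InteractionDataset"))
  d <- ds@drugs
  if (!nrow(d))
    return(data.frame(drug_id = character(0), similarity = numeric(0)))
  sim <- .avgTanimotoBatch(d$canonical, canonicalSmiles(query))[, "avg"]
  keep <- sim > threshold & d$canonical != canonicalSmiles(query)
  out <- data.frame(drug_id = d$drug_id[keep], similarity = sim[keep])
  out[order(-out$similarity, out$drug_id), , drop = FALSE]
}

#' Candidate targets of the similar drugs
#'
#' The union of targets linked by an interaction edge to any of the
#' similar drugs.
#' @param similar data frame from [findSimilarDrugs()] (or a character
#'   vector of drug ids).
#' @param ds an [InteractionDataset-class].
#' @return sorted character vector of target accessions.
#' @export
collectCandidateTargets <- function(similar, ds) {
  stopifnot(is(ds, "InteractionDataset"))
  ids <- if (is.data.frame(similar)) similar$drug_id else similar
  sort(unique(ds@edges$accession[ds@edges$drug_id %in% ids]))
}

#' Filter candidate targets by oracle affinity
#'
#' Retains a candidate target iff the query scores strictly above the
#' cutoff against it AND (depending on `supportMode`) one or all of the
#' similar drugs linked to it do too. Both scores are recorded as
#' machine-checkable evidence.
#'
#' @param query a [Molecule-class].
#' @param candidates character vector of candidate accessions.
#' @param similar data frame from [findSimilarDrugs()].
#' @param ds an [InteractionDataset-class].
#' @param oracle affinity oracle function, see [surrogateAffinity()].
#' @param cutoff strict pIC50 cutoff (default 4.0).
#' @param supportMode `"any"` or `"all"` supporting drugs above cutoff.
#' @return data frame of `accession`, `pic50_query`, `best_support_drug`,
#'   `best_support_similarity`, `best_support_pic50`, `n_support`,
#'   ordered by descending `pic50_query` then accession.
#' @export
filterByAffinity <- function(query, candidates, similar, ds, oracle,
                             cutoff = 4.0, supportMode = c("any", "all")) {
  stopifnot(is(query, "Molecule"), is(ds, "InteractionDataset"),
            is.function(oracle))
  supportMode <- match.arg(supportMode)
  qsmi <- canonicalSmiles(query)
  targets <- ds@targets
  drugs <- ds@drugs
  simTab <- if (is.data.frame(similar)) similar else
    data.frame(drug_id = similar, similarity = NA_real_)
  rows <- list()
  for (acc in candidates) {
    seq <- targets$sequence[match(acc, targets$accession)]
    pq <- tryCatch(oracle(qsmi, acc, seq), error = function(e)
      stop("affinity oracle failed for pair (query, ", acc, "): ",
           conditionMessage(e), call. = FALSE))
    if (!is.finite(pq))
      stop("affinity oracle returned a non-finite score for (query, ",
           acc, ")")
    if (pq <= cutoff) next
    linked <- ds@edges$drug_id[ds@edges$accession == acc]
    linked <- simTab[simTab$drug_id %in% linked, , drop = FALSE]
    if (!nrow(linked)) next
    ps <- vapply(seq_len(nrow(linked)), function(i) {
      smi <- drugs$canonical[match(linked$drug_id[i], drugs$drug_id)]
      tryCatch(oracle(smi, acc, seq), error = function(e)
        stop("affinity oracle failed for pair (", linked$drug_id[i],
             ", ", acc, "): ", conditionMessage(e), call. = FALSE))
    }, numeric(1))
    ok <- if (supportMode == "any") any(ps > cutoff) else all(ps > cutoff)
    if (!ok) next
    best <- which.max(ps)
    rows[[acc]] <- data.frame(
      accession = acc, pic50_query = pq,
      best_support_drug = linked$drug_id[best],
      best_support_similarity = linked$similarity[best],
      best_support_pic50 = ps[best],
      n_support = sum(ps > cutoff))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), pic50_query = numeric(0),
               best_support_drug = character(0),
               best_support_similarity = numeric(0),
               best_support_pic50 = numeric(0), n_support = integer(0))
  rownames(out) <- NULL
  out[order(-out$pic50_query, out$accession), , drop = FALSE]
}

#' Intersect affinity-positive targets with a disease phenotype
#'
#' A target matches when its accession maps through the cross-reference
#' to a gene symbol with at least one phenotype containing the query
#' string (case-insensitive substring). Accessions absent from the
#' cross-reference are treated as unmatched. Only matched candidates
#' are returned.
#'
#' @param cands data frame from [filterByAffinity()].
#' @param dt a [DiseaseTable-class].
#' @param phenotypeQuery substring to match (default `"Alzheimer"`).
#' @return `cands` restricted to matched rows, with `gene_symbol` and
#'   `phenotype` evidence columns appended.
#' @export
mapToDisease <- function(cands, dt, phenotypeQuery = "Alzheimer") {
  stopifnot(is(dt, "DiseaseTable"))
  gene <- dt@xref$gene_symbol[match(cands$accession, dt@xref$accession)]
  assoc <- dt@associations
  hit <- grepl(phenotypeQuery, assoc$phenotype, ignore.case = TRUE)
  phenoFor <- function(g) {
    if (is.na(g)) return(NA_character_)
    p <- assoc$phenotype[hit & assoc$gene_symbol == g]
    if (length(p)) p[1L] else NA_character_
  }
  pheno <- vapply(gene, phenoFor, "")
  keep <- !is.na(pheno)
  out <- cands[keep, , drop = FALSE]
  out$gene_symbol <- gene[keep]
  out$phenotype <- pheno[keep]
  rownames(out) <- NULL
  out
}

#' Run the full three-step target identification
#'
#' Similarity screen, affinity filter, disease intersection. The result
#' is deterministic for a given dataset, oracle and configuration.
#'
#' @param query a [Molecule-class] (or SMILES string) for the query
#'   ligand.
#' @param ds an [InteractionDataset-class].
#' @param dt a [DiseaseTable-class].
#' @param oracle affinity oracle function.
#' @param config a [PipelineConfig-class].
#' @return data frame with one row per identified target: accession,
#'   gene symbol, query pIC50, best supporting drug with its similarity
#'   and pIC50, and the phenotype evidence; ordered by descending query
#'   pIC50 then accession.
#' @seealso [writeTargetReport()]
#' @export
runTargetIdentification <- function(query, ds, dt, oracle,
                                    config = pipelineConfig()) {
  if (is.character(query)) query <- parseSmiles(query)
  stopifnot(is(query, "Molecule"), is(config, "PipelineConfig"))
  similar <- findSimilarDrugs(query, ds, config@similarityThreshold)
  cands <- collectCandidateTargets(similar, ds)
  aff <- filterByAffinity(query, cands, similar, ds, oracle,
                          cutoff = config@affinityCutoff,
                          supportMode = config@supportMode)
  out <- mapToDisease(aff, dt, config@phenotypeQuery)
  out[, c("accession", "gene_symbol", "pic50_query", "best_support_drug",
          "best_support_similarity", "best_support_pic50", "n_support",
          "phenotype")]
}

#' Write the identification report as TSV
#'
#' Numeric evidence is printed at four decimals; rows keep the
#' deterministic ordering of [runTargetIdentification()], so identical
#' runs produce byte-identical files.
#' @param report data frame from [runTargetIdentification()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTargetReport <- function(report, path) {
  fmt <- report
  for (v in c("pic50_query", "best_support_similarity", "best_support_pic50"))
    fmt[[v]] <- sprintf("%.4f", report[[v]])
  lines <- c(paste(names(fmt), collapse = "\t"),
             if (nrow(fmt)) do.call(paste,
                                    c(unname(as.list(fmt)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
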