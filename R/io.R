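# File-format plumbing for the identification stage.
#
# Formats: .smi (one "SMILES<whitespace>identifier" per line), FASTA
# (60-column wrap, accession as record id; via Biostrings), and
# tab-separated tables with header rows. Readers fail with the file
# name and line number of the first malformed record.

.readTsvChecked <- function(path, columns) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty table (missing header): ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(columns %in% header))
    stop(path, ":1: header must contain columns ",
         paste(columns, collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop(path, ":", bad[1L] + 1L, ": expected ", length(header),
         " tab-separated fields")
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  if (!length(body))
    out <- as.data.frame(matrix(character(0), 0L, length(header)),
                         stringsAsFactors = FALSE)
  names(out) <- header
  out[, columns, drop = FALSE]
}

#' Read a SMILES (.smi) drug library
#'
#' @param path .smi file: one `SMILES<whitespace>identifier` per line.
#' @return data frame of `drug_id`, `smiles`.
#' @export
readDrugLibrary <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(f) < 2L)
  if (length(bad))
    stop(path, ":", bad[1L], ": expected 'SMILES identifier'")
  data.frame(drug_id = vapply(f, `[`, "", 2L),
             smiles = vapply(f, `[`, "", 1L))
}

#' @rdname readDrugLibrary
#' @param drugs data frame with `drug_id` and `smiles`.
#' @export
writeDrugLibrary <- function(drugs, path) {
  writeLines(sprintf("%s %s", drugs$smiles, drugs$drug_id), path)
  invisible(path)
}

#' Read target protein sequences from FASTA
#'
#' @param path FASTA file; record ids are target accessions.
#' @return data frame of `accession`, `sequence`.
#' @export
readTargetSequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  data.frame(accession = unname(vapply(strsplit(names(aa), "[ \t]"), `[`, "", 1L)),
             sequence = unname(as.character(aa)))
}

#' @rdname readTargetSequences
#' @param targets data frame with `accession` and `sequence`.
#' @export
writeTargetSequences <- function(targets, path) {
  aa <- Biostrings::AAStringSet(targets$sequence)
  names(aa) <- targets$accession
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read an interaction-dataset directory
#'
#' Expects `drugs.smi`, `targets.fasta` and `interactions.tsv` (columns
#' `drug_id`, `accession`).
#' @param dir directory path.
#' @return an [InteractionDataset-class].
#' @export
readInteractionDataset <- function(dir) {
  drugs <- readDrugLibrary(file.path(dir, "drugs.smi"))
  targets <- readTargetSequences(file.path(dir, "targets.fasta"))
  edges <- .readTsvChecked(file.path(dir, "interactions.tsv"),
                           c("drug_id", "accession"))
  interactionDataset(drugs, targets, edges)
}

#' Read disease and cross-reference tables
#'
#' Expects `disease.tsv` (columns `gene_symbol`, `phenotype`) and
#' `xref.tsv` (columns `accession`, `gene_symbol`).
#' @param dir directory path.
#' @return a [DiseaseTable-class].
#' @export
readDiseaseTable <- function(dir) {
  assoc <- .readTsvChecked(file.path(dir, "disease.tsv"),
                           c("gene_symbol", "phenotype"))
  xref <- .readTsvChecked(file.path(dir, "xref.tsv"),
                          c("accession", "gene_symbol"))
  diseaseTable(assoc, xref)
}

.writeTsv <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a surrogate-oracle specification
#'
#' Serialized as YAML carrying the seed, affinity baseline and effect,
#' the planted target accessions and the feature molecule's SMILES (the
#' feature fingerprint is recomputed on read).
#' @param spec a [SurrogateSpec-class].
#' @param featureSmiles SMILES whose Morgan fingerprint is the planted
#'   feature set (required when any targets are planted).
#' @param path output file.
#' @return `path` (write) / a [SurrogateSpec-class] (read).
#' @export
writeOracleSpec <- function(spec, featureSmiles, path) {
  stopifnot(is(spec, "SurrogateSpec"))
  yaml::write_yaml(list(
    oracle = "surrogate",
    seed = spec@seed, baseline = spec@baseline, effect = spec@effect,
    feature_smiles = featureSmiles,
    planted_targets = as.list(names(spec@plantedFeatures))), path)
  invisible(path)
}

#' @rdname writeOracleSpec
#' @export
readOracleSpec <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  y <- yaml::read_yaml(path)
  planted <- unlist(y$planted_targets)
  surrogateSpec(seed = y$seed, baseline = y$baseline, effect = y$effect,
                plantedTargets = if (is.null(planted)) character(0) else planted,
                featureMolecule = if (length(planted))
                  parseSmiles(y$feature_smiles) else NULL)
}
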