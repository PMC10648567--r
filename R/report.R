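# Report rendering and run manifests.

#' Render the analog report as TSV text
#'
#' One row per hall-of-fame analog, mirroring the property-table layout
#' of the optimization stage's published summaries: `No.`, `QED`,
#' `SAScore`, `plogP`, `logP`, a combined `Filters` verdict and the
#' docking score, with numbers rounded to two decimals. A companion
#' `SMILES` column carries the structure.
#' @param hall a [HallOfFame-class].
#' @return character vector of TSV lines (header first).
#' @export
renderAnalogReport <- function(hall) {
  stopifnot(is(hall, "HallOfFame"))
  header <- paste(c("No.", "QED", "SAScore", "plogP", "logP",
                    "Filters(PAINS, BRENK, NIH, ZINC)",
                    "DockingScore", "SMILES"), collapse = "\t")
  if (!length(hall)) return(header)
  tab <- hallOfFameTable(hall)
  rows <- sprintf("No.%d\t%.2f\t%.2f\t%.2f\t%.2f\t%s\t%.2f\t%s",
                  seq_len(nrow(tab)), tab$qed, tab$sascore, tab$plogp,
                  tab$logp, ifelse(tab$filters_pass, "Pass", "Fail"),
                  tab$docking, tab$smiles)
  c(header, rows)
}

#' @rdname renderAnalogReport
#' @param path output TSV path; a companion `.smi` file (same stem) is
#'   written with one `SMILES No.<i>` record per analog.
#' @return `path`, invisibly.
#' @export
writeAnalogReport <- function(hall, path) {
  writeLines(renderAnalogReport(hall), path)
  if (length(hall)) {
    tab <- hallOfFameTable(hall)
    smiPath <- paste0(sub("\\.tsv$", "", path), ".smi")
    writeLines(sprintf("%s No.%d", tab$smiles, seq_len(nrow(tab))), smiPath)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, input-file checksums, seed,
#' package version and timestamp of an artifact-producing run --
#' everything needed to reproduce it.
#' @param path output YAML path.
#' @param command name of the command that ran.
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths (checksummed).
#' @param outputs character vector of output file paths.
#' @param seed integer seed used.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, command, config = list(),
                             inputs = character(0),
                             outputs = character(0), seed = NA_integer_) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  yaml::write_yaml(list(
    command = command,
    package = "targan",
    version = as.character(utils::packageVersion("targan")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = sums,
    outputs = as.list(outputs)), path)
  invisible(path)
}
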