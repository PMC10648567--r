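# Structural-alert filters: PAINS, Brenk, NIH and ZINC SMARTS catalogs.
#
# The shipped catalogs are curated representative subsets of the public
# alert collections (see inst/extdata/alerts/*.smarts); a molecule
# passes a catalog when no alert in it matches.

.alertCatalogVersion <- "targan-2026.09"

.alertCatalogNames <- c("pains", "brenk", "nih", "zinc")

#' Load the structural-alert catalogs
#'
#' Reads the four SMARTS alert catalogs shipped with the package (or a
#' drop-in replacement directory with the same file layout).
#'
#' @param dir directory holding `pains_subset.smarts`,
#'   `brenk_subset.smarts`, `nih_subset.smarts`, `zinc_subset.smarts`;
#'   defaults to the package's own copies.
#' @return named list of data frames with columns `smarts`, `name`, plus
#'   a `version` attribute.
#' @export
loadAlertCatalogs <- function(dir = NULL) {
  if (is.null(dir)) {
    cached <- .targanEnv$alertCatalogs
    if (!is.null(cached)) return(cached)
    dir <- system.file("extdata", "alerts", package = "targan",
                       mustWork = TRUE)
  }
  out <- list()
  for (cat in .alertCatalogNames) {
    path <- file.path(dir, paste0(cat, "_subset.smarts"))
    if (!file.exists(path))
      stop("alert catalog file missing: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) != 2L))
      stop("malformed alert catalog (expected SMARTS<TAB>name): ", path)
    out[[cat]] <- data.frame(smarts = vapply(f, `[`, "", 1L),
                             name = vapply(f, `[`, "", 2L))
  }
  attr(out, "version") <- .alertCatalogVersion
  if (is.null(.targanEnv$alertCatalogs) &&
      identical(dir, system.file("extdata", "alerts", package = "targan")))
    .targanEnv$alertCatalogs <- out
  out
}

#' FilterReport: structural-alert verdicts for one molecule
#'
#' @slot matches named list (pains/brenk/nih/zinc) of matched alert
#'   names, possibly empty.
#' @slot overallPass `TRUE` iff all four catalogs matched zero alerts.
#' @slot catalogVersion version string of the catalogs used.
#' @export
setClass("FilterReport",
         representation(matches = "list", overallPass = "logical",
                        catalogVersion = "character"))

setValidity("FilterReport", function(object) {
  if (!identical(sort(names(object@matches)), sort(.alertCatalogNames)))
    return("matches must cover the four catalogs")
  consistent <- object@overallPass == !any(lengths(object@matches) > 0L)
  if (!consistent) return("overallPass inconsistent with matches")
  TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport (catalogs ", object@catalogVersion, "): ",
      if (object@overallPass) "Pass" else "Fail", "\n", sep = "")
  for (cat in .alertCatalogNames) {
    hits <- object@matches[[cat]]
    cat(sprintf("  %-5s: %s\n", cat,
                if (length(hits)) paste(hits, collapse = ", ") else "clean"))
  }
  invisible(object)
})

#' @describeIn FilterReport-class catalog-wise pass verdicts.
#' @param x a `FilterReport`.
#' @export
filterVerdicts <- function(x) {
  stopifnot(is(x, "FilterReport"))
  vapply(x@matches, function(h) length(h) == 0L, logical(1))
}

#' @describeIn FilterReport-class overall verdict.
#' @export
overallPass <- function(x) x@overallPass

# Batch matcher: canonical SMILES vector -> logical matrix of matched
# alerts, organised as list(catalog -> matrix [mol x alert]).
.alertMatchBatch <- function(canSmiles, catalogs = loadAlertCatalogs()) {
  refs <- .obMolRefs(canSmiles)
  out <- list()
  for (cat in .alertCatalogNames) {
    tab <- catalogs[[cat]]
    m <- matrix(FALSE, length(canSmiles), nrow(tab),
                dimnames = list(NULL, tab$name))
    for (j in seq_len(nrow(tab))) {
      m[, j] <- .obSmartsCount(refs, tab$smarts[j]) > 0L
    }
    out[[cat]] <- m
  }
  out
}

#' Run the structural-alert filters on a molecule
#'
#' Matches the molecule against the PAINS, Brenk, NIH and ZINC alert
#' catalogs. A molecule passes when no alert in any catalog matches.
#'
#' @param m a [Molecule-class].
#' @param catalogs catalogs as returned by [loadAlertCatalogs()].
#' @return a [FilterReport-class].
#' @examples
#' overallPass(runFilters(parseSmiles("CCC")))   # propane: clean
#' @export
runFilters <- function(m, catalogs = loadAlertCatalogs()) {
  stopifnot(is(m, "Molecule"))
  hits <- .alertMatchBatch(canonicalSmiles(m), catalogs)
  matches <- lapply(hits, function(h) colnames(h)[h[1L, ]])
  new("FilterReport", matches = matches,
      overallPass = !any(lengths(matches) > 0L),
      catalogVersion = attr(catalogs, "version"))
}
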