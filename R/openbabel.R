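# Thin, batched bridge to OpenBabel through ChemmineOB.
#
# All calls are batch-oriented: OpenBabel conversions carry per-record
# titles so that records it silently drops (unparseable SMILES) can be
# realigned with their inputs instead of shifting the batch.

.targanEnv <- new.env(parent = emptyenv())

.obCache <- function() {
  if (is.null(.targanEnv$cache)) .targanEnv$cache <- new.env(parent = emptyenv())
  .targanEnv$cache
}

#' Clear targan's internal molecule cache
#'
#' Fingerprints, property profiles and filter verdicts are memoised by
#' canonical SMILES for the lifetime of the session. The cache is purely
#' an optimisation; results never depend on its state.
#' @return Invisibly, `NULL`.
#' @export
clearMoleculeCache <- function() {
  .targanEnv$cache <- new.env(parent = emptyenv())
  invisible(NULL)
}

.cacheGet <- function(key) {
  ca <- .obCache()
  if (exists(key, envir = ca, inherits = FALSE)) get(key, envir = ca) else NULL
}

.cacheSet <- function(key, value) {
  assign(key, value, envir = .obCache())
  value
}

.quietly <- function(expr) {
  # OpenBabel chats on stderr for every perception pass; silence it but
  # keep R-level errors.
  withCallingHandlers(
    suppressWarnings(suppressMessages(expr)),
    message = function(m) invokeRestart("muffleMessage"))
}

# Canonical SMILES for a character vector; NA where OpenBabel refuses to
# parse. Titles key the realignment.
.obCanonical <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  bad <- !nzchar(smiles) | grepl("[\t\n]", smiles)
  out <- rep(NA_character_, length(smiles))
  todo <- which(!bad)
  if (length(todo)) {
    input <- paste(sprintf("%s nr%d", smiles[todo], todo), collapse = "\n")
    res <- .quietly(ChemmineOB::convertFormat("SMI", "CAN", input))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) >= 2L && grepl("^nr[0-9]+$", f[2L])) {
        i <- as.integer(sub("^nr", "", f[2L]))
        out[i] <- f[1L]
      }
    }
  }
  out
}

# SMILES -> list of graphs (NULL where unparseable), via kekulized SDF.
.obGraphs <- function(smiles) {
  if (!length(smiles)) return(list())
  out <- vector("list", length(smiles))
  ok <- nzchar(smiles) & !grepl("[\t\n]", smiles) & !is.na(smiles)
  todo <- which(ok)
  if (!length(todo)) return(out)
  input <- paste(sprintf("%s nr%d", smiles[todo], todo), collapse = "\n")
  sdftxt <- .quietly(ChemmineOB::convertFormat("SMI", "SDF", input))
  blocks <- strsplit(sdftxt, "\\$\\$\\$\\$\n")[[1]]
  for (blk in blocks) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    if (length(lines) < 4L) next
    title <- trimws(lines[1L])
    if (!grepl("^nr[0-9]+$", title)) next
    i <- as.integer(sub("^nr", "", title))
    g <- tryCatch(.parseMolblock(lines), error = function(e) NULL)
    out[[i]] <- g
  }
  out
}

# Graphs -> canonical SMILES (NA on failure), batched through one SDF.
.obCanonicalFromGraphs <- function(graphs) {
  if (!length(graphs)) return(character(0))
  out <- rep(NA_character_, length(graphs))
  txt <- character(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (is.null(g) || .graphNAtoms(g) == 0L) next
    txt <- c(txt, .writeMolblock(g, title = sprintf("nr%d", i)))
  }
  if (!length(txt)) return(out)
  res <- .quietly(ChemmineOB::convertFormat("SDF", "CAN",
                                            paste0(paste(txt, collapse = "\n"), "\n")))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) >= 2L && grepl("^nr[0-9]+$", f[2L])) {
      out[as.integer(sub("^nr", "", f[2L]))] <- f[1L]
    }
  }
  out
}

# OpenBabel molecule references for known-good SMILES (one batch).
.obMolRefs <- function(smiles) {
  if (!length(smiles)) return(list())
  .quietly(ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                  identity))
}

# Fingerprint matrix for known-good SMILES. type: "ECFP4" or "MACCS".
# ECFP4 (Morgan radius 2) is folded from OpenBabel's 4096 bits to 2048;
# MACCS is truncated to its 166 keys.
.obFingerprints <- function(smiles, type = c("ECFP4", "MACCS")) {
  type <- match.arg(type)
  keyp <- if (type == "ECFP4") "fpM|" else "fpK|"
  width <- if (type == "ECFP4") 2048L else 166L
  out <- matrix(FALSE, length(smiles), width)
  need <- integer(0)
  for (i in seq_along(smiles)) {
    hit <- .cacheGet(paste0(keyp, smiles[i]))
    if (is.null(hit)) need <- c(need, i) else out[i, ] <- hit
  }
  if (length(need)) {
    uniq <- unique(smiles[need])
    refs <- .obMolRefs(uniq)
    fp <- .quietly(ChemmineOB::fingerprint_OB(refs, type))
    fp <- matrix(as.logical(fp), nrow = length(uniq))
    if (type == "ECFP4") {
      fp <- fp[, 1:2048, drop = FALSE] | fp[, 2049:4096, drop = FALSE]
    } else {
      fp <- fp[, 1:166, drop = FALSE]
    }
    rownames(fp) <- uniq
    for (u in uniq) .cacheSet(paste0(keyp, u), fp[u, ])
    for (i in need) out[i, ] <- fp[smiles[i], ]
  }
  out
}

# Unique (per-occurrence) SMARTS match counts over a batch of molrefs.
.obSmartsCount <- function(molRefs, smarts, uniqueMatches = TRUE) {
  res <- tryCatch(
    .quietly(ChemmineOB::smartsSearch_OB(molRefs, smarts,
                                         uniqueMatches = uniqueMatches)),
    error = function(e) stop("SMARTS pattern rejected by OpenBabel: ",
                             smarts, call. = FALSE))
  as.integer(res)
}

.obProps <- function(smiles) {
  refs <- .obMolRefs(smiles)
  p <- .quietly(ChemmineOB::prop_OB(refs))
  p
}
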