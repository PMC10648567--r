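# Internal molecular-graph layer.
#
# Molecules are held as plain kekulized graphs: element symbols, formal
# charges and an explicit bond list with integer orders. Hydrogens are
# implicit throughout; stereochemistry is not modelled. OpenBabel (via
# ChemmineOB) is the authority for SMILES parsing and canonicalization;
# this layer only carries the connectivity needed by the scaffold,
# ring-penalty and GA edit machinery.

# graph := list(elem = character(n), charge = integer(n),
#               bonds = integer matrix [m x 3] (a1, a2, order))

.emptyGraph <- function() {
  list(elem = character(0), charge = integer(0),
       bonds = matrix(integer(0), ncol = 3L,
                      dimnames = list(NULL, c("a1", "a2", "order"))))
}

.graphNAtoms <- function(g) length(g$elem)
.graphNBonds <- function(g) nrow(g$bonds)

# Parse one V2000 molblock (character vector of lines) into a graph.
.parseMolblock <- function(lines) {
  if (length(lines) < 4L) stop("molblock too short")
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L) stop("molblock with no atoms")
  atomLines <- lines[5L:(4L + na)]
  elem <- trimws(substr(atomLines, 32L, 34L))
  charge <- integer(na)
  bonds <- matrix(integer(0), ncol = 3L)
  if (nb > 0L) {
    bondLines <- lines[(5L + na):(4L + na + nb)]
    bonds <- cbind(as.integer(substr(bondLines, 1L, 3L)),
                   as.integer(substr(bondLines, 4L, 6L)),
                   as.integer(substr(bondLines, 7L, 9L)))
  }
  # formal charges live in M  CHG property lines
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1]])
    nent <- f[1L]
    for (i in seq_len(nent)) {
      charge[f[2L * i]] <- f[2L * i + 1L]
    }
  }
  colnames(bonds) <- c("a1", "a2", "order")
  list(elem = elem, charge = charge, bonds = bonds)
}

# Serialize a graph to a V2000 molblock (no coordinates, no stereo).
.writeMolblock <- function(g, title = "") {
  na <- .graphNAtoms(g)
  nb <- .graphNBonds(g)
  out <- c(title, " targan", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  out <- c(out, sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    g$elem))
  if (nb > 0L) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          g$bonds[, 1L], g$bonds[, 2L], g$bonds[, 3L]))
  }
  chg <- which(g$charge != 0L)
  if (length(chg)) {
    # at most 8 entries per M  CHG line
    for (i in split(chg, ceiling(seq_along(chg) / 8L))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(i)),
                           paste0(sprintf("%4d%4d", i, g$charge[i]),
                                  collapse = "")))
    }
  }
  c(out, "M  END", "$$$$")
}

.adjacency <- function(g) {
  n <- .graphNAtoms(g)
  adj <- vector("list", n)
  if (.graphNBonds(g) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1L]; j <- g$bonds[b, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

.componentsOf <- function(g) {
  n <- .graphNAtoms(g)
  adj <- .adjacency(g)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- k; queue <- c(queue, w) }
    }
  }
  comp
}

# BFS shortest path length from u to v, optionally ignoring one bond row.
.bfsDist <- function(adj, u, v, skip = NULL) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[u] <- 0L
  queue <- u
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (y in adj[[x]]) {
      if (!is.null(skip) && ((x == skip[1L] && y == skip[2L]) ||
                             (x == skip[2L] && y == skip[1L]))) next
      if (is.na(dist[y])) {
        dist[y] <- dist[x] + 1L
        if (y == v) return(dist[y])
        queue <- c(queue, y)
      }
    }
  }
  NA_integer_
}

# Ring perception. An edge lies in a ring iff it is not a bridge; the
# smallest ring through each such edge is 1 + the shortest alternative
# path between its endpoints. nRings is the cyclomatic number.
.ringInfo <- function(g) {
  n <- .graphNAtoms(g)
  m <- .graphNBonds(g)
  if (n == 0L || m == 0L) {
    return(list(nRings = 0L, ringAtoms = logical(n), ringBonds = logical(m),
                ringSizes = integer(0), largest = 0L))
  }
  adj <- .adjacency(g)
  comp <- .componentsOf(g)
  nRings <- m - n + length(unique(comp))
  ringBonds <- logical(m)
  sizes <- rep(NA_integer_, m)
  for (b in seq_len(m)) {
    u <- g$bonds[b, 1L]; v <- g$bonds[b, 2L]
    d <- .bfsDist(adj, u, v, skip = c(u, v))
    if (!is.na(d)) {
      ringBonds[b] <- TRUE
      sizes[b] <- d + 1L
    }
  }
  ringAtoms <- logical(n)
  ringAtoms[as.vector(g$bonds[ringBonds, 1:2])] <- TRUE
  ringSizes <- sizes[ringBonds]
  list(nRings = as.integer(nRings), ringAtoms = ringAtoms,
       ringBonds = ringBonds, ringSizes = ringSizes,
       largest = if (length(ringSizes)) max(ringSizes) else 0L)
}

# Murcko framework atom set: iteratively prune terminal atoms, then put
# back atoms attached to the framework by a double or triple bond.
.murckoKeepSet <- function(g) {
  n <- .graphNAtoms(g)
  if (n == 0L) return(logical(0))
  keep <- rep(TRUE, n)
  if (.graphNBonds(g) == 0L) return(rep(FALSE, n))
  repeat {
    deg <- integer(n)
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1L]; j <- g$bonds[b, 2L]
      if (keep[i] && keep[j]) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (any(keep)) {
    for (b in seq_len(nrow(g$bonds))) {
      if (g$bonds[b, 3L] >= 2L) {
        i <- g$bonds[b, 1L]; j <- g$bonds[b, 2L]
        if (keep[i] && !keep[j]) keep[j] <- TRUE
        else if (keep[j] && !keep[i]) keep[i] <- TRUE
      }
    }
  }
  keep
}

# Induced subgraph on a logical/integer atom index set; atoms renumbered,
# original indices returned as the "origin" attribute.
.inducedSubgraph <- function(g, atoms) {
  idx <- if (is.logical(atoms)) which(atoms) else sort(unique(atoms))
  map <- integer(.graphNAtoms(g))
  map[idx] <- seq_along(idx)
  keepBond <- g$bonds[, 1L] %in% idx & g$bonds[, 2L] %in% idx
  bonds <- g$bonds[keepBond, , drop = FALSE]
  if (nrow(bonds)) {
    bonds[, 1L] <- map[bonds[, 1L]]
    bonds[, 2L] <- map[bonds[, 2L]]
  }
  out <- list(elem = g$elem[idx], charge = g$charge[idx], bonds = bonds)
  attr(out, "origin") <- idx
  out
}

# Reorder atoms so that `first` (original indices) occupy positions
# 1..length(first) in the stated order.
.reorderAtoms <- function(g, first) {
  n <- .graphNAtoms(g)
  ord <- c(first, setdiff(seq_len(n), first))
  map <- integer(n)
  map[ord] <- seq_len(n)
  bonds <- g$bonds
  if (nrow(bonds)) {
    bonds[, 1L] <- map[bonds[, 1L]]
    bonds[, 2L] <- map[bonds[, 2L]]
  }
  list(elem = g$elem[ord], charge = g$charge[ord], bonds = bonds)
}

# Standard (neutral) maximum valences used by the GA edit operators.
.maxValence <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L,
                 I = 1L, P = 3L, B = 3L, Si = 4L)

.usedValence <- function(g) {
  n <- .graphNAtoms(g)
  used <- integer(n)
  if (.graphNBonds(g) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      used[g$bonds[b, 1L]] <- used[g$bonds[b, 1L]] + g$bonds[b, 3L]
      used[g$bonds[b, 2L]] <- used[g$bonds[b, 2L]] + g$bonds[b, 3L]
    }
  }
  used
}

.freeValence <- function(g) {
  mx <- .maxValence[g$elem]
  mx[is.na(mx)] <- 4L
  # a positive charge on N buys one extra bond, a negative charge on O/S
  # removes one; other charge states are left to OpenBabel's judgement
  mx <- mx + ifelse(g$elem == "N" & g$charge > 0L, 1L, 0L)
  mx <- mx - ifelse(g$charge < 0L, 1L, 0L)
  as.integer(mx) - .usedValence(g)
}

# Iterative Morgan-style environment labels for radii 0..radius. Returns
# the multiset of labels (character vector); used by the synthetic-
# accessibility fragment model.
.atomEnvironments <- function(g, radius = 2L) {
  n <- .graphNAtoms(g)
  if (n == 0L) return(character(0))
  ri <- .ringInfo(g)
  adj <- vector("list", n)
  if (.graphNBonds(g) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1L]; j <- g$bonds[b, 2L]; o <- g$bonds[b, 3L]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  lab <- sprintf("%s%d%s", g$elem, deg, ifelse(ri$ringAtoms, "R", ""))
  out <- lab
  for (r in seq_len(radius)) {
    lab2 <- character(n)
    for (i in seq_len(n)) {
      if (is.null(adj[[i]])) { lab2[i] <- lab[i]; next }
      nb <- sort(sprintf("%d:%s", adj[[i]][, 2L], lab[adj[[i]][, 1L]]))
      lab2[i] <- paste0(lab[i], "(", paste(nb, collapse = ","), ")")
    }
    lab <- lab2
    out <- c(out, lab)
  }
  out
}
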