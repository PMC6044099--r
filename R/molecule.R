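#' Molecule objects
#'
#' A `molecule` is a hydrogen-suppressed molecular graph: heavy atoms with
#' element, formal charge, Sybyl atom type, aromatic flag and implicit
#' hydrogen count, plus a bond list with orders (1, 2, 3, or 1.5 for
#' aromatic). An optional binary activity label travels with the molecule.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `element`, `charge`, `type`,
#'   `aromatic`, `n_h`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3 or 1.5
#'   for aromatic). May have zero rows.
#' @param activity one of `"active"`, `"inactive"`, `"unknown"`.
#' @return an object of class `molecule`.
#' @export
molecule <- function(id, atoms, bonds = NULL, activity = "unknown") {
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  stopifnot(nrow(atoms) >= 1L,
            all(c("element", "charge") %in% names(atoms)))
  if (is.null(atoms$type)) atoms$type <- atoms$element
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$n_h)) atoms$n_h <- 0L
  n <- nrow(atoms)
  if (any(atoms$element %in% c("H", "D", "T"))) {
    stop("molecule '", id, "': explicit hydrogens are not allowed in the ",
         "heavy-atom graph")
  }
  if (nrow(bonds)) {
    if (!all(bonds$i >= 1 & bonds$i <= n & bonds$j >= 1 & bonds$j <= n)) {
      stop("molecule '", id, "': bond endpoint out of range")
    }
    if (any(bonds$i == bonds$j)) stop("molecule '", id, "': self-bond")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("molecule '", id, "': duplicate bond")
  }
  activity <- match.arg(activity, c("unknown", "active", "inactive"))
  deg <- integer(n)
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds$i, bonds$j), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  atoms$degree <- deg
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 activity = activity),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d heavy atoms, %d bonds, activity=%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), x$activity))
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol a `molecule`.
#' @return integer heavy-atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# igraph view of the heavy-atom skeleton (used for path lengths, fragments)
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  g
}

# all-pairs shortest path lengths in bonds (Inf when disconnected)
mol_distances <- function(mol) {
  igraph::distances(mol_graph(mol))
}

# indices of bonds that lie on a cycle (ring bonds)
ring_bond_flags <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  g <- mol_graph(mol)
  vapply(seq_len(nrow(mol$bonds)), function(k) {
    g2 <- igraph::delete_edges(g, k)
    d <- igraph::distances(g2, v = mol$bonds$i[k], to = mol$bonds$j[k])
    is.finite(d[1, 1])
  }, logical(1))
}

# --- MOL2 ingestion -------------------------------------------------------

# Parse TRIPOS MOL2 text (as produced by OpenBabel with explicit hydrogens)
# into molecule objects. Hydrogens are folded into per-heavy-atom counts;
# if the heavy-atom graph is disconnected, the largest fragment is kept.
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  out <- list()
  for (s in seq_along(starts)) {
    from <- starts[s]
    to <- if (s < length(starts)) starts[s + 1] - 1L else length(lines)
    blk <- lines[from:to]
    name <- trimws(blk[2])
    counts <- as.integer(strsplit(trimws(blk[3]), "\\s+")[[1]])
    na <- counts[1]; nb <- if (length(counts) > 1) counts[2] else 0L
    a0 <- grep("^@<TRIPOS>ATOM", blk)[1]
    atom_lines <- blk[(a0 + 1):(a0 + na)]
    af <- do.call(rbind, lapply(atom_lines, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      c(f[6], f[2])
    }))
    type <- af[, 1]
    element <- vapply(seq_len(na), function(i) {
      el <- sub("\\..*$", "", type[i])
      if (el %in% c("Du", "LP", "Any")) el <- gsub("[0-9]+$", "", af[i, 2])
      el
    }, character(1))
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
    if (nb > 0) {
      b0 <- grep("^@<TRIPOS>BOND", blk)[1]
      bf <- do.call(rbind, lapply(blk[(b0 + 1):(b0 + nb)], function(l) {
        strsplit(trimws(l), "\\s+")[[1]][2:4]
      }))
      ord <- vapply(bf[, 3], function(t) {
        switch(t, "1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, 1)
      }, numeric(1), USE.NAMES = FALSE)
      bonds <- data.frame(i = as.integer(bf[, 1]), j = as.integer(bf[, 2]),
                          order = ord)
    }
    charge <- numeric(na)
    u0 <- grep("^@<TRIPOS>UNITY_ATOM_ATTR", blk)
    if (length(u0)) {
      k <- u0[1] + 1L
      while (k <= length(blk) && !grepl("^@<TRIPOS>", blk[k]) &&
             nzchar(trimws(blk[k]))) {
        hdr <- as.integer(strsplit(trimws(blk[k]), "\\s+")[[1]])
        for (j in seq_len(hdr[2])) {
          attr_f <- strsplit(trimws(blk[k + j]), "\\s+")[[1]]
          if (attr_f[1] == "charge") charge[hdr[1]] <- as.numeric(attr_f[2])
        }
        k <- k + hdr[2] + 1L
      }
    }
    out[[length(out) + 1L]] <- fold_hydrogens(
      name = name, element = element, type = type, charge = charge,
      bonds = bonds)
  }
  out
}

# collapse explicit hydrogens into per-heavy-atom counts; keep the largest
# connected fragment of the remaining heavy-atom graph
fold_hydrogens <- function(name, element, type, charge, bonds) {
  is_h <- element == "H"
  n_h <- integer(length(element))
  if (any(is_h) && nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (is_h[i] && !is_h[j]) n_h[j] <- n_h[j] + 1L
      if (is_h[j] && !is_h[i]) n_h[i] <- n_h[i] + 1L
    }
  }
  keep <- which(!is_h)
  if (!length(keep)) stop("molecule '", name, "' has no heavy atoms")
  idx <- match(seq_along(element), keep)
  hb <- bonds[!is_h[bonds$i] & !is_h[bonds$j], , drop = FALSE]
  hb$i <- idx[hb$i]; hb$j <- idx[hb$j]
  aromatic <- grepl("\\.ar$", type[keep])
  atoms <- data.frame(element = element[keep], charge = charge[keep],
                      type = type[keep], aromatic = aromatic,
                      n_h = n_h[keep], stringsAsFactors = FALSE)
  # largest fragment
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  if (nrow(hb)) g <- igraph::add_edges(g, rbind(hb$i, hb$j))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    big <- which.max(comp$csize)
    keep2 <- which(comp$membership == big)
    ws_log("molecule '", name, "': kept largest fragment (",
           length(keep2), " of ", nrow(atoms), " heavy atoms)")
    idx2 <- match(seq_len(nrow(atoms)), keep2)
    hb <- hb[!is.na(idx2[hb$i]) & !is.na(idx2[hb$j]), , drop = FALSE]
    hb$i <- idx2[hb$i]; hb$j <- idx2[hb$j]
    atoms <- atoms[keep2, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  molecule(id = name, atoms = atoms, bonds = hb)
}
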