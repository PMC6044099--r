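atomic_masses <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007,
                   O = 15.999, F = 18.998, Si = 28.086, P = 30.974,
                   S = 32.06, Cl = 35.453, Se = 78.971, Br = 79.904,
                   I = 126.904)

#' Names of the 8 simple-property descriptors
#' @return character vector of length 8.
#' @export
property_names <- function() {
  c("MW", "LOGP", "TPSA", "HBD", "HBA", "ROTB", "AROM_RINGS", "HEAVY_ATOMS")
}

# coarse polar-surface-area contribution for one N/O atom
tpsa_contrib <- function(element, aromatic, n_h, type, charge) {
  if (element == "O") {
    if (aromatic) return(13.14)
    if (type %in% c("O.2", "O.co2")) return(17.07)
    if (n_h >= 1) return(20.23)
    return(9.23)
  }
  if (element == "N") {
    if (charge > 0 || type == "N.4") return(if (n_h > 0) 27.64 else 0.00)
    if (aromatic) return(if (n_h >= 1) 15.79 else 12.89)
    if (n_h >= 2) return(26.02)
    if (n_h == 1) return(12.03)
    return(3.24)
  }
  0
}

#' Compute the 8 simple-property descriptors
#'
#' Molecular weight (implicit hydrogens included), estimated logP (sum of
#' the atomic lipophilicity increments), topological polar surface area
#' (coarse N/O contribution scheme), H-bond donor and acceptor counts,
#' rotatable bond count (acyclic single bonds between non-terminal heavy
#' atoms), aromatic ring count (cycle rank of the aromatic subgraph) and
#' heavy atom count.
#'
#' @param mol a [molecule()].
#' @param ann its [annotate()] result.
#' @return named numeric vector of length 8.
#' @export
property_block <- function(mol, ann) {
  at <- mol$atoms
  mw <- sum(atomic_masses[at$element], na.rm = TRUE) +
    sum(at$n_h) * atomic_masses[["H"]]
  logp <- sum(ann$lipophilicity)
  tpsa <- sum(vapply(seq_len(nrow(at)), function(i) {
    tpsa_contrib(at$element[i], at$aromatic[i], at$n_h[i], at$type[i],
                 at$charge[i])
  }, numeric(1)))
  hbd <- sum(vapply(ann$classes, function(cl) "donor" %in% cl, logical(1)))
  hba <- sum(vapply(ann$classes, function(cl) "acceptor" %in% cl, logical(1)))
  rotb <- 0L
  if (nrow(mol$bonds)) {
    ring <- ring_bond_flags(mol)
    deg <- at$degree
    rotb <- sum(mol$bonds$order == 1 & !ring &
                  deg[mol$bonds$i] >= 2 & deg[mol$bonds$j] >= 2)
  }
  arom <- 0L
  ab <- mol$bonds[mol$bonds$order == 1.5, , drop = FALSE]
  if (nrow(ab)) {
    verts <- unique(c(ab$i, ab$j))
    g <- igraph::graph_from_edgelist(
      cbind(match(ab$i, verts), match(ab$j, verts)), directed = FALSE)
    arom <- nrow(ab) - length(verts) + igraph::components(g)$no
  }
  stats::setNames(
    c(mw, logp, tpsa, hbd, hba, rotb, arom, n_atoms(mol)),
    property_names())
}

#' Names of the 147 pharmacophore-pair fingerprint bits
#'
#' 21 unordered pairs of the six pharmacophore classes (including
#' self-pairs) crossed with 7 topological-distance bins (shortest path
#' lengths 2, 3, 4, 5, 6, 7 and >= 8 bonds).
#'
#' @return character vector of length 147.
#' @export
fingerprint_names <- function() {
  cls <- pharmacophore_classes()
  out <- character(0)
  for (a in seq_along(cls)) for (b in a:length(cls))
    for (d in 2:8)
      out <- c(out, sprintf("FP_%s_%s_d%s", cls[a], cls[b],
                            if (d == 8) "8p" else d))
  out
}

#' Compute the 147 pharmacophore-pair fingerprint bits
#'
#' A bit is 1 iff some pair of atoms carrying the two classes lies at the
#' binned topological (shortest-path) distance. Bonded and identical atom
#' pairs (distance < 2) are not encoded.
#'
#' @param mol a [molecule()].
#' @param ann its [annotate()] result.
#' @return named integer vector of length 147 with values in \{0, 1\}.
#' @export
fingerprint_block <- function(mol, ann) {
  cls <- pharmacophore_classes()
  bits <- stats::setNames(integer(147), fingerprint_names())
  n <- n_atoms(mol)
  if (n >= 2L) {
    D <- mol_distances(mol)
    has <- vapply(cls, function(cl)
      vapply(ann$classes, function(s) cl %in% s, logical(1)),
      logical(n))
    has <- matrix(has, nrow = n)
    for (a in seq_along(cls)) for (b in a:length(cls)) {
      ia <- which(has[, a]); ib <- which(has[, b])
      if (!length(ia) || !length(ib)) next
      d <- D[ia, ib, drop = FALSE]
      d <- d[is.finite(d) & d >= 2]
      if (!length(d)) next
      for (bin in unique(pmin(d, 8))) {
        nm <- sprintf("FP_%s_%s_d%s", cls[a], cls[b],
                      if (bin == 8) "8p" else bin)
        bits[nm] <- 1L
      }
    }
  }
  bits
}

#' The full 179-column descriptor schema
#'
#' @return character vector: 24 WBN names, 8 property names, 147
#'   fingerprint names, in fixed order.
#' @export
descriptor_schema <- function() {
  c(wbn_names(), property_names(), fingerprint_names())
}

#' Compute the descriptor table for a molecule library
#'
#' One row per molecule: 24 weighted Burden numbers, 8 simple properties and
#' 147 pharmacophore-pair bits (179 columns), plus `id` and `activity`.
#' Molecules whose annotation or eigen-decomposition fails are dropped with
#' a warning.
#'
#' @param mols list of [molecule()].
#' @param tables an [atom_property_table()].
#' @return data.frame with columns `id`, `activity` and the 179 descriptors.
#' @export
descriptor_table <- function(mols, tables = atom_property_table()) {
  stopifnot(length(mols) >= 1L)
  schema <- descriptor_schema()
  rows <- vector("list", length(mols))
  failed <- character(0)
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    row <- tryCatch({
      ann <- annotate(m, tables)
      c(wbn_block(m, ann), property_block(m, ann), fingerprint_block(m, ann))
    }, error = function(e) {
      failed <<- c(failed, m$id)
      NULL
    })
    rows[[k]] <- row
  }
  if (length(failed)) {
    warning("descriptor computation failed for ", length(failed),
            " molecule(s): ", paste(failed, collapse = ", "))
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("descriptor computation failed for all molecules")
  mat <- do.call(rbind, rows[keep])
  stopifnot(identical(colnames(mat), schema))
  out <- data.frame(
    id = vapply(mols[keep], function(m) m$id, character(1)),
    activity = vapply(mols[keep], function(m) m$activity, character(1)),
    mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a descriptor table as CSV
#'
#' @param table a descriptor table ([descriptor_table()]).
#' @param path file path.
#' @return `path` (writer) / the table (reader).
#' @export
write_descriptor_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a descriptor table in attribute-relation (ARFF) text format
#'
#' @param table a descriptor table.
#' @param path file path.
#' @param relation relation name written to the header.
#' @return `path`, invisibly.
#' @export
write_arff <- function(table, path, relation = "wbnscreen") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@RELATION ", relation), con)
  num_cols <- setdiff(names(table), c("id", "activity"))
  writeLines(paste0("@ATTRIBUTE id STRING"), con)
  for (nm in num_cols) {
    writeLines(paste0("@ATTRIBUTE \"", nm, "\" NUMERIC"), con)
  }
  if ("activity" %in% names(table)) {
    writeLines("@ATTRIBUTE class {active,inactive,unknown}", con)
  }
  writeLines("@DATA", con)
  for (r in seq_len(nrow(table))) {
    vals <- c(table$id[r],
              format(unlist(table[r, num_cols]), trim = TRUE, digits = 12),
              if ("activity" %in% names(table)) table$activity[r])
    writeLines(paste(vals, collapse = ","), con)
  }
  invisible(path)
}
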