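#' Load an atomic property table
#'
#' Property tables (Pauling electronegativities per element, atomic
#' lipophilicity increments per Sybyl atom type) ship as versioned YAML so an
#' alternative scheme can be substituted without code changes.
#'
#' @param path YAML file; default is the table shipped with the package.
#' @return an object of class `atom_property_table`.
#' @export
atom_property_table <- function(path = NULL) {
  if (is.null(path)) path <- ws_extdata("atom_properties.yaml")
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$electronegativity), !is.null(y$lipophilicity))
  structure(list(
    name = y$name %||% "unnamed", version = y$version %||% "0",
    en = unlist(y$electronegativity),
    en_fallback = y$electronegativity_fallback %||% 2.0,
    lp = unlist(y$lipophilicity),
    lp_fallback = y$lipophilicity_fallback %||% 0.0
  ), class = "atom_property_table")
}

en_lookup <- function(tables, element) {
  v <- tables$en[element]
  miss <- is.na(v)
  if (any(miss)) {
    ws_log("no electronegativity entry for: ",
           paste(unique(element[miss]), collapse = ", "),
           "; using fallback ", tables$en_fallback)
    v[miss] <- tables$en_fallback
  }
  unname(v)
}

lp_lookup <- function(tables, type, element) {
  v <- tables$lp[type]
  miss <- is.na(v)
  if (any(miss)) v[miss] <- tables$lp[element[miss]]
  miss <- is.na(v)
  if (any(miss)) {
    ws_log("no lipophilicity entry for atom type(s): ",
           paste(unique(type[miss]), collapse = ", "),
           "; using fallback ", tables$lp_fallback)
    v[miss] <- tables$lp_fallback
  }
  unname(v)
}

# --- Gasteiger PEOE -------------------------------------------------------

# (a, b, c) parameters of the electronegativity polynomial chi = a + b q +
# c q^2, keyed by Sybyl atom type. Classic partial-equalization values.
peoe_params <- function() {
  m <- rbind(
    H     = c(7.17, 6.24, -0.56),
    C.3   = c(7.98, 9.18, 1.88),
    C.2   = c(8.79, 9.32, 1.51),
    C.cat = c(8.79, 9.32, 1.51),
    C.ar  = c(8.79, 9.32, 1.51),
    C.1   = c(10.39, 9.45, 0.73),
    N.3   = c(11.54, 10.82, 1.36),
    N.4   = c(11.54, 10.82, 1.36),
    N.pl3 = c(11.54, 10.82, 1.36),
    N.2   = c(12.87, 11.15, 0.85),
    N.ar  = c(12.87, 11.15, 0.85),
    N.am  = c(12.87, 11.15, 0.85),
    N.1   = c(15.68, 11.70, -0.27),
    O.3   = c(14.18, 12.92, 1.39),
    O.2   = c(17.07, 13.79, 0.47),
    O.co2 = c(17.07, 13.79, 0.47),
    F     = c(14.66, 13.85, 2.31),
    Cl    = c(11.00, 9.69, 1.35),
    Br    = c(10.08, 8.47, 1.16),
    I     = c(9.90, 7.96, 0.96),
    S.3   = c(10.14, 9.13, 1.38),
    S.2   = c(10.14, 9.13, 1.38),
    S.o   = c(10.14, 9.13, 1.38),
    S.o2  = c(10.14, 9.13, 1.38),
    P.3   = c(8.90, 8.24, 0.96)
  )
  colnames(m) <- c("a", "b", "c")
  m
}

#' Gasteiger partial charges by iterative partial equalization (PEOE)
#'
#' Implicit hydrogens take part in the iteration as pseudo-atoms and their
#' converged charges are folded back into the bonded heavy atom, so the sum
#' over heavy atoms equals the total formal charge to machine precision.
#'
#' @param mol a [molecule()].
#' @param max_iter maximum damped-iteration count.
#' @param tol convergence threshold on the largest per-step transfer.
#' @return numeric vector of per-heavy-atom charges.
#' @export
gasteiger_charges <- function(mol, max_iter = 20L, tol = 1e-8) {
  par <- peoe_params()
  n <- n_atoms(mol)
  types <- mol$atoms$type
  unknown <- !(types %in% rownames(par))
  if (any(unknown)) {
    # fall back to the sp3 parameters of the element, then to carbon sp3
    fb <- paste0(mol$atoms$element[unknown], ".3")
    fb[!(fb %in% rownames(par))] <-
      ifelse(mol$atoms$element[unknown][!(fb %in% rownames(par))] %in%
               rownames(par),
             mol$atoms$element[unknown][!(fb %in% rownames(par))], "C.3")
    ws_log("PEOE: no parameters for type(s) ",
           paste(unique(types[unknown]), collapse = ", "),
           "; using element fallback")
    types[unknown] <- fb
  }
  # expand implicit hydrogens into pseudo-atoms
  nh <- mol$atoms$n_h
  n_all <- n + sum(nh)
  typ_all <- c(types, rep("H", sum(nh)))
  owner <- c(seq_len(n), rep(seq_len(n), nh))
  edges <- cbind(mol$bonds$i, mol$bonds$j)
  if (sum(nh)) {
    hidx <- n + seq_len(sum(nh))
    edges <- rbind(edges, cbind(rep(seq_len(n), nh), hidx))
  }
  a <- par[typ_all, "a"]; b <- par[typ_all, "b"]; cc <- par[typ_all, "c"]
  chi_plus <- a + b + cc
  chi_plus[typ_all == "H"] <- 20.02
  q <- c(as.numeric(mol$atoms$charge), rep(0, sum(nh)))
  if (nrow(edges)) {
    damp <- 1
    for (it in seq_len(max_iter)) {
      damp <- damp * 0.5
      chi <- a + b * q + cc * q^2
      dq <- numeric(n_all)
      for (k in seq_len(nrow(edges))) {
        i <- edges[k, 1]; j <- edges[k, 2]
        if (chi[j] > chi[i]) {
          t <- (chi[j] - chi[i]) / chi_plus[i] * damp
          dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
        } else {
          t <- (chi[i] - chi[j]) / chi_plus[j] * damp
          dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
        }
      }
      q <- q + dq
      if (max(abs(dq)) < tol) break
    }
  }
  # fold hydrogen charges into their heavy atom
  as.numeric(tapply(q, factor(owner, levels = seq_len(n)), sum))
}

# --- pharmacophore classes ------------------------------------------------

#' The six pharmacophore feature classes
#' @return character vector of class names.
#' @export
pharmacophore_classes <- function() {
  c("donor", "acceptor", "positive", "negative", "hydrophobic", "aromatic")
}

# per-atom class sets from element / type / charge / implicit-H rules
assign_classes <- function(mol) {
  at <- mol$atoms
  nbr_no <- logical(nrow(at))
  if (nrow(mol$bonds)) {
    polar <- at$element %in% c("N", "O")
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (polar[j]) nbr_no[i] <- TRUE
      if (polar[i]) nbr_no[j] <- TRUE
    }
  }
  lapply(seq_len(nrow(at)), function(i) {
    cl <- character(0)
    el <- at$element[i]; ty <- at$type[i]
    if (at$aromatic[i]) cl <- c(cl, "aromatic")
    if (el %in% c("N", "O") && at$n_h[i] >= 1L && at$charge[i] <= 0)
      cl <- c(cl, "donor")
    if (el %in% c("N", "O") && at$charge[i] <= 0 &&
        ty != "N.am" && !(el == "N" && at$aromatic[i] && at$n_h[i] >= 1L))
      cl <- c(cl, "acceptor")
    if (at$charge[i] > 0 || ty == "N.4") cl <- c(cl, "positive")
    if (at$charge[i] < 0 || ty == "O.co2") cl <- c(cl, "negative")
    if (el %in% c("C", "S", "Cl", "Br", "I") && !nbr_no[i] &&
        at$charge[i] == 0)
      cl <- c(cl, "hydrophobic")
    unique(cl)
  })
}

#' Annotate a molecule with atomic properties
#'
#' Computes Gasteiger partial charges (PEOE), looks up electronegativity and
#' lipophilicity increments, and assigns pharmacophore classes (donor,
#' acceptor, positive, negative, hydrophobic, aromatic) by explicit atom
#' typing rules.
#'
#' @param mol a [molecule()].
#' @param tables an [atom_property_table()] (default: shipped table).
#' @return an object of class `atom_annotation` with per-atom vectors
#'   `gasteiger`, `electronegativity`, `lipophilicity` and list `classes`.
#' @export
annotate <- function(mol, tables = atom_property_table()) {
  stopifnot(inherits(mol, "molecule"))
  g <- gasteiger_charges(mol)
  structure(list(
    id = mol$id,
    gasteiger = g,
    electronegativity = en_lookup(tables, mol$atoms$element),
    lipophilicity = lp_lookup(tables, mol$atoms$type, mol$atoms$element),
    classes = assign_classes(mol),
    table = paste0(tables$name, "-", tables$version)
  ), class = "atom_annotation")
}

#' @export
print.atom_annotation <- function(x, ...) {
  cat(sprintf("<atom_annotation %s: %d atoms, charge sum %.4f>\n",
              x$id, length(x$gasteiger), sum(x$gasteiger)))
  invisible(x)
}
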