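#' Weighted Burden number descriptor configuration
#'
#' The WBN block places one of three atomic properties on the diagonal of
#' the Burden connectivity matrix — Pauling electronegativity (`EN`),
#' Gasteiger partial charge (`GC`) or an atomic lipophilicity increment
#' (`LP`) — scales the off-diagonal bond terms by one of four weights
#' (raw weights 2.5, 5.0, 7.5, 10.0, i.e. fractions 0.25–1.00 of the base
#' bond values), and keeps the highest (`H`) and lowest (`L`) eigenvalue:
#' 3 properties x 4 weights x 2 extremes = 24 descriptors.
#'
#' @name wbn
NULL

wbn_properties <- function() c("EN", "GC", "LP")
wbn_weights <- function() c(0.25, 0.50, 0.75, 1.00)

#' Names of the 24 weighted Burden number descriptors
#'
#' Grammar: `WBN_<EN|GC|LP>_<H|L>_<0.25|0.50|0.75|1.00>`.
#'
#' @return character vector of length 24.
#' @export
wbn_names <- function() {
  out <- character(0)
  for (p in wbn_properties())
    for (w in wbn_weights())
      for (e in c("H", "L"))
        out <- c(out, sprintf("WBN_%s_%s_%.2f", p, e, w))
  out
}

# base off-diagonal contribution per bond order
burden_bond_value <- function(order) {
  ifelse(order == 1.5, 0.15,
         ifelse(order == 1, 0.1, ifelse(order == 2, 0.2, 0.3)))
}

#' Build a Burden connectivity matrix
#'
#' Diagonal: the chosen atomic property. Bonded pairs:
#' `weight_fraction * b(order)` with b = 0.1 (single), 0.2 (double),
#' 0.3 (triple), 0.15 (aromatic), plus 0.01 when either endpoint is
#' terminal (heavy-atom degree 1). Non-bonded pairs: 0.001.
#'
#' @param mol a [molecule()].
#' @param ann its [annotate()] result.
#' @param diagonal `"EN"`, `"GC"` or `"LP"`.
#' @param weight_fraction one of 0.25, 0.50, 0.75, 1.00.
#' @return symmetric numeric matrix of size heavy-atom count.
#' @export
build_burden_matrix <- function(mol, ann,
                                diagonal = c("EN", "GC", "LP"),
                                weight_fraction = 1.00) {
  diagonal <- match.arg(diagonal)
  stopifnot(weight_fraction %in% wbn_weights())
  n <- n_atoms(mol)
  d <- switch(diagonal,
              EN = ann$electronegativity,
              GC = ann$gasteiger,
              LP = ann$lipophilicity)
  B <- matrix(0.001, n, n)
  diag(B) <- d
  if (nrow(mol$bonds)) {
    deg <- mol$atoms$degree
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      v <- weight_fraction * burden_bond_value(mol$bonds$order[k])
      if (deg[i] == 1L || deg[j] == 1L) v <- v + 0.01
      B[i, j] <- v; B[j, i] <- v
    }
  }
  B
}

#' Compute the 24 weighted Burden number descriptors
#'
#' @param mol a [molecule()].
#' @param ann its [annotate()] result.
#' @return named numeric vector of length 24 (names from [wbn_names()]).
#' @export
wbn_block <- function(mol, ann) {
  out <- numeric(0)
  for (p in wbn_properties()) {
    for (w in wbn_weights()) {
      B <- build_burden_matrix(mol, ann, p, w)
      ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
      if (any(!is.finite(ev))) {
        stop("eigen-decomposition failed for molecule ", mol$id)
      }
      v <- c(max(ev), min(ev))
      names(v) <- sprintf("WBN_%s_%s_%.2f", p, c("H", "L"), w)
      out <- c(out, v)
    }
  }
  out
}
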