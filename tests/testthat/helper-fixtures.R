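# shared fixtures, all built in code at test time

# a small panel of hand-checkable structures
fixture_smiles <- function() {
  c(ethane = "CC", ethanol = "CCO", benzene = "c1ccccc1",
    phenol = "c1ccc(O)cc1", glycol = "OCCO", methane = "C",
    pyridine = "c1ccncc1", acetone = "CC(=O)C", thiophene = "c1ccsc1",
    acetamide = "CC(N)=O", toluene = "Cc1ccccc1", acetate = "CC(=O)[O-]")
}

fixture_molecules <- function() {
  s <- fixture_smiles()
  suppressMessages(molecules_from_smiles(s, ids = names(s)))
}

fixture_mol <- function(name) {
  mols <- fixture_molecules()
  mols[[match(name, vapply(mols, function(m) m$id, character(1)))]]
}

# permute the atoms of a molecule object (bonds re-indexed accordingly)
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$i <- inv[bonds$i]
  bonds$j <- inv[bonds$j]
  molecule(mol$id, atoms[, c("element", "charge", "type", "aromatic", "n_h")],
           bonds, mol$activity)
}

# a modest synthetic library shared by several tests (computed once)
shared_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        generate_library(library_config(n = 150, prevalence = 0.3,
                                        seed = 404)))
    }
    cache
  }
})

shared_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(descriptor_table(shared_library()))
    }
    cache
  }
})
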