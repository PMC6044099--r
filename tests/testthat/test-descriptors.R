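test_that("Burden matrix follows the stated construction rules", {
  # ethane: C-C single bond, both terminal -> off-diagonal 1.0*(0.1+0.01)
  eth <- fixture_mol("ethane")
  ann <- annotate(eth)
  B <- build_burden_matrix(eth, ann, "EN", 1.00)
  expect_equal(B, matrix(c(2.55, 0.11, 0.11, 2.55), 2, 2))
  # weight fraction scales the bond term only
  B2 <- build_burden_matrix(eth, ann, "EN", 0.50)
  expect_equal(B2[1, 2], 0.5 * 0.1 + 0.01)
  # single heavy atom: 1x1 matrix = the diagonal property
  met <- fixture_mol("methane")
  expect_equal(build_burden_matrix(met, annotate(met), "EN", 0.25),
               matrix(2.55, 1, 1))
  # non-bonded entries are 0.001
  pr <- suppressMessages(molecules_from_smiles("CCC", "propane"))[[1]]
  B3 <- build_burden_matrix(pr, annotate(pr), "EN", 1.00)
  expect_equal(B3[1, 3], 0.001)
  # aromatic bonds use the 0.15 base value (no terminal atoms in benzene)
  bz <- fixture_mol("benzene")
  B4 <- build_burden_matrix(bz, annotate(bz), "EN", 1.00)
  expect_equal(B4[1, 2], 0.15)
})

test_that("the WBN block emits 24 finite named descriptors with H >= L", {
  for (m in fixture_molecules()[1:6]) {
    w <- wbn_block(m, annotate(m))
    expect_identical(names(w), wbn_names())
    expect_length(w, 24L)
    expect_true(all(is.finite(w)))
    h <- w[grepl("_H_", names(w))]
    l <- w[grepl("_L_", names(w))]
    expect_true(all(h >= l))
  }
})

test_that("ethane WBN eigenvalues match the 2x2 closed form", {
  w <- wbn_block(fixture_mol("ethane"), annotate(fixture_mol("ethane")))
  expect_equal(unname(w["WBN_EN_H_1.00"]), 2.66, tolerance = 1e-12)
  expect_equal(unname(w["WBN_EN_L_1.00"]), 2.44, tolerance = 1e-12)
})

test_that("single-heavy-atom molecules give H = L = diagonal property", {
  met <- fixture_mol("methane")
  w <- wbn_block(met, annotate(met))
  for (p in c("EN", "GC", "LP")) {
    h <- w[grepl(paste0("WBN_", p, "_H"), names(w))]
    l <- w[grepl(paste0("WBN_", p, "_L"), names(w))]
    expect_equal(unname(h), unname(l))
    expect_equal(max(h), min(h))  # weight-independent for 1x1
  }
})

# brute-force oracle: reconstruct the dense Burden matrix directly from the
# stated rules (independent of build_burden_matrix) and eigendecompose it
oracle_burden <- function(mol, diag_vals, wf) {
  n <- n_atoms(mol)
  B <- matrix(NA_real_, n, n)
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), n)
  base <- c(`1` = 0.1, `2` = 0.2, `3` = 0.3, `1.5` = 0.15)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { B[i, j] <- diag_vals[i]; next }
    hit <- which((mol$bonds$i == i & mol$bonds$j == j) |
                   (mol$bonds$i == j & mol$bonds$j == i))
    B[i, j] <- if (length(hit)) {
      wf * base[[as.character(mol$bonds$order[hit])]] +
        if (deg[i] == 1 || deg[j] == 1) 0.01 else 0
    } else 0.001
  }
  B
}

test_that("WBN values match a brute-force dense eigensolver oracle", {
  small <- Filter(function(m) n_atoms(m) <= 6, fixture_molecules())
  expect_gte(length(small), 5L)
  for (m in small) {
    ann <- annotate(m)
    w <- wbn_block(m, ann)
    for (p in c("EN", "GC", "LP")) for (wf in c(0.25, 0.50, 0.75, 1.00)) {
      dvals <- switch(p, EN = ann$electronegativity, GC = ann$gasteiger,
                      LP = ann$lipophilicity)
      B <- oracle_burden(m, dvals, wf)
      expect_equal(B, build_burden_matrix(m, ann, p, wf), tolerance = 1e-15)
      ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
      expect_equal(unname(w[sprintf("WBN_%s_H_%.2f", p, wf)]), max(ev),
                   tolerance = 1e-9)
      expect_equal(unname(w[sprintf("WBN_%s_L_%.2f", p, wf)]), min(ev),
                   tolerance = 1e-9)
    }
  }
})

test_that("extreme eigenvalues agree with characteristic-polynomial roots", {
  skip_if_not_installed("pracma")
  small <- Filter(function(m) n_atoms(m) <= 6, fixture_molecules())
  for (m in small[1:4]) {
    ann <- annotate(m)
    w <- wbn_block(m, ann)
    B <- build_burden_matrix(m, ann, "EN", 1.00)
    ev <- if (nrow(B) == 1L) B[1, 1] else {
      Re(polyroot(rev(pracma::charpoly(B))))
    }
    # polyroot carries ~1e-7 numerical error on degree-6 polynomials
    expect_equal(unname(w["WBN_EN_H_1.00"]), max(ev), tolerance = 1e-6)
    expect_equal(unname(w["WBN_EN_L_1.00"]), min(ev), tolerance = 1e-6)
  }
})

test_that("WBN values respect Gershgorin bounds and permutation invariance", {
  mols <- shared_library()[1:40]
  for (m in mols) {
    ann <- annotate(m)
    w <- wbn_block(m, ann)
    for (p in c("EN", "GC", "LP")) {
      B <- build_burden_matrix(m, ann, p, 1.00)
      radius <- rowSums(abs(B)) - abs(diag(B))
      lo <- min(diag(B) - radius); hi <- max(diag(B) + radius)
      expect_gte(w[sprintf("WBN_%s_H_1.00", p)], lo - 1e-12)
      expect_lte(w[sprintf("WBN_%s_H_1.00", p)], hi + 1e-12)
      expect_gte(w[sprintf("WBN_%s_L_1.00", p)], lo - 1e-12)
      expect_lte(w[sprintf("WBN_%s_L_1.00", p)], hi + 1e-12)
    }
  }
  set.seed(99)
  for (m in mols[1:10]) {
    perm <- sample(n_atoms(m))
    mp <- permute_molecule(m, perm)
    expect_equal(wbn_block(m, annotate(m)), wbn_block(mp, annotate(mp)),
                 tolerance = 1e-9)
  }
})

test_that("the property block matches hand counts on reference molecules", {
  eth <- fixture_mol("ethanol")
  p <- property_block(eth, annotate(eth))
  expect_identical(names(p), property_names())
  expect_equal(unname(p["HBD"]), 1)
  expect_equal(unname(p["HBA"]), 1)
  expect_equal(unname(p["HEAVY_ATOMS"]), 3)
  expect_equal(unname(p["ROTB"]), 0)  # both bonds end on a terminal atom
  expect_equal(unname(p["MW"]), 46.069, tolerance = 1e-3)
  bz <- fixture_mol("benzene")
  pb <- property_block(bz, annotate(bz))
  expect_equal(unname(pb["AROM_RINGS"]), 1)
  expect_equal(unname(pb["HBD"]), 0)
  tol <- fixture_mol("toluene")
  pt <- property_block(tol, annotate(tol))
  expect_equal(unname(pt["ROTB"]), 0)  # methyl is terminal
  naph <- suppressMessages(
    molecules_from_smiles("c1ccc2ccccc2c1", "naphthalene"))[[1]]
  expect_equal(unname(property_block(naph, annotate(naph))["AROM_RINGS"]), 2)
  # counts are non-negative integers, everything finite
  for (m in shared_library()[1:20]) {
    v <- property_block(m, annotate(m))
    expect_true(all(is.finite(v)))
    counts <- v[c("HBD", "HBA", "ROTB", "AROM_RINGS", "HEAVY_ATOMS")]
    expect_true(all(counts >= 0 & counts == round(counts)))
  }
})

test_that("the fingerprint block encodes class pairs at binned distances", {
  met <- fixture_mol("methane")
  f <- fingerprint_block(met, annotate(met))
  expect_length(f, 147L)
  expect_identical(names(f), fingerprint_names())
  expect_true(all(f == 0L))  # no atom pairs
  gly <- fixture_mol("glycol")  # OCCO: donor-donor at path length 3
  fg <- fingerprint_block(gly, annotate(gly))
  expect_identical(unname(fg["FP_donor_donor_d3"]), 1L)
  expect_true(all(fg %in% c(0L, 1L)))
  # long chain reaches the >= 8 bin
  lng <- suppressMessages(
    molecules_from_smiles("OCCCCCCCCCO", "longdiol"))[[1]]
  fl <- fingerprint_block(lng, annotate(lng))
  expect_identical(unname(fl["FP_donor_donor_d8p"]), 1L)
})

test_that("descriptor_table emits the 179-column schema deterministically", {
  mols <- fixture_molecules()[1:6]
  tab <- descriptor_table(mols)
  expect_identical(setdiff(names(tab), c("id", "activity")),
                   descriptor_schema())
  expect_identical(ncol(tab), 181L)
  expect_false(anyNA(tab))
  # duplicate structure -> identical descriptor rows
  dup <- suppressMessages(
    molecules_from_smiles(c("CCO", "CCO"), c("a", "b")))
  td <- descriptor_table(dup)
  expect_equal(unlist(td[1, -(1:2)]), unlist(td[2, -(1:2)]),
               tolerance = 1e-15)
})

test_that("descriptor tables survive a CSV round-trip to 12 digits", {
  tab <- descriptor_table(fixture_molecules()[1:5])
  tf <- tempfile(fileext = ".csv")
  write_descriptor_csv(tab, tf)
  back <- read_descriptor_csv(tf)
  expect_identical(names(back), names(tab))
  num <- setdiff(names(tab), c("id", "activity"))
  expect_equal(as.matrix(back[, num]), as.matrix(tab[, num]),
               tolerance = 1e-12)
})

test_that("ARFF export writes a well-formed header and data block", {
  tab <- descriptor_table(fixture_molecules()[1:3])
  tf <- tempfile(fileext = ".arff")
  write_arff(tab, tf, relation = "fixture")
  lines <- readLines(tf)
  expect_identical(lines[1], "@RELATION fixture")
  expect_length(grep("^@ATTRIBUTE", lines), 181L)
  expect_identical(sum(lines == "@DATA"), 1L)
  expect_length(lines[seq(which(lines == "@DATA") + 1, length(lines))], 3L)
})
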