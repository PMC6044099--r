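#' Read a molecule library from SDF or SMILES CSV
#'
#' Structures are interpreted by OpenBabel (through ChemmineOB) and converted
#' to an internal hydrogen-suppressed graph that retains aromaticity, Sybyl
#' atom types, formal charges and implicit hydrogen counts. Records that fail
#' to parse are skipped with a warning and counted in the `skipped`
#' attribute. For multi-fragment records the largest fragment is kept.
#'
#' @param path file path.
#' @param format `"sdf"`, `"smiles_csv"`, or `"auto"` (by extension). A
#'   SMILES CSV must have columns `id`, `smiles`, `activity`.
#' @return list of [molecule()] objects (attribute `skipped` = number of
#'   unparsable records).
#' @export
read_library <- function(path, format = c("auto", "sdf", "smiles_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read library: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE))
      "sdf" else "smiles_csv"
  }
  if (format == "smiles_csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "smiles", "activity")
    if (!all(need %in% names(df))) {
      stop("smiles_csv must have columns id, smiles, activity")
    }
    mols <- molecules_from_smiles(df$smiles, ids = as.character(df$id),
                                  activity = df$activity)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    mols <- molecules_from_sdf_text(txt)
  }
  if (length(mols) == 0L) {
    stop("no valid records could be parsed from ", path)
  }
  mols
}

#' Build molecules from SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param ids identifiers (default `mol1`, `mol2`, ...).
#' @param activity optional activity labels (any of active/inactive, 1/0,
#'   TRUE/FALSE dialects).
#' @return list of [molecule()] (attribute `skipped` counts parse failures).
#' @export
molecules_from_smiles <- function(smiles, ids = NULL, activity = NULL) {
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_len(n))
  stopifnot(length(ids) == n)
  tags <- paste0("WSREC", seq_len(n))
  src <- paste0(smiles, " ", tags, collapse = "\n")
  mol2 <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "MOL2", paste0(src, "\n"),
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)))
  parsed <- parse_mol2(mol2)
  # a malformed record can abort the batch conversion mid-stream; retry the
  # unconverted records one at a time so later valid records survive
  parsed <- recover_missing(parsed, tags, function(k) {
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "MOL2", paste0(smiles[k], " ", tags[k], "\n"),
      options = data.frame(names = "h", args = "",
                           stringsAsFactors = FALSE)))
  })
  finalize_records(parsed, tags, ids, activity)
}

recover_missing <- function(parsed, tags, convert_one) {
  got <- vapply(parsed, function(m) m$id, character(1))
  for (k in which(!(tags %in% got))) {
    more <- tryCatch(parse_mol2(convert_one(k)), error = function(e) list())
    parsed <- c(parsed, more)
  }
  parsed
}

# SDF text -> molecules; record titles are replaced by tags so skipped
# records can be identified after conversion; an <activity> data field is
# honoured when present.
molecules_from_sdf_text <- function(txt) {
  recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  n <- length(recs)
  if (!n) stop("empty SDF input")
  ids <- character(n); act <- rep(NA_character_, n)
  tags <- paste0("WSREC", seq_len(n))
  fixed <- vapply(seq_len(n), function(k) {
    l <- strsplit(sub("^\n+", "", recs[k]), "\n", fixed = TRUE)[[1]]
    ids[k] <<- if (nzchar(trimws(l[1]))) trimws(l[1]) else paste0("mol", k)
    fk <- grep("^>.*<activity>", l)
    if (length(fk) && length(l) > fk[1]) act[k] <<- trimws(l[fk[1] + 1])
    l[1] <- tags[k]
    paste(l, collapse = "\n")
  }, character(1))
  sdf <- paste0(paste(fixed, collapse = "\n$$$$\n"), "\n$$$$\n")
  mol2 <- suppressWarnings(ChemmineOB::convertFormat(
    "SDF", "MOL2", sdf,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)))
  parsed <- parse_mol2(mol2)
  parsed <- recover_missing(parsed, tags, function(k) {
    suppressWarnings(ChemmineOB::convertFormat(
      "SDF", "MOL2", paste0(fixed[k], "\n$$$$\n"),
      options = data.frame(names = "h", args = "",
                           stringsAsFactors = FALSE)))
  })
  finalize_records(parsed, tags, ids, act)
}

finalize_records <- function(parsed, tags, ids, activity) {
  got <- vapply(parsed, function(m) m$id, character(1))
  pos <- match(tags, got)
  skipped <- sum(is.na(pos))
  if (skipped > 0) {
    warning(skipped, " record(s) could not be parsed and were skipped: ",
            paste(ids[is.na(pos)], collapse = ", "))
  }
  act <- if (is.null(activity)) rep("unknown", length(tags)) else {
    a <- normalize_activity(activity); a[is.na(a)] <- "unknown"; a
  }
  out <- list()
  for (k in seq_along(tags)) {
    if (is.na(pos[k])) next
    m <- parsed[[pos[k]]]
    m$id <- ids[k]
    m$activity <- act[k]
    out[[length(out) + 1L]] <- m
  }
  attr(out, "skipped") <- skipped
  out
}

# molecules -> SDF (V2000) text, one string per molecule
sdf_text <- function(mols) {
  vapply(mols, function(m) {
    n <- n_atoms(m); nb <- nrow(m$bonds)
    lines <- c(m$id, "  wbnscreen", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, m$atoms$element))
    if (nb) {
      code <- ifelse(m$bonds$order == 1.5, 4L, as.integer(m$bonds$order))
      lines <- c(lines, sprintf("%3d%3d%3d  0", m$bonds$i, m$bonds$j, code))
    }
    chg <- which(m$atoms$charge != 0)
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        "M  CHG", sprintf("%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, as.integer(m$atoms$charge[grp])),
               collapse = "")))
    }
    lines <- c(lines, "M  END")
    if (m$activity != "unknown") {
      lines <- c(lines, "> <activity>", m$activity, "")
    }
    paste(c(lines, "$$$$", ""), collapse = "\n")
  }, character(1))
}

#' Write molecules to an SDF (V2000) file
#'
#' Aromatic bonds are written as bond type 4; formal charges as `M  CHG`
#' lines; the activity label as an `<activity>` data field. Coordinates are
#' zero (the package is purely topological).
#'
#' @param mols list of [molecule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  writeLines(sdf_text(mols), path, sep = "")
  invisible(path)
}

# SMARTS match counts: molecules x patterns matrix (OpenBabel matcher)
smarts_match_counts <- function(mols, patterns) {
  txt <- paste(sdf_text(mols), collapse = "")
  per_mol <- ChemmineOB::forEachMol("SDF", txt, function(mol) {
    vapply(patterns, function(p) {
      as.numeric(ChemmineOB::smartsSearch_OB(list(mol), p,
                                             uniqueMatches = FALSE))
    }, numeric(1))
  })
  mat <- do.call(rbind, per_mol)
  matrix(mat, nrow = length(mols),
         dimnames = list(NULL, names(patterns)))
}
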