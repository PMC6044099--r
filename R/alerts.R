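#' Load structural-alert rules from a YAML file
#'
#' Rules come in two kinds: `reject` (any match eliminates the compound)
#' and `demerit` (matches accumulate points; a compound whose total exceeds
#' the engine threshold is eliminated), after the rejection/demerit design
#' of published medicinal-chemistry rule sets. A demonstration set of
#' reactive and promiscuity-prone motifs ships with the package.
#'
#' @param path YAML rule file; default: the shipped demo set.
#' @return list of `alert_rule` objects (name, smarts, kind, points), in
#'   file order; class `alert_rules`.
#' @export
load_alert_rules <- function(path = NULL) {
  if (is.null(path)) path <- ws_extdata("alert_rules_demo.yaml")
  y <- yaml::read_yaml(path)
  raw <- y$rules %||% list()
  rules <- lapply(raw, function(r) {
    stopifnot(!is.null(r$name), !is.null(r$smarts), !is.null(r$kind))
    kind <- match.arg(r$kind, c("reject", "demerit"))
    pts <- if (kind == "demerit") as.integer(r$points %||% 0L) else 0L
    if (kind == "demerit" && pts <= 0L) {
      stop("demerit rule '", r$name, "' needs positive points")
    }
    structure(list(name = r$name, smarts = r$smarts, kind = kind,
                   points = pts), class = "alert_rule")
  })
  # validate every pattern up front so a malformed rule fails by name
  if (length(rules)) {
    probe <- molecules_from_smiles("CCO", ids = "probe")
    for (r in rules) {
      ok <- tryCatch({
        smarts_match_counts(probe, stats::setNames(r$smarts, r$name))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) stop("invalid SMARTS in rule '", r$name, "': ", r$smarts)
    }
  }
  structure(rules, class = "alert_rules")
}

#' @export
print.alert_rules <- function(x, ...) {
  cat("<alert_rules: ", length(x), " rules (",
      sum(vapply(x, function(r) r$kind == "reject", logical(1))),
      " reject, ",
      sum(vapply(x, function(r) r$kind == "demerit", logical(1))),
      " demerit)>\n", sep = "")
  invisible(x)
}

#' Apply structural-alert rules to molecules
#'
#' Substructure matching is SMARTS-based (OpenBabel). Each matched demerit
#' rule counts once per compound regardless of match multiplicity. A
#' compound is rejected when any reject rule matches or its demerit total
#' exceeds `threshold`.
#'
#' @param mols a [molecule()] or list of molecules.
#' @param rules an `alert_rules` object ([load_alert_rules()]).
#' @param threshold demerit rejection threshold (default 100).
#' @return data.frame of class `alert_verdict`: `id`, `matched_rules`
#'   (semicolon-joined), `demerits`, `outcome` (`pass`/`reject`).
#' @export
apply_alerts <- function(mols, rules, threshold = 100L) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  n <- length(mols)
  ids <- vapply(mols, function(m) m$id, character(1))
  matched <- vector("list", n)
  demerits <- integer(n)
  reject <- logical(n)
  if (length(rules) && n) {
    pats <- stats::setNames(vapply(rules, `[[`, character(1), "smarts"),
                            vapply(rules, `[[`, character(1), "name"))
    counts <- smarts_match_counts(mols, pats)
    for (k in seq_along(rules)) {
      r <- rules[[k]]
      for (i in which(counts[, k] > 0)) {
        matched[[i]] <- c(matched[[i]], r$name)
        if (r$kind == "reject") reject[i] <- TRUE
        else demerits[i] <- demerits[i] + r$points
      }
    }
  }
  outcome <- ifelse(reject | demerits > threshold, "reject", "pass")
  structure(data.frame(
    id = ids,
    matched_rules = vapply(matched, function(m)
      paste(m %||% character(0), collapse = ";"), character(1)),
    demerits = demerits,
    outcome = outcome,
    stringsAsFactors = FALSE), class = c("alert_verdict", "data.frame"))
}
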