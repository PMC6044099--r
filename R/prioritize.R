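#' Principal component analysis of a descriptor table
#'
#' Columns are standardized (mean 0, sd 1) and the correlation matrix is
#' eigen-decomposed. The sign of each component is fixed so that its
#' largest-magnitude loading is positive. Per-variable contributions to a
#' component are the squared loadings of the unit-norm eigenvector, which
#' sum to one.
#'
#' @param table descriptor table (data.frame with `id`/`activity` plus
#'   numeric columns).
#' @param scope `"continuous"` (default: the WBN + property blocks) or
#'   `"all"` (every descriptor column present).
#' @return an object of class `pca_result`: `eigenvalues`, `loadings`
#'   (variables x components), `contributions` (squared loadings),
#'   `variance_explained`, `variables`, `dropped` (zero-variance columns).
#' @export
pca_descriptors <- function(table, scope = c("continuous", "all")) {
  scope <- match.arg(scope)
  vars <- if (scope == "continuous") {
    intersect(c(wbn_names(), property_names()), names(table))
  } else {
    setdiff(names(table), c("id", "activity"))
  }
  stopifnot(nrow(table) >= 2L)
  X <- as.matrix(table[, vars, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  dropped <- vars[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  }
  vars <- setdiff(vars, dropped)
  if (length(vars) < 2L) stop("fewer than 2 usable columns for PCA")
  X <- X[, vars, drop = FALSE]
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  val <- pmax(e$values, 0)
  vec <- e$vectors
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(vec))) {
    piv <- which.max(abs(vec[, k]))
    if (vec[piv, k] < 0) vec[, k] <- -vec[, k]
  }
  rownames(vec) <- vars
  colnames(vec) <- paste0("F", seq_len(ncol(vec)))
  contrib <- sweep(vec^2, 2, colSums(vec^2), "/")
  structure(list(eigenvalues = val,
                 loadings = vec,
                 contributions = contrib,
                 variance_explained = val / sum(val),
                 variables = vars,
                 dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d variables, F1 explains %.1f%% of variance>\n",
              length(x$variables), 100 * x$variance_explained[1]))
  invisible(x)
}

#' Select the descriptors contributing most to the first component
#'
#' The `m` variables with the largest contribution to F1, ties broken by
#' schema column order; the selection is returned in order of decreasing
#' contribution. With `components > 1` the criterion becomes the
#' eigenvalue-weighted sum of contributions over the leading components
#' (non-default).
#'
#' @param result a [pca_descriptors()] result.
#' @param m number of descriptors to keep (default 14).
#' @param components number of leading components in the ranking criterion
#'   (default 1).
#' @return an object of class `pcad_selection`; element `names` is the
#'   ordered selection.
#' @export
select_pcad <- function(result, m = 14L, components = 1L) {
  stopifnot(inherits(result, "pca_result"),
            m >= 1L, m <= length(result$variables),
            components >= 1L)
  score <- if (components == 1L) {
    result$contributions[, 1]
  } else {
    ks <- seq_len(min(components, ncol(result$contributions)))
    as.numeric(result$contributions[, ks, drop = FALSE] %*%
                 result$eigenvalues[ks])
  }
  # ties (to 1e-12, e.g. duplicated columns) broken by schema position
  ord <- order(-round(score, 12), seq_along(score))
  sel <- result$variables[ord[seq_len(m)]]
  structure(list(names = sel, m = as.integer(m),
                 score = score[ord[seq_len(m)]],
                 components = as.integer(components)),
            class = "pcad_selection")
}

#' @export
print.pcad_selection <- function(x, ...) {
  cat("<pcad_selection: ", x$m, " descriptors>\n", sep = "")
  cat(paste0("  ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

#' The 14-descriptor reference selection
#'
#' The weighted Burden number descriptors reported as the PCA-prioritized
#' subset (PCAD) of the original study, shipped as a plain-text fixture in
#' the package's descriptor-name grammar.
#'
#' @return character vector of 14 WBN descriptor names.
#' @export
pcad_reference <- function() {
  readLines(ws_extdata("pcad_reference.txt"))
}

#' Write PCA results / a PCAD selection to disk
#'
#' @param result a `pca_result`.
#' @param path output file (CSV for results, plain text for selections).
#' @return `path`, invisibly.
#' @export
write_pca_csv <- function(result, path) {
  df <- data.frame(variable = result$variables,
                   contribution_F1 = result$contributions[, 1],
                   loading_F1 = result$loadings[, 1])
  df <- df[order(-df$contribution_F1), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pca_csv
#' @param selection a `pcad_selection`.
#' @export
write_pcad <- function(selection, path) {
  writeLines(selection$names, path)
  invisible(path)
}
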