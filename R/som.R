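#' Self-organizing map configuration
#'
#' Online Kohonen training on a rectangular grid with Gaussian
#' neighborhood and exponential decay of the learning rate and
#' neighborhood radius.
#'
#' @param rows,cols grid dimensions (default 5 x 5).
#' @param epochs passes over the data (default 100).
#' @param alpha0 initial learning rate in [0, 1] (0 freezes the weights at
#'   their initialization, useful for testing).
#' @param sigma0 initial neighborhood radius (default: half the larger grid
#'   dimension).
#' @param seed RNG seed (weight initialization and presentation order).
#' @return an object of class `som_config`.
#' @export
som_config <- function(rows = 5L, cols = 5L, epochs = 100L, alpha0 = 0.5,
                       sigma0 = NULL, seed = 1L) {
  stopifnot(rows >= 1L, cols >= 1L, epochs >= 1L,
            alpha0 >= 0, alpha0 <= 1)
  if (is.null(sigma0)) sigma0 <- max(rows, cols) / 2
  stopifnot(sigma0 > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 epochs = as.integer(epochs), alpha0 = alpha0,
                 sigma0 = sigma0, seed = as.integer(seed)),
            class = "som_config")
}

#' Fit a self-organizing map
#'
#' Online competitive learning: weights are initialized by sampling input
#' rows; for each presented row the best-matching unit (BMU, minimum
#' Euclidean distance, ties to the lower row-major index) and its Gaussian
#' neighborhood move toward the input,
#' `w <- w + alpha(t) h(bmu, cell, sigma(t)) (x - w)`, with `alpha` and
#' `sigma` decaying exponentially over epochs. Inputs are expected in a
#' standardized feature space (see [standardize_features()]).
#'
#' @param x numeric matrix (rows = compounds, columns = features).
#' @param config a [som_config()].
#' @return an object of class `som_grid`: `weights` (cells x features, in
#'   row-major cell order), `coords`, `qe_trace` (mean quantization error
#'   per epoch, length `epochs`), and the config.
#' @export
som_fit <- function(x, config = som_config()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("SOM input contains non-finite values")
  stopifnot(nrow(x) >= 1L)
  ncell <- config$rows * config$cols
  coords <- cbind(row = rep(seq_len(config$rows), each = config$cols),
                  col = rep(seq_len(config$cols), times = config$rows))
  set.seed(derive_seed(config$seed, 0L))
  w <- x[sample(nrow(x), ncell, replace = nrow(x) < ncell), , drop = FALSE]
  lambda <- config$epochs / log(max(config$sigma0, 1 + 1e-9))
  qe <- numeric(config$epochs)
  d2grid <- as.matrix(stats::dist(coords))^2
  for (ep in seq_len(config$epochs)) {
    alpha <- config$alpha0 * exp(-(ep - 1) / config$epochs)
    sigma <- config$sigma0 * exp(-(ep - 1) / lambda)
    set.seed(derive_seed(config$seed, ep))
    ord <- sample(nrow(x))
    err <- numeric(length(ord))
    for (r in seq_along(ord)) {
      xi <- x[ord[r], ]
      d2 <- rowSums(sweep(w, 2, xi)^2)
      bmu <- which.min(d2)  # which.min takes the first (row-major) tie
      err[r] <- sqrt(d2[bmu])
      h <- exp(-d2grid[bmu, ] / (2 * sigma^2))
      w <- w + (alpha * h) * sweep(-w, 2, xi, `+`)
    }
    qe[ep] <- mean(err)
  }
  structure(list(weights = w, coords = coords, qe_trace = qe,
                 config = config), class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid %dx%d: %d features, final QE %.4g>\n",
              x$config$rows, x$config$cols, ncol(x$weights),
              x$qe_trace[length(x$qe_trace)]))
  invisible(x)
}

#' Assign rows to their best-matching unit
#'
#' @param grid a [som_fit()] result.
#' @param x numeric matrix with the grid's feature dimension.
#' @return data.frame with `cell` (row-major index), `row`, `col` and the
#'   quantization error per input row.
#' @export
som_assign <- function(grid, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(grid$weights)) {
    stop("dimension mismatch: grid has ", ncol(grid$weights),
         " features, input has ", ncol(x))
  }
  cell <- integer(nrow(x)); qe <- numeric(nrow(x))
  for (r in seq_len(nrow(x))) {
    d2 <- rowSums(sweep(grid$weights, 2, x[r, ])^2)
    cell[r] <- which.min(d2)
    qe[r] <- sqrt(d2[cell[r]])
  }
  data.frame(cell = cell,
             row = grid$coords[cell, "row"],
             col = grid$coords[cell, "col"],
             qe = qe)
}

#' Standardize features with training-population statistics
#'
#' @param x numeric matrix or data.frame of features.
#' @param center,scale optional means / sds; computed from `x` when absent.
#'   Zero sds are replaced by 1.
#' @return standardized matrix with attributes `center` and `scale`.
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  out <- sweep(sweep(x, 2, center), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Report screened compounds co-located with reference compounds
#'
#' For each reference compound (e.g. an approved drug), lists the
#' non-reference compounds sharing its best-matching SOM cell — the
#' map-based notion of similarity used to shortlist screened hits.
#'
#' @param assignments a [som_assign()] data.frame.
#' @param ids compound identifiers, parallel to `assignments`.
#' @param reference_ids identifiers of the reference compounds (must occur
#'   in `ids`).
#' @param features optional data.frame of per-compound feature values to
#'   tabulate alongside each group.
#' @return an object of class `co_location_report`: a list (one element per
#'   reference) with the reference id, cell, and co-located compound ids
#'   (plus features when given).
#' @export
co_location_report <- function(assignments, ids, reference_ids,
                               features = NULL) {
  stopifnot(length(ids) == nrow(assignments))
  if (!all(reference_ids %in% ids)) {
    stop("reference id(s) not among assigned rows: ",
         paste(setdiff(reference_ids, ids), collapse = ", "))
  }
  groups <- lapply(reference_ids, function(rid) {
    cell <- assignments$cell[match(rid, ids)]
    mates <- ids[assignments$cell == cell & !(ids %in% reference_ids)]
    g <- list(reference = rid, cell = cell, compounds = mates)
    if (!is.null(features)) {
      g$feature_values <- features[match(c(rid, mates), ids), , drop = FALSE]
    }
    g
  })
  names(groups) <- reference_ids
  structure(groups, class = "co_location_report")
}

#' @export
print.co_location_report <- function(x, ...) {
  for (g in x) {
    cat(sprintf("reference %s (cell %d): %s\n", g$reference, g$cell,
                if (length(g$compounds)) paste(g$compounds, collapse = ", ")
                else "(alone in its cell)"))
  }
  invisible(x)
}

#' Write SOM assignments as CSV
#'
#' @param assignments a [som_assign()] data.frame.
#' @param ids compound identifiers.
#' @param reference_ids ids flagged as reference compounds.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_som_csv <- function(assignments, ids, reference_ids, path) {
  df <- data.frame(id = ids, cell = assignments$cell,
                   row = assignments$row, col = assignments$col,
                   is_reference = ids %in% reference_ids,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
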