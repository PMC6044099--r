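#' Fragment vocabulary for the synthetic library generator
#'
#' Molecules are assembled by concatenating SMILES fragments chosen so that
#' every junction is valence-legal: `starters` and `units` end (or begin)
#' on an atom with a free valence, `linkers` are divalent, `caps` are
#' monovalent terminators. This guarantees chemically valid, parseable
#' structures while covering aromatic and aliphatic rings, heteroatoms,
#' charged groups and the reactive motifs the alert engine looks for.
#'
#' @param id vocabulary name (only `"default"` ships).
#' @return list with character vectors `starters`, `linkers`, `units`,
#'   `caps`.
#' @export
fragment_vocabulary <- function(id = "default") {
  stopifnot(identical(id, "default"))
  list(
    starters = c("c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccc2ccccc2c1",
                 "c1ccsc1", "c1ccoc1", "c1cc[nH]c1", "C1CCCCC1",
                 "C1CCNCC1", "C1CCOCC1", "C1CCCC1", "CC(C)C", "CCCC"),
    linkers = c("C", "CC", "CCC", "CN", "CO", "CS", "C(=O)", "C(=O)N",
                "C=C", "COC", "CNC", "C(C)"),
    units = c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCOCC1", "c1ccsc1",
              "C", "CC", "C(C)C"),
    caps = c("O", "N", "F", "Cl", "Br", "C", "C#N", "[N+](=O)[O-]",
             "C(=O)O", "C(F)(F)F", "OC", "N(C)C", "C=O", "S", "C(N)=O")
  )
}

#' Configuration for the synthetic bioassay library generator
#'
#' @param n number of compounds.
#' @param prevalence target active fraction in (0, 1); the intercept is
#'   calibrated by bisection against the generated descriptor
#'   distribution. Use `NULL` to fix `beta0` directly.
#' @param beta0 logistic intercept (only used when `prevalence` is NULL).
#' @param beta coefficients on the designated (standardized) WBN
#'   descriptors.
#' @param designated names of the WBN descriptors carrying the activity
#'   signal.
#' @param noise_scale sd of the extra logit noise.
#' @param vocabulary fragment vocabulary id.
#' @param seed RNG seed.
#' @return an object of class `library_config`.
#' @export
library_config <- function(n = 2000L, prevalence = 0.05, beta0 = 0,
                           beta = c(2.0, 1.5, 1.5, 1.0, 1.0),
                           designated = c("WBN_EN_H_1.00", "WBN_LP_H_0.75",
                                          "WBN_LP_H_1.00", "WBN_GC_H_1.00",
                                          "WBN_LP_L_1.00"),
                           noise_scale = 0.5, vocabulary = "default",
                           seed = 1L) {
  stopifnot(n >= 2L, length(beta) == length(designated),
            all(designated %in% wbn_names()))
  if (!is.null(prevalence)) stopifnot(prevalence > 0, prevalence < 1)
  structure(list(n = as.integer(n), prevalence = prevalence, beta0 = beta0,
                 beta = beta, designated = designated,
                 noise_scale = noise_scale, vocabulary = vocabulary,
                 seed = as.integer(seed)),
            class = "library_config")
}

# bisection on the logistic intercept so the mean response probability hits
# the target prevalence
calibrate_intercept <- function(linear, prevalence, lo = -50, hi = 50) {
  f <- function(b0) mean(stats::plogis(b0 + linear)) - prevalence
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic bioassay library
#'
#' Assembles valence-legal structures from the fragment grammar, computes
#' the designated weighted Burden descriptors on each structure, and draws
#' activity labels `Bernoulli(sigmoid(beta0 + beta . z(d(x)) + noise))`
#' where `z` standardizes the designated descriptors over the library. With
#' a target prevalence the intercept is calibrated by bisection.
#'
#' @param config a [library_config()].
#' @param tables an [atom_property_table()].
#' @return list of labelled [molecule()] objects, with attributes
#'   `prevalence` (achieved), `beta0`, `designated`, `smiles`.
#' @export
generate_library <- function(config = library_config(),
                             tables = atom_property_table()) {
  voc <- fragment_vocabulary(config$vocabulary)
  set.seed(derive_seed(config$seed, 0L))
  smiles <- vapply(seq_len(config$n), function(i) {
    s <- sample(voc$starters, 1)
    for (j in seq_len(sample(0:2, 1, prob = c(0.25, 0.5, 0.25)))) {
      s <- paste0(s, sample(voc$linkers, 1), sample(voc$units, 1))
    }
    if (stats::runif(1) < 0.7) s <- paste0(s, sample(voc$caps, 1))
    s
  }, character(1))
  ids <- sprintf("syn%05d", seq_len(config$n))
  mols <- molecules_from_smiles(smiles, ids = ids)
  if (attr(mols, "skipped") > 0) {
    stop("fragment grammar produced unparseable structures; vocabulary bug")
  }
  d <- t(vapply(mols, function(m) {
    wbn_block(m, annotate(m, tables))[config$designated]
  }, numeric(length(config$designated))))
  z <- standardize_features(d)
  set.seed(derive_seed(config$seed, 1L))
  linear <- as.numeric(z %*% config$beta) +
    stats::rnorm(config$n, sd = config$noise_scale)
  beta0 <- if (is.null(config$prevalence)) config$beta0 else
    calibrate_intercept(linear, config$prevalence)
  set.seed(derive_seed(config$seed, 2L))
  y <- stats::rbinom(config$n, 1L, stats::plogis(beta0 + linear))
  achieved <- mean(y)
  if (!is.null(config$prevalence)) {
    tol <- 3 * sqrt(config$prevalence * (1 - config$prevalence) / config$n)
    if (abs(achieved - config$prevalence) > tol) {
      warning(sprintf(
        "achieved prevalence %.4f differs from target %.4f", achieved,
        config$prevalence))
    }
  }
  for (k in seq_len(config$n)) {
    mols[[k]]$activity <- if (y[k] == 1L) "active" else "inactive"
  }
  attr(mols, "prevalence") <- achieved
  attr(mols, "beta0") <- beta0
  attr(mols, "designated") <- config$designated
  attr(mols, "smiles") <- smiles
  mols
}

#' Configuration for the planted-structure descriptor-table generator
#'
#' @param n rows (compounds).
#' @param p columns; `p = 179` exposes the full descriptor schema naming,
#'   otherwise columns are `V1..Vp`.
#' @param planted names (or indices) of the informative columns sharing the
#'   latent factor.
#' @param loading loading strength of the latent factor on planted columns.
#' @param noise_sd sd of the independent column noise.
#' @param label_strength logistic coefficient of the latent factor in the
#'   label model (0 = labels independent of the table).
#' @param prevalence target active fraction (intercept calibrated).
#' @param seed RNG seed.
#' @return an object of class `table_config`.
#' @export
table_config <- function(n = 500L, p = 179L,
                         planted = c("WBN_EN_H_1.00", "WBN_LP_H_0.75",
                                     "WBN_LP_H_1.00", "WBN_GC_H_1.00",
                                     "WBN_LP_L_1.00"),
                         loading = 5, noise_sd = 1, label_strength = 2,
                         prevalence = 0.5, seed = 1L) {
  cols <- if (p == 179L) descriptor_schema() else paste0("V", seq_len(p))
  if (is.numeric(planted)) planted <- cols[planted]
  stopifnot(all(planted %in% cols), loading > 0, noise_sd >= 0,
            prevalence > 0, prevalence < 1, n >= 2L)
  structure(list(n = as.integer(n), p = as.integer(p), columns = cols,
                 planted = planted, loading = loading, noise_sd = noise_sd,
                 label_strength = label_strength, prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "table_config")
}

#' Generate a descriptor table with planted low-rank structure
#'
#' Planted columns are `loading x latent factor + noise`; the remaining
#' continuous columns are independent noise and (under the full schema)
#' fingerprint columns are independent bits. Labels follow a logistic
#' model on the latent factor.
#'
#' @param config a [table_config()].
#' @return descriptor-table data.frame (`id`, `activity`, `p` columns) with
#'   attributes `latent` and `planted`.
#' @export
generate_table <- function(config = table_config()) {
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n
  f <- stats::rnorm(n)
  X <- matrix(stats::rnorm(n * config$p), n, config$p)
  colnames(X) <- config$columns
  if (config$p == 179L) {
    fp <- intersect(fingerprint_names(), config$columns)
    X[, fp] <- matrix(stats::rbinom(n * length(fp), 1L, 0.3),
                      n, length(fp))
  }
  for (cn in config$planted) {
    X[, cn] <- config$loading * f + stats::rnorm(n, sd = config$noise_sd)
  }
  linear <- config$label_strength * f
  beta0 <- calibrate_intercept(linear, config$prevalence)
  set.seed(derive_seed(config$seed, 1L))
  y <- stats::rbinom(n, 1L, stats::plogis(beta0 + linear))
  out <- data.frame(id = sprintf("row%05d", seq_len(n)),
                    activity = ifelse(y == 1L, "active", "inactive"),
                    X, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "latent") <- f
  attr(out, "planted") <- config$planted
  out
}
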