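#' Sampling plan for down-sizing an imbalanced bioassay
#'
#' The inactive majority class is split into `k` near-equal contiguous
#' chunks; every chunk is pooled with all actives and a simple random
#' sample of `round(f * pool size)` compounds (without replacement) becomes
#' one training set.
#'
#' @param k number of subsets (default 15).
#' @param f sampling fraction (default 0.05).
#' @param seed master seed; each set uses a derived stream
#'   ([derive_seed()]).
#' @param monitored descriptor names validated by the Z-test (default: the
#'   24-descriptor WBN block).
#' @param alpha significance level for the per-descriptor Z-test.
#' @param exclude_n how many lowest-aggregate-mean sets to flag for
#'   exclusion (default 1; set 0 to keep all).
#' @return an object of class `sample_plan`.
#' @export
sample_plan <- function(k = 15L, f = 0.05, seed = 1L,
                        monitored = wbn_names(), alpha = 0.05,
                        exclude_n = 1L) {
  stopifnot(k >= 2L, f > 0, f <= 1, exclude_n >= 0L)
  structure(list(k = as.integer(k), f = f, seed = as.integer(seed),
                 monitored = monitored, alpha = alpha,
                 exclude_n = as.integer(exclude_n)),
            class = "sample_plan")
}

#' Split, mix and sample an imbalanced bioassay
#'
#' @param inactives vector (or list) of inactive compound ids, in input
#'   order.
#' @param actives vector (or list) of active compound ids.
#' @param plan a [sample_plan()].
#' @return list of `k` character vectors of sampled ids (class
#'   `sampled_sets`), each with attribute `pool_size`.
#' @export
split_mix_sample <- function(inactives, actives, plan = sample_plan()) {
  inactives <- as.character(unlist(inactives))
  actives <- as.character(unlist(actives))
  stopifnot(length(inactives) > 0, length(actives) > 0)
  k <- plan$k
  # contiguous near-equal chunks, sizes differing by at most 1
  sizes <- rep(length(inactives) %/% k, k)
  extra <- length(inactives) %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  out <- vector("list", k)
  for (s in seq_len(k)) {
    pool <- c(inactives[starts[s]:stops[s]], actives)
    n_draw <- round_half_up(plan$f * length(pool))
    if (n_draw < 1) {
      stop("sample size round(f * N) is zero for set ", s,
           " (f = ", plan$f, ", pool = ", length(pool), ")")
    }
    set.seed(derive_seed(plan$seed, s))
    draw <- sample(pool, n_draw, replace = FALSE)
    attr(draw, "pool_size") <- length(pool)
    out[[s]] <- draw
  }
  class(out) <- "sampled_sets"
  out
}

#' Validate sampled sets with one-sample Z-tests
#'
#' For every set and monitored descriptor the sampled mean is compared to
#' the population mean with `z = (xbar - mu) / (sigma / sqrt(n))` using the
#' population standard deviation, two-sided `p = 2 (1 - Phi(|z|))`. A set
#' passes when every monitored descriptor has `p >= alpha`. Independently,
#' the `exclude_n` sets with the lowest aggregate (summed) monitored means
#' are flagged for exclusion, mirroring the practice of dropping the set
#' with the lowest descriptor values.
#'
#' @param sets a `sampled_sets` object (list of id vectors).
#' @param population descriptor table of the full population with an `id`
#'   column and the monitored descriptor columns.
#' @param plan the [sample_plan()].
#' @return an object of class `ztest_report`: data.frame `tests` (set,
#'   descriptor, n, sample_mean, mu, sigma, z, p), logical `pass` per set,
#'   integer `excluded` set ids, and `retained` set ids.
#' @export
ztest_validate <- function(sets, population, plan = sample_plan()) {
  monitored <- intersect(plan$monitored, names(population))
  if (!length(monitored)) stop("population table lacks monitored descriptors")
  mu <- vapply(monitored, function(d) mean(population[[d]]), numeric(1))
  sigma <- vapply(monitored, function(d) stats::sd(population[[d]]), numeric(1))
  zero_sd <- sigma == 0 | !is.finite(sigma)
  if (any(zero_sd)) {
    warning("monitored descriptor(s) with zero population sd skipped: ",
            paste(monitored[zero_sd], collapse = ", "))
    monitored <- monitored[!zero_sd]
    mu <- mu[!zero_sd]; sigma <- sigma[!zero_sd]
  }
  rows <- list()
  agg <- numeric(length(sets))
  for (s in seq_along(sets)) {
    ids <- sets[[s]]
    stopifnot(length(ids) >= 2L)
    sub <- population[match(ids, population$id), monitored, drop = FALSE]
    xbar <- vapply(monitored, function(d) mean(sub[[d]]), numeric(1))
    n <- length(ids)
    z <- (xbar - mu) / (sigma / sqrt(n))
    p <- 2 * stats::pnorm(-abs(z))
    agg[s] <- sum(xbar)
    rows[[s]] <- data.frame(set = s, descriptor = monitored, n = n,
                            sample_mean = unname(xbar), mu = unname(mu),
                            sigma = unname(sigma), z = unname(z),
                            p = unname(p), stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  pass <- vapply(seq_along(sets), function(s) {
    all(tests$p[tests$set == s] >= plan$alpha)
  }, logical(1))
  excluded <- integer(0)
  if (plan$exclude_n > 0L) {
    excluded <- order(agg)[seq_len(min(plan$exclude_n, length(sets)))]
  }
  structure(list(tests = tests, pass = pass,
                 aggregate_mean = agg,
                 excluded = sort(excluded),
                 retained = setdiff(seq_along(sets), excluded),
                 alpha = plan$alpha),
            class = "ztest_report")
}

#' @export
print.ztest_report <- function(x, ...) {
  cat(sprintf("<ztest_report: %d sets, %d pass at alpha=%.3g, excluded: %s>\n",
              length(x$pass), sum(x$pass), x$alpha,
              if (length(x$excluded)) paste(x$excluded, collapse = ",")
              else "none"))
  invisible(x)
}

#' Write a Z-test report as CSV
#'
#' One row per (set, descriptor) with mean, z, p and the per-set verdicts.
#'
#' @param report a `ztest_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ztest_csv <- function(report, path) {
  df <- report$tests
  df$pass <- report$pass[df$set]
  df$excluded <- df$set %in% report$excluded
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
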