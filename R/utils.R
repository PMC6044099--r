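#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm rnorm runif rbinom cor sd quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a per-stream seed from a master seed
#'
#' Counter-based derivation so that independent stages (or set indices) get
#' distinct, reproducible RNG streams from one master seed. The result stays
#' below 2^31 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream counter.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # 64-bit-safe affine hash folded into [0, 2^31 - 1]
  m <- (as.double(master) %% 2147483647) + 1
  h <- (m * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(h)
}

# round-half-up (R's round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

# simple condition-tagged message so callers can suppress package chatter
ws_log <- function(...) message("[wbnscreen] ", ...)

# normalize an activity label vector to active/inactive/unknown
normalize_activity <- function(x) {
  if (is.null(x)) return(NULL)
  x0 <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x0))
  out[x0 %in% c("active", "1", "true", "yes")] <- "active"
  out[x0 %in% c("inactive", "0", "false", "no")] <- "inactive"
  bad <- !(x0 %in% c("active", "inactive", "1", "0", "true", "false",
                     "yes", "no", "unknown", "na", ""))
  if (any(bad)) {
    warning("unrecognized activity labels mapped to 'unknown': ",
            paste(unique(x0[bad]), collapse = ", "))
  }
  out
}

ws_extdata <- function(file) {
  path <- system.file("extdata", file, package = "wbnscreen")
  if (!nzchar(path)) stop("shipped data file not found: ", file)
  path
}
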