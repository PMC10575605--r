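# Internal helpers shared across modules.

# wrap an angle (radians) to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi + 1e-15 & a > 0] <- pi
  w
}

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("zero-length direction vector")
  v / n
}

deg2rad <- function(d) d * pi / 180

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits.  Used to stamp
# pipeline outputs with a configuration fingerprint.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 0x811C9DC5
  for (b in bytes) {
    # XOR touches only the low byte (b < 256); keep h as a double mod 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# clamp integer voxel index into [1, n]
clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

#' @useDynLib nrbrt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median coef predict residuals rnorm runif sd quantile
#'   cor lm
#' @importFrom utils write.csv read.csv head
NULL
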