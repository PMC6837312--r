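#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

vec3 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x)) stop(what, " must be a numeric 3-vector")
  x
}

vnorm <- function(x) sqrt(sum(x * x))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Derive a child RNG seed from a master seed and a counter
#'
#' Counter-based seed splitting: every subject, stage and permutation stream
#' in the pipeline draws its seed as `split_seed(master, counter)` with a
#' documented counter, so the whole experiment is a pure function of one
#' master seed.  The map is a full-period multiplicative congruence on the
#' Mersenne prime 2^31 - 1, so distinct counters give distinct seeds and the
#' result always fits a 32-bit integer.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(master, counter) {
  m <- 2147483647            # 2^31 - 1
  s <- (as.numeric(master) %% (m - 1)) + 1
  s <- (s * 48271) %% m
  s <- (s + 104729 * (as.numeric(counter) %% m)) %% m
  s <- (s * 69621) %% m
  as.integer(s + 1)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Uniform-parameter Catmull-Rom interpolation matrix: m samples through k
## control points (k >= 2).  End segments use reflected phantom points so the
## curve passes through the first and last control points.
catmull_rom_matrix <- function(k, m) {
  stopifnot(k >= 2L, m >= 2L)
  if (k == 2L) {
    t <- seq(0, 1, length.out = m)
    M <- cbind(1 - t, t)
    return(M)
  }
  nseg <- k - 1L
  u <- seq(0, nseg, length.out = m)
  seg <- pmin(floor(u), nseg - 1L)
  t <- u - seg
  M <- matrix(0, m, k + 2L)     # columns: phantom, P1..Pk, phantom
  t2 <- t * t
  t3 <- t2 * t
  b0 <- 0.5 * (-t + 2 * t2 - t3)
  b1 <- 0.5 * (2 - 5 * t2 + 3 * t3)
  b2 <- 0.5 * (t + 4 * t2 - 3 * t3)
  b3 <- 0.5 * (-t2 + t3)
  rows <- seq_len(m)
  j <- seg + 1L                 # control index of segment start in padded frame
  M[cbind(rows, j)] <- b0
  M[cbind(rows, j + 1L)] <- b1
  M[cbind(rows, j + 2L)] <- b2
  M[cbind(rows, j + 3L)] <- b3
  ## fold phantom points P0 = 2 P1 - P2 and P_{k+1} = 2 P_k - P_{k-1}
  A <- matrix(0, m, k)
  A[, 1:k] <- M[, 2:(k + 1)]
  A[, 1] <- A[, 1] + 2 * M[, 1]
  A[, 2] <- A[, 2] - M[, 1]
  A[, k] <- A[, k] + 2 * M[, k + 2]
  A[, k - 1] <- A[, k - 1] - M[, k + 2]
  A
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d * d)))
}

## FNV-1a hash of a serialized R object, reported as hex; used for manifest
## config fingerprints (no cryptographic claim).
fnv1a_hash <- function(object) {
  bytes <- as.integer(serialize(object, connection = NULL, version = 2))
  h <- 5381L
  for (b in bytes) h <- (bitwXor(h, b) * 33L) %% 16777216L
  sprintf("%06x", h)
}
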