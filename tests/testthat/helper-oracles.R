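## Independent oracles used to check the package's closed-form routines.
## These are deliberately implemented with different algorithms than the
## package (dense sampling, Floyd-Warshall, exhaustive enumeration).

## Dense-sampling minimum distance between a polyline and a segment:
## points every `step` mm along both curves, exact pairwise distances.
oracle_polyline_segment_distance <- function(pts, q0, q1, step = 0.05) {
  densify <- function(p0, p1) {
    len <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    cbind(p0[1] + t * (p1[1] - p0[1]),
          p0[2] + t * (p1[2] - p0[2]),
          p0[3] + t * (p1[3] - p0[3]))
  }
  a <- do.call(rbind, lapply(seq_len(nrow(pts) - 1L), function(i)
    densify(pts[i, ], pts[i + 1L, ])))
  b <- densify(q0, q1)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

## Floyd-Warshall all-pairs shortest paths (vs the package's BFS layers).
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_cpl <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_geff <- function(A) {
  D <- oracle_distances(A)
  mean(1 / D[row(D) != col(D)])
}

## Triangle-counting clustering by neighborhood pair enumeration.
oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + A[nb[a], nb[b]]
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

## Degree correlation by explicit edge-list construction.
oracle_assortativity <- function(A) {
  k <- rowSums(A)
  xs <- c(); ys <- c()
  n <- nrow(A)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (A[i, j] == 1) {
    xs <- c(xs, k[i], k[j]); ys <- c(ys, k[j], k[i])
  }
  if (length(xs) < 4 || sd(xs) == 0 || sd(ys) == 0) return(NaN)
  cor(xs, ys)
}

## All undirected graphs on n nodes (as adjacency matrices).
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(seq_len(2^m) - 1L, function(code) {
    A <- matrix(0, n, n)
    A[ut] <- as.integer(intToBits(code))[seq_len(m)]
    A + t(A)
  })
}

rand_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- rbinom(length(ut), 1, p)
  A + t(A)
}

## Exhaustive permutation p-value (all group-a subsets) for the
## mean-difference statistic.
exhaustive_perm_p <- function(a, b) {
  v <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  splits <- combn(length(v), na)
  stats <- apply(splits, 2, function(idx) mean(v[idx]) - mean(v[-idx]))
  mean(abs(stats) >= abs(obs) - 1e-12)
}

## Small fast cohort spec for pipeline-level tests.
tiny_cohort_spec <- function(seed = 1L, ...) {
  default_cohort_spec(n_per_group = 4, streamline_scale = 0.3, seed = seed, ...)
}

## Random polyline with points in a box (for geometry property tests).
rand_streamline <- function(npts = 4, half = 10) {
  matrix(runif(3 * npts, -half, half), npts, 3)
}

planted_nodes <- c("R_ram", "R_cam", "R_pm", "R_prec")
planted_edges <- c("R_cam|R_ram", "R_pm|R_ram", "R_prec|R_ram",
                   "R_cam|R_pm", "R_cam|R_prec", "R_pm|R_prec")

## First N(0,1) draw under a given seed (for the single-edge resampling case).
with_seed_value <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(1)
}

edge_keys <- function(df) {
  paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b), sep = "|")
}
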