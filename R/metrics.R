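## Global graph indices on binary undirected adjacency matrices, following
## the standard complex-network (Rubinov & Sporns) definitions.

check_adjacency <- function(adjacency) {
  a <- unclass(adjacency)
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary")
  if (any(a != t(a))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  a
}

## All-pairs shortest-path steps on a binary graph via breadth-first
## expansion of the reachability matrix; Inf marks unreachable pairs.
binary_distances <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) == 1
  frontier <- a > 0
  d <- 1
  while (any(newhit <- frontier & !reach & D == Inf)) {
    D[newhit] <- d
    reach <- reach | frontier
    frontier <- (frontier %*% a) > 0
    d <- d + 1
    if (d > n) break
  }
  D
}

#' Mean clustering coefficient of a binary graph
#'
#' Average over nodes of the local clustering coefficient
#' `2 T_i / (k_i (k_i - 1))`, where `T_i` counts triangles through node `i`
#' and `k_i` is its degree; nodes of degree < 2 contribute 0.
#'
#' @param adjacency binary symmetric matrix, zero diagonal.
#' @return scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(adjacency) {
  a <- check_adjacency(adjacency)
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  mean(ci)
}

#' Characteristic path length of a binary graph
#'
#' Mean number of steps along shortest paths over all ordered pairs of
#' distinct, mutually reachable nodes; disconnected pairs are excluded
#' rather than penalized.
#'
#' @inheritParams clustering_coefficient
#' @return scalar (NaN when no pair of nodes is connected).
#' @export
characteristic_path_length <- function(adjacency) {
  a <- check_adjacency(adjacency)
  D <- binary_distances(a)
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0L) return(NaN)
  mean(fin)
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered pairs of distinct nodes of the inverse shortest-path
#' length, with `1/Inf = 0` for disconnected pairs.
#'
#' @inheritParams clustering_coefficient
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adjacency) {
  a <- check_adjacency(adjacency)
  D <- binary_distances(a)
  inv <- 1 / D[row(D) != col(D)]
  mean(inv)
}

#' Degree assortativity of a binary graph
#'
#' Pearson correlation of the degrees at the two ends of every edge, each
#' undirected edge counted in both orientations.  Undefined (NaN, with a
#' warning) when the endpoint degrees have zero variance, e.g. on regular
#' graphs such as complete graphs.
#'
#' @inheritParams clustering_coefficient
#' @return scalar in `[-1, 1]`, or NaN when degenerate.
#' @export
assortativity <- function(adjacency) {
  a <- check_adjacency(adjacency)
  e <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  if (nrow(e) < 2L) stop("assortativity needs at least 2 edges")
  k <- rowSums(a)
  x <- c(k[e[, 1]], k[e[, 2]])
  y <- c(k[e[, 2]], k[e[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("assortativity undefined: zero degree variance over edge endpoints")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Nodal strength of a weighted matrix
#'
#' Row sums of a symmetric weighted connectivity matrix.  Strengths can be
#' negative after Gaussian resampling.
#'
#' @param weighted_matrix symmetric matrix with zero diagonal.
#' @return named numeric vector of node strengths.
#' @export
nodal_strength <- function(weighted_matrix) {
  w <- as.matrix(unclass(weighted_matrix))
  if (any(abs(w - t(w)) > 1e-12)) stop("weighted matrix must be symmetric")
  if (any(diag(w) != 0)) stop("weighted matrix must have a zero diagonal")
  s <- rowSums(w)
  names(s) <- rownames(w)
  s
}

#' All four global indices of one subject's adjacency matrix
#'
#' @inheritParams clustering_coefficient
#' @return named numeric vector: `clustering`, `char_path_length`,
#'   `global_efficiency`, `assortativity`.
#' @export
graph_indices <- function(adjacency) {
  c(clustering = clustering_coefficient(adjacency),
    char_path_length = characteristic_path_length(adjacency),
    global_efficiency = global_efficiency(adjacency),
    assortativity = suppressWarnings(
      tryCatch(assortativity(adjacency), error = function(e) NaN)))
}
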