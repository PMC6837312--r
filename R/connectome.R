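#' Parcellation as node centroids with a capture radius
#'
#' The synthetic parcellation assigns a 3-D endpoint to the nearest node
#' centroid provided it lies within the capture radius; otherwise the
#' endpoint is unassigned.  (A label-volume lookup used with real data plays
#' the same role; the assignment rule is deterministic either way.)
#'
#' @param centroids numeric matrix (nodes x 3), mm.
#' @param labels node labels (default `node01`, ...).
#' @param capture_radius maximum endpoint-to-centroid distance (mm).
#' @export
parcellation <- function(centroids, labels = NULL, capture_radius = 4) {
  centroids <- as.matrix(centroids)
  stopifnot(ncol(centroids) == 3L, nrow(centroids) >= 2L, capture_radius > 0)
  if (is.null(labels)) labels <- sprintf("node%02d", seq_len(nrow(centroids)))
  stopifnot(length(labels) == nrow(centroids), !anyDuplicated(labels))
  structure(list(centroids = centroids, labels = labels,
                 node_count = nrow(centroids), capture_radius = capture_radius),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", x$node_count, "nodes, capture radius",
      x$capture_radius, "mm\n")
  invisible(x)
}

nearest_node <- function(pts, parc) {
  d2 <- outer(rowSums(pts^2), rowSums(parc$centroids^2), "+") -
    2 * pts %*% t(parc$centroids)
  idx <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(pts)), idx)], 0))
  idx[dist > parc$capture_radius] <- NA_integer_
  idx
}

#' Remove streamlines longer than a maximum arc length
#'
#' Overlong streamlines are a known source of false-positive connections;
#' the default 200 mm cap mirrors standard whole-brain tracking practice.
#' Streamlines with arc length strictly greater than `max_length` are
#' removed; a streamline of exactly `max_length` is kept.
#'
#' @param tractogram a [tractogram()].
#' @param max_length maximum polyline arc length (mm, > 0).
#' @export
filter_by_length <- function(tractogram, max_length = 200) {
  stopifnot(inherits(tractogram, "tractogram"), max_length > 0)
  len <- streamline_lengths(tractogram)
  subset_streamlines(tractogram, which(len <= max_length))
}

#' Assign streamline endpoints to parcellation nodes
#'
#' Each terminal point is assigned to the nearest node centroid within the
#' capture radius.  Streamlines with an unassigned endpoint or with both
#' endpoints on the same node are rejected; rejection is a normal outcome
#' tallied for QC, not an error.
#'
#' @param tractogram a [tractogram()].
#' @param parc a [parcellation()].
#' @return data.frame with one row per streamline: `node_a`, `node_b`
#'   (NA when unassigned), `accepted`, and `reason`
#'   (`"ok"`, `"unassigned_endpoint"`, `"same_node"`).
#' @export
endpoints_to_nodes <- function(tractogram, parc) {
  stopifnot(inherits(tractogram, "tractogram"), inherits(parc, "parcellation"))
  ns <- n_streamlines(tractogram)
  if (ns == 0L)
    return(data.frame(node_a = integer(0), node_b = integer(0),
                      accepted = logical(0), reason = character(0)))
  ep <- tractogram_endpoints(tractogram)
  a <- nearest_node(ep$first, parc)
  b <- nearest_node(ep$last, parc)
  reason <- rep("ok", ns)
  reason[!is.na(a) & !is.na(b) & a == b] <- "same_node"
  reason[is.na(a) | is.na(b)] <- "unassigned_endpoint"
  data.frame(node_a = a, node_b = b, accepted = reason == "ok", reason = reason)
}

new_connectivity_matrix <- function(values, labels, weight_kind) {
  dimnames(values) <- list(labels, labels)
  attr(values, "weight_kind") <- weight_kind
  values
}

#' Build NOS and TW-FA connectivity matrices from one tractogram
#'
#' For every accepted streamline (see [endpoints_to_nodes()]) the NOS matrix
#' counts one connection between its endpoint nodes, and the TW-FA matrix
#' accumulates the streamline's mean per-point FA (track-weighted sum).
#' Both matrices are symmetric with a zero diagonal; construction is
#' invariant to streamline ordering and to reversing any streamline's point
#' order.
#'
#' @param tractogram a [tractogram()].
#' @param parc a [parcellation()].
#' @return list with `nos`, `twfa` (n x n matrices with a `weight_kind`
#'   attribute) and `qc` (the [endpoints_to_nodes()] table).
#' @export
build_matrices <- function(tractogram, parc) {
  assign <- endpoints_to_nodes(tractogram, parc)
  n <- parc$node_count
  nos <- matrix(0, n, n)
  twfa <- matrix(0, n, n)
  keep <- which(assign$accepted)
  if (length(keep)) {
    sid <- rep.int(seq_len(n_streamlines(tractogram)), tractogram$npts)
    mean_fa <- as.vector(rowsum(tractogram$fa, sid) / tractogram$npts)
    i <- pmin(assign$node_a[keep], assign$node_b[keep])
    j <- pmax(assign$node_a[keep], assign$node_b[keep])
    for (k in seq_along(keep)) {
      nos[i[k], j[k]] <- nos[i[k], j[k]] + 1
      twfa[i[k], j[k]] <- twfa[i[k], j[k]] + mean_fa[keep[k]]
    }
    nos <- nos + t(nos)
    twfa <- twfa + t(twfa)
  }
  list(nos = new_connectivity_matrix(nos, parc$labels, "NOS"),
       twfa = new_connectivity_matrix(twfa, parc$labels, "TWFA"),
       qc = assign)
}

#' Group-level edge inclusion mask
#'
#' An edge is included when it is present (NOS > 0) in a strict majority of
#' the control subjects AND in a strict majority of the patient subjects.
#' An edge present in exactly half of either sample is excluded.
#'
#' @param control_matrices,patient_matrices lists of NOS matrices (same
#'   dimension).
#' @return symmetric logical matrix with zero (FALSE) diagonal.
#' @export
group_edge_mask <- function(control_matrices, patient_matrices) {
  stopifnot(length(control_matrices) >= 1L, length(patient_matrices) >= 1L)
  n <- nrow(control_matrices[[1]])
  for (m in c(control_matrices, patient_matrices))
    if (!all(dim(m) == c(n, n))) stop("matrix dimension mismatch")
  pres <- function(ms) Reduce(`+`, lapply(ms, function(m) (m > 0) * 1))
  mask <- (pres(control_matrices) > length(control_matrices) / 2) &
    (pres(patient_matrices) > length(patient_matrices) / 2)
  diag(mask) <- FALSE
  mask
}

#' Rank-based Gaussian resampling of a weighted connectivity matrix
#'
#' Replaces the N nonzero upper-triangle weights, rank for rank, by the
#' sorted values of N fresh draws from the unit Gaussian: the smallest raw
#' weight receives the smallest draw, and so on until all raw values are
#' replaced.  Absent edges (structural zeros) stay zero; ties among raw
#' weights are broken by stable input order; symmetry is restored.  The
#' output distribution over included edges is exactly Gaussian, which makes
#' the non-normal raw TW-FA weights comparable across subjects.
#'
#' @param matrix a symmetric weighted connectivity matrix with >= 1 nonzero
#'   upper-triangle entry.
#' @param rng_seed seed for the Gaussian draws (NULL = current RNG stream).
#' @return resampled matrix (`weight_kind` attribute `"gaussianized"`).
#' @export
gaussian_resample <- function(matrix, rng_seed = NULL) {
  m <- unclass(matrix)
  ut <- upper.tri(m)
  nz <- which(ut & m != 0)
  if (length(nz) == 0L) stop("all-zero matrix: nothing to resample")
  with_seed(rng_seed, {
    draws <- sort(stats::rnorm(length(nz)))
    rk <- rank(m[nz], ties.method = "first")
    out <- m
    out[nz] <- draws[rk]
    out[lower.tri(out)] <- t(out)[lower.tri(out)]
    new_connectivity_matrix(out, rownames(m), "gaussianized")
  })
}

#' Binary adjacency from a weighted or count matrix
#'
#' @param matrix connectivity matrix.
#' @param mask optional logical edge mask applied before binarization.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @export
binarize <- function(matrix, mask = NULL) {
  a <- (unclass(matrix) != 0) * 1
  if (!is.null(mask)) a <- a * (mask * 1)
  diag(a) <- 0
  new_connectivity_matrix(a, rownames(matrix), "binary")
}
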