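#' Permutation test for a group difference in a global index
#'
#' Tests the difference of group means by relabeling: the null distribution
#' is built from `n_perm` random reassignments of subjects to groups, and
#' the two-sided p-value uses the add-one estimator
#' `p = (1 + #{|perm stat| >= |observed|}) / (1 + n_perm)`, so `p` is never
#' exactly zero and never below `1/(n_perm + 1)`.  When every subject in
#' both groups carries the same value the test is degenerate and returns
#' `p = 1`.
#'
#' @param values_a,values_b per-subject index values (each length >= 2).
#' @param n_perm number of permutations.
#' @param seed RNG seed (NULL = current stream).
#' @return object of class `perm_test`: `statistic` (mean_a - mean_b),
#'   `p_value`, `n_perm`, `seed`.
#' @export
permutation_test_index <- function(values_a, values_b, n_perm = 10000,
                                   seed = NULL) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L, n_perm >= 1)
  na <- length(values_a)
  v <- c(values_a, values_b)
  n <- length(v)
  obs <- mean(values_a) - mean(values_b)
  total <- sum(v)
  nb <- n - na
  stat_from_sum <- function(sa) sa / na - (total - sa) / nb
  exceed <- with_seed(seed, {
    sums <- vapply(seq_len(n_perm),
                   function(i) sum(v[sample.int(n, na)]), numeric(1))
    sum(abs(stat_from_sum(sums)) >= abs(obs) - 1e-12)
  })
  structure(list(statistic = obs, p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> mean difference %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

## Pooled or Welch two-sample t for one variable; returns t, df, p, variant.
gated_t <- function(a, b, gate_alpha = 0.05) {
  va <- stats::var(a); vb <- stats::var(b)
  flagged <- FALSE
  if (va == 0 && vb == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(t = 0, p = p, variant = "degenerate", flagged = TRUE,
                normal_ok = NA, var_ok = NA))
  }
  sw <- function(x) {
    if (stats::sd(x) == 0 || length(x) < 3L) return(0)   # cannot confirm normality
    stats::shapiro.test(x)$p.value
  }
  normal_ok <- sw(a) > gate_alpha && sw(b) > gate_alpha
  var_ok <- if (va > 0 && vb > 0)
    stats::var.test(a, b)$p.value > gate_alpha else FALSE
  if (normal_ok && var_ok) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    variant <- "pooled"
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    variant <- "welch"
    flagged <- TRUE
  }
  list(t = unname(tt$statistic), p = tt$p.value, variant = variant,
       flagged = flagged, normal_ok = normal_ok, var_ok = var_ok)
}

#' Gated nodal-strength t-tests with FDR correction
#'
#' For every node, compares the two groups' strengths with a two-sample
#' t-test gated by a Shapiro-Wilk normality check on each group and an F
#' test of variance homogeneity: when both gates pass, the pooled-variance
#' t-test is used; otherwise the Welch test is used and the node is flagged.
#' Raw p-values are corrected across nodes with Benjamini-Hochberg FDR.
#'
#' @param controls,patients matrices (subjects x nodes) or lists of
#'   per-subject strength vectors.
#' @param alpha significance level applied to the adjusted p-values.
#' @param gate_alpha level of the Shapiro-Wilk / F-test gates.
#' @return data.frame, one row per node: `node`, `t`, `p`, `p_fdr`,
#'   `mean_control`, `mean_patient`, `decrease` (strength lower in
#'   patients), `significant`, `variant`, `flagged`.
#' @export
nodal_strength_tests <- function(controls, patients, alpha = 0.05,
                                 gate_alpha = 0.05) {
  as_mat <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  A <- as_mat(controls)
  B <- as_mat(patients)
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 3L, nrow(B) >= 3L)
  res <- lapply(seq_len(ncol(A)), function(j) gated_t(A[, j], B[, j], gate_alpha))
  nodes <- colnames(A)
  if (is.null(nodes)) nodes <- sprintf("node%02d", seq_len(ncol(A)))
  out <- data.frame(
    node = nodes,
    t = vapply(res, `[[`, 0, "t"),
    p = vapply(res, `[[`, 0, "p"),
    mean_control = colMeans(A),
    mean_patient = colMeans(B),
    variant = vapply(res, `[[`, "", "variant"),
    flagged = vapply(res, `[[`, TRUE, "flagged"),
    row.names = NULL)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$decrease <- out$mean_patient < out$mean_control
  out$significant <- out$p_fdr < alpha
  out
}

## Vectorized pooled two-sample t statistics over the columns of X for a
## given index set of group-1 rows.
pooled_t_cols <- function(X, idx_a) {
  na <- length(idx_a)
  nb <- nrow(X) - na
  sa <- colSums(X[idx_a, , drop = FALSE])
  sb <- colSums(X) - sa
  qa <- colSums(X[idx_a, , drop = FALSE]^2)
  qb <- colSums(X^2) - qa
  ma <- sa / na
  mb <- sb / nb
  sp2 <- (pmax(qa - na * ma^2, 0) + pmax(qb - nb * mb^2, 0)) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

max_component_extent <- function(t_vals, crit, edges, n_nodes) {
  best <- 0
  for (sgn in c(1, -1)) {
    sel <- which(!is.na(t_vals) & sgn * t_vals > crit)
    if (!length(sel)) next
    g <- igraph::graph_from_edgelist(edges[sel, , drop = FALSE], directed = FALSE)
    comp <- igraph::components(g)
    memb <- comp$membership[edges[sel, 1]]
    best <- max(best, max(tabulate(memb)))
  }
  best
}

#' Network-based statistic (NBS) with component-extent FWER control
#'
#' The four-step NBS procedure: (1) a two-sample t-test on every included
#' edge (pooled-variance, controls minus patients); (2) a primary threshold
#' at the t-value of the two-sided uncorrected `primary_alpha`, forming the
#' suprathreshold edge set; (3) extraction of the connected components of
#' that set, scored by extent (edge count), separately for decrease
#' (`t > 0`) and increase (`t < 0`) edges; (4) a permutation null of the
#' maximum component extent under group relabeling, iterated `n_perm` times.
#' Component p-values use the add-one estimator and control the family-wise
#' error rate at the component level; a component is significant when
#' `p < alpha`.  Only edges allowed by `edge_mask` are tested.
#'
#' @param control_matrices,patient_matrices lists of symmetric weighted (or
#'   count) matrices, one per subject.
#' @param edge_mask symmetric logical inclusion matrix (see
#'   [group_edge_mask()]).
#' @param primary_alpha two-sided uncorrected alpha defining the primary
#'   t threshold.
#' @param n_perm permutations for the max-extent null.
#' @param alpha component-level significance threshold.
#' @param seed RNG seed.
#' @return object of class `nbs_result`: `components` (list with `edges`
#'   data.frame, `extent`, `p`, `sign`, `significant`), `t_threshold`,
#'   `edge_stats` (per tested edge), `null_max_extent`, `n_perm`, `seed`.
#' @export
nbs <- function(control_matrices, patient_matrices, edge_mask,
                primary_alpha = 0.001, n_perm = 5000, alpha = 0.05,
                seed = NULL) {
  stopifnot(length(control_matrices) >= 2L, length(patient_matrices) >= 2L)
  n_nodes <- nrow(edge_mask)
  eidx <- which(edge_mask & upper.tri(edge_mask))
  if (!length(eidx)) stop("edge mask is empty")
  ## (row, col) of each upper-triangle index, column-major; row < col
  edges <- cbind((eidx - 1L) %% n_nodes + 1L, (eidx - 1L) %/% n_nodes + 1L)
  X <- rbind(
    do.call(rbind, lapply(control_matrices, function(m) unclass(m)[eidx])),
    do.call(rbind, lapply(patient_matrices, function(m) unclass(m)[eidx])))
  na <- length(control_matrices)
  ntot <- nrow(X)
  df <- ntot - 2
  crit <- stats::qt(1 - primary_alpha / 2, df)
  t_obs <- pooled_t_cols(X, seq_len(na))

  labels <- rownames(control_matrices[[1]])
  if (is.null(labels)) labels <- sprintf("node%02d", seq_len(n_nodes))
  components <- list()
  for (sgn in c(1, -1)) {
    sel <- which(!is.na(t_obs) & sgn * t_obs > crit)
    if (!length(sel)) next
    g <- igraph::graph_from_edgelist(edges[sel, , drop = FALSE], directed = FALSE)
    memb <- igraph::components(g)$membership
    ce <- memb[edges[sel, 1]]
    for (cid in unique(ce)) {
      rows <- sel[ce == cid]
      components[[length(components) + 1L]] <- list(
        edges = data.frame(node_a = labels[edges[rows, 1]],
                           node_b = labels[edges[rows, 2]],
                           t = t_obs[rows]),
        extent = length(rows),
        sign = if (sgn > 0) "decrease" else "increase")
    }
  }

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ntot, na)
      max_component_extent(pooled_t_cols(X, idx), crit, edges, n_nodes)
    }, numeric(1))
  })
  for (i in seq_along(components)) {
    ext <- components[[i]]$extent
    p <- (1 + sum(null_max >= ext)) / (1 + n_perm)
    components[[i]]$p <- p
    components[[i]]$significant <- p < alpha
  }
  ## order components by decreasing extent
  if (length(components))
    components <- components[order(-vapply(components, `[[`, 0, "extent"))]
  structure(list(components = components, t_threshold = crit,
                 primary_alpha = primary_alpha, alpha = alpha,
                 edge_stats = data.frame(node_a = labels[edges[, 1]],
                                         node_b = labels[edges[, 2]],
                                         t = t_obs),
                 null_max_extent = null_max, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %d tested edges, t threshold %.3f, %d component(s)\n",
              nrow(x$edge_stats), x$t_threshold, length(x$components)))
  for (comp in x$components)
    cat(sprintf("  %s component: extent %d, FWER p = %.4g%s\n", comp$sign,
                comp$extent, comp$p, if (comp$significant) " *" else ""))
  invisible(x)
}
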