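#' Experiment configuration
#'
#' Bundles every knob of the virtual-ventriculostomy experiment: cohort
#' design, instrument radius, streamline length cap, permutation counts,
#' thresholds, the master seed, and the acquisition profiles.  Profiles
#' emulate complementary acquisitions (e.g. a high-angular-resolution and a
#' high-spatial-resolution field) as generator settings; results significant
#' in both profiles form the intersection report.
#'
#' @param profile `"desk"` (12 nodes, 8 subjects/group, reduced permutation
#'   counts) or `"full"` (44 subjects/group, 10K/5K permutations).
#' @param n_per_group subjects per group (overrides the profile default).
#' @param instrument_radius cylinder radius in mm (2 mm = 4 mm diameter).
#' @param max_length streamline length cap in mm.
#' @param n_perm_index,n_perm_nbs permutation counts for the global-index
#'   tests and the NBS.
#' @param primary_alpha NBS primary (edge-level) two-sided alpha.
#' @param alpha significance threshold for corrected p-values.
#' @param seed master seed; every stage seed is split from it.
#' @param nbs_weights run the NBS on `"gaussianized"` TW-FA matrices
#'   (default) or raw `"nos"` count matrices.
#' @param minor_bundles include the stochastic low-count bundles in the
#'   cohort design.
#' @param acquisitions named list of per-profile generator settings, each a
#'   list with `streamline_scale`, `jitter_sd`, `fa_sd`.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "full"),
                              n_per_group = NULL,
                              instrument_radius = 2,
                              max_length = 200,
                              n_perm_index = NULL,
                              n_perm_nbs = NULL,
                              primary_alpha = 0.001,
                              alpha = 0.05,
                              seed = 1L,
                              nbs_weights = c("gaussianized", "nos"),
                              minor_bundles = TRUE,
                              acquisitions = list(
                                hi_angular = list(streamline_scale = 1,
                                                  jitter_sd = 0.5, fa_sd = 0.05),
                                hi_spatial = list(streamline_scale = 0.6,
                                                  jitter_sd = 0.35, fa_sd = 0.04))) {
  profile <- match.arg(profile)
  nbs_weights <- match.arg(nbs_weights)
  if (is.null(n_per_group)) n_per_group <- if (profile == "desk") 8L else 44L
  if (is.null(n_perm_index)) n_perm_index <- if (profile == "desk") 1000L else 10000L
  if (is.null(n_perm_nbs)) n_perm_nbs <- if (profile == "desk") 500L else 5000L
  stopifnot(instrument_radius > 0, max_length > 0, n_perm_index >= 1,
            n_perm_nbs >= 1, primary_alpha > 0, primary_alpha < 1,
            alpha > 0, alpha < 1, length(acquisitions) >= 1)
  structure(list(profile = profile, n_per_group = as.integer(n_per_group),
                 instrument_radius = instrument_radius,
                 max_length = max_length,
                 n_perm_index = as.integer(n_perm_index),
                 n_perm_nbs = as.integer(n_perm_nbs),
                 primary_alpha = primary_alpha, alpha = alpha,
                 seed = as.integer(seed), nbs_weights = nbs_weights,
                 minor_bundles = minor_bundles, acquisitions = acquisitions),
            class = "experiment_config")
}

apply_mask <- function(m, mask) {
  out <- unclass(m) * (mask * 1)
  new_connectivity_matrix(out, rownames(m), attr(m, "weight_kind"))
}

## One control-vs-patient comparison: mask, resample, three stages.
run_comparison <- function(ctrl, pats, config, seed_base) {
  mask <- group_edge_mask(lapply(ctrl, `[[`, "nos"), lapply(pats, `[[`, "nos"))
  gaussify <- function(mats, offset)
    lapply(seq_along(mats), function(i)
      gaussian_resample(apply_mask(mats[[i]]$twfa, mask),
                        rng_seed = split_seed(seed_base, offset + i)))
  g_ctrl <- gaussify(ctrl, 100L)
  g_pat <- gaussify(pats, 200L)
  adj <- function(mats) lapply(mats, function(m) binarize(m$nos, mask))
  a_ctrl <- adj(ctrl)
  a_pat <- adj(pats)

  ## stage 1: global indices + permutation tests, FDR over the four indices
  idx_ctrl <- t(vapply(a_ctrl, graph_indices, numeric(4)))
  idx_pat <- t(vapply(a_pat, graph_indices, numeric(4)))
  stage1 <- do.call(rbind, lapply(colnames(idx_ctrl), function(nm) {
    pt <- permutation_test_index(idx_ctrl[, nm], idx_pat[, nm],
                                 n_perm = config$n_perm_index,
                                 seed = split_seed(seed_base, 300L + match(nm, colnames(idx_ctrl))))
    data.frame(index = nm, mean_control = mean(idx_ctrl[, nm]),
               sd_control = stats::sd(idx_ctrl[, nm]),
               mean_patient = mean(idx_pat[, nm]),
               sd_patient = stats::sd(idx_pat[, nm]),
               diff = pt$statistic, p = pt$p_value)
  }))
  stage1$p_fdr <- stats::p.adjust(stage1$p, method = "BH")

  ## stage 2: nodal strength, gated t-tests, FDR over nodes
  s_ctrl <- t(vapply(g_ctrl, nodal_strength, numeric(nrow(mask))))
  s_pat <- t(vapply(g_pat, nodal_strength, numeric(nrow(mask))))
  stage2 <- nodal_strength_tests(s_ctrl, s_pat, alpha = config$alpha)

  ## stage 3: NBS
  nbs_ctrl <- if (config$nbs_weights == "gaussianized") g_ctrl
  else lapply(ctrl, `[[`, "nos")
  nbs_pat <- if (config$nbs_weights == "gaussianized") g_pat
  else lapply(pats, `[[`, "nos")
  stage3 <- nbs(nbs_ctrl, nbs_pat, mask,
                primary_alpha = config$primary_alpha,
                n_perm = config$n_perm_nbs, alpha = config$alpha,
                seed = split_seed(seed_base, 400L))
  list(edge_mask = mask, stage1 = stage1, stage2 = stage2, stage3 = stage3)
}

run_profile <- function(config, acq_name, acq, prof_seed) {
  spec <- default_cohort_spec(
    n_per_group = config$n_per_group,
    streamline_scale = acq$streamline_scale,
    jitter_sd = acq$jitter_sd, fa_sd = acq$fa_sd,
    minor_bundles = config$minor_bundles, seed = prof_seed)
  cohort <- generate_cohort(spec)
  parc <- spec$parcellation
  removal <- list()
  mats <- lapply(cohort, function(tr) {
    tr <- filter_by_length(tr, config$max_length)
    if (tr$group %in% c("left", "right")) {
      ins <- build_instrument(tr$head, tr$group, radius = config$instrument_radius)
      les <- apply_lesion(tr, ins)
      removal[[tr$subject]] <<- length(les$report$transected_ids) /
        max(1L, length(les$report$min_distance))
      tr <- les$tractogram
    }
    m <- build_matrices(tr, parc)
    m$group <- tr$group
    m
  })
  groups <- vapply(mats, `[[`, "", "group")
  ctrl <- mats[groups == "control"]
  comparisons <- list(
    left = run_comparison(ctrl, mats[groups == "left"], config,
                          split_seed(prof_seed, 11L)),
    right = run_comparison(ctrl, mats[groups == "right"], config,
                           split_seed(prof_seed, 12L)))
  list(acquisition = acq_name, spec = spec, comparisons = comparisons,
       removal_fraction = unlist(removal))
}

significant_edges <- function(comparison, sign = NULL) {
  out <- character(0)
  for (comp in comparison$stage3$components) {
    if (!isTRUE(comp$significant)) next
    if (!is.null(sign) && comp$sign != sign) next
    e <- comp$edges
    out <- c(out, paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b),
                        sep = "|"))
  }
  unique(out)
}

significant_nodes <- function(comparison) {
  s2 <- comparison$stage2
  s2$node[s2$significant]
}

#' Run the full virtual-ventriculostomy experiment
#'
#' Executes, per acquisition profile: cohort generation, streamline length
#' filtering, left/right lesion application to the two patient groups
#' (controls untouched), connectivity matrix construction, group edge
#' masking, per-subject rank-Gaussian resampling, and the three inference
#' stages (global-index permutation tests; gated nodal t-tests with FDR;
#' NBS).  With two or more profiles, results significant in both of the
#' first two profiles are intersected.  The whole run is a pure function of
#' the configuration (including its seed).
#'
#' @param config an [experiment_config()].
#' @return object of class `vlc_experiment`: `profiles` (per-acquisition
#'   results), `intersection` (shared significant edges/nodes per side, when
#'   >= 2 profiles), and `manifest` (config hash, seeds, stage log,
#'   timestamps, package version).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  manifest <- list(config_hash = fnv1a_hash(unclass(config)),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("vlconn")),
                   started = format(Sys.time(), usetz = TRUE),
                   completed_stages = character(0))
  profiles <- list()
  for (i in seq_along(config$acquisitions)) {
    nm <- names(config$acquisitions)[i]
    res <- tryCatch(
      run_profile(config, nm, config$acquisitions[[i]],
                  split_seed(config$seed, 1000L * i)),
      error = function(e)
        stop(structure(class = c("vlc_stage_error", "error", "condition"),
                       list(message = paste0("profile '", nm, "' failed: ",
                                             conditionMessage(e)),
                            call = sys.call(-1), manifest = manifest))))
    profiles[[nm]] <- res
    manifest$completed_stages <- c(manifest$completed_stages, nm)
  }
  intersection <- NULL
  if (length(profiles) >= 2L)
    intersection <- intersect_results(profiles[[1]], profiles[[2]])
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  structure(list(profiles = profiles, intersection = intersection,
                 manifest = manifest, config = config),
            class = "vlc_experiment")
}

#' Intersect the significant results of two pipeline runs
#'
#' Emulates the dual-acquisition strategy of keeping only findings common to
#' both fields: for each lesion side, the significant NBS edge set (and the
#' FDR-significant node set) of the report is the intersection of the two
#' runs' sets.
#'
#' @param run_a,run_b per-profile result lists from [run_experiment()]
#'   (elements of `$profiles`), sharing node labels.
#' @return list per side with `edges` (character `"a|b"` keys) and `nodes`.
#' @export
intersect_results <- function(run_a, run_b) {
  out <- list()
  for (side in c("left", "right")) {
    ca <- run_a$comparisons[[side]]
    cb <- run_b$comparisons[[side]]
    out[[side]] <- list(
      edges = intersect(significant_edges(ca), significant_edges(cb)),
      nodes = intersect(significant_nodes(ca), significant_nodes(cb)))
  }
  out
}

#' @export
print.vlc_experiment <- function(x, ...) {
  cat("<vlc_experiment>", length(x$profiles), "acquisition profile(s), seed",
      x$manifest$seed, "\n")
  for (nm in names(x$profiles)) {
    pr <- x$profiles[[nm]]
    for (side in c("left", "right")) {
      cmp <- pr$comparisons[[side]]
      nsig <- sum(cmp$stage2$significant)
      ncomp <- sum(vapply(cmp$stage3$components, `[[`, TRUE, "significant"))
      cat(sprintf("  [%s/%s] global index min p = %.3g; %d significant node(s); %d significant NBS component(s)\n",
                  nm, side, min(cmp$stage1$p), nsig, ncomp))
    }
  }
  if (!is.null(x$intersection))
    for (side in c("left", "right"))
      cat(sprintf("  intersection/%s: %d edge(s), %d node(s)\n", side,
                  length(x$intersection[[side]]$edges),
                  length(x$intersection[[side]]$nodes)))
  invisible(x)
}
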