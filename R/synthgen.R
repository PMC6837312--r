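#' Bundle specification for the synthetic tractogram generator
#'
#' A bundle is a coherent set of streamlines connecting two parcellation
#' nodes along a common smooth trajectory through a list of waypoints, with
#' Gaussian lateral spread around that trajectory and per-point FA drawn from
#' a clipped Gaussian.
#'
#' @param node_a,node_b endpoint node indices.
#' @param n_streamlines number of streamlines to generate (>= 0).
#' @param waypoints list of 3-vectors (mm) the bundle is routed through
#'   (may be empty).
#' @param spread_sd per-axis Gaussian lateral spread of each control point
#'   (mm, >= 0).
#' @param fa_mean,fa_sd FA distribution parameters; `0 < fa_mean < 1`.
#' @param points_per_streamline minimum number of polyline points; the
#'   generator densifies further so point spacing never exceeds 1 mm.
#' @param name optional bundle label.
#' @export
bundle_spec <- function(node_a, node_b, n_streamlines, waypoints = list(),
                        spread_sd = 1, fa_mean = 0.45, fa_sd = 0.05,
                        points_per_streamline = 30L, name = NULL) {
  stopifnot(n_streamlines >= 0, spread_sd >= 0, fa_mean > 0, fa_mean < 1,
            fa_sd >= 0, points_per_streamline >= 2L, node_a != node_b)
  waypoints <- lapply(waypoints, vec3, what = "waypoint")
  structure(list(node_a = as.integer(node_a), node_b = as.integer(node_b),
                 n_streamlines = as.integer(n_streamlines),
                 waypoints = waypoints, spread_sd = spread_sd,
                 fa_mean = fa_mean, fa_sd = fa_sd,
                 points_per_streamline = as.integer(points_per_streamline),
                 name = if (is.null(name)) paste0("b", node_a, "_", node_b) else name),
            class = "bundle_spec")
}

#' Cohort specification for the synthetic generator
#'
#' Describes a three-group virtual-ventriculostomy cohort: a template head,
#' a parcellation (node centroids with a capture radius), the bundle
#' architecture shared by all subjects, the inter-subject landmark/waypoint
#' jitter, and optional planted group effects.
#'
#' @param n_per_group subjects per group (>= 2; the full cohort has three
#'   groups: control, left lesion, right lesion).
#' @param parcellation a [parcellation()] (defines `node_count`).
#' @param bundles list of [bundle_spec()] objects.
#' @param head_template a [head_model()] all subjects are jittered from.
#' @param jitter_sd per-axis inter-subject Gaussian jitter of landmarks and
#'   waypoints (mm).
#' @param seed master seed; all per-subject randomness is split from it with
#'   [split_seed()].
#' @param effects optional list of planted group effects, each a list with
#'   fields `group` ("left"/"right"/"control"), `bundle` (name or index),
#'   and any of `nos_scale` (multiplies the streamline count) or `fa_shift`
#'   (added to `fa_mean`).
#' @export
cohort_spec <- function(n_per_group, parcellation, bundles,
                        head_template = head_model(), jitter_sd = 1,
                        seed = 1L, effects = list()) {
  stopifnot(n_per_group >= 2, inherits(parcellation, "parcellation"),
            length(bundles) >= 1L, jitter_sd >= 0,
            inherits(head_template, "head_model"))
  n <- parcellation$node_count
  for (b in bundles)
    if (b$node_a < 1 || b$node_a > n || b$node_b < 1 || b$node_b > n)
      stop("bundle endpoints must map to valid nodes")
  structure(list(n_per_group = as.integer(n_per_group),
                 parcellation = parcellation, bundles = bundles,
                 head_template = head_template, jitter_sd = jitter_sd,
                 seed = as.integer(seed), effects = effects),
            class = "cohort_spec")
}

#' Jittered per-subject head model
#'
#' Perturbs the template landmarks (nasion, both foramina) with independent
#' per-axis Gaussian noise of SD `jitter_sd`, then re-projects the nasion
#' radially onto the scalp sphere so it remains a scalp point.  Deterministic
#' for a fixed `(spec, subject_index, rng_seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index subject counter within the cohort (1-based).
#' @param rng_seed seed for the jitter draws (defaults to a
#'   [split_seed()] stream of the cohort seed).
#' @return a [head_model()].
#' @export
make_head_model <- function(spec, subject_index,
                            rng_seed = split_seed(spec$seed, subject_index)) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject_index >= 1, subject_index <= 3 * spec$n_per_group)
  tpl <- spec$head_template
  with_seed(rng_seed, {
    j <- matrix(stats::rnorm(9, sd = spec$jitter_sd), 3, 3)
    nas <- tpl$nasion + j[, 1]
    nas <- tpl$center + tpl$scalp_radius * unitize(nas - tpl$center)
    head_model(scalp_radius = tpl$scalp_radius, center = tpl$center,
               nasion = nas,
               foramen_left = tpl$foramen_left + j[, 2],
               foramen_right = tpl$foramen_right + j[, 3],
               midline_normal = tpl$midline_normal)
  })
}

## Apply the planted effects for one group to the bundle list.
bundles_for_group <- function(spec, group) {
  bundles <- spec$bundles
  names(bundles) <- vapply(bundles, function(b) b$name, "")
  for (ef in spec$effects) {
    if (!identical(ef$group, group)) next
    i <- if (is.character(ef$bundle)) match(ef$bundle, names(bundles)) else ef$bundle
    if (is.na(i)) stop("unknown bundle in planted effect: ", ef$bundle)
    b <- bundles[[i]]
    if (!is.null(ef$nos_scale))
      b$n_streamlines <- as.integer(round(b$n_streamlines * ef$nos_scale))
    if (!is.null(ef$fa_shift))
      b$fa_mean <- min(max(b$fa_mean + ef$fa_shift, 1e-3), 1 - 1e-3)
    bundles[[i]] <- b
  }
  bundles
}

FA_CLIP <- c(1e-4, 1 - 1e-4)

#' Generate one subject's synthetic tractogram
#'
#' Every bundle contributes exactly `n_streamlines` smooth polylines running
#' from its first node's region to its second node's region through the
#' bundle waypoints.  Each streamline perturbs every control point (endpoints
#' and waypoints) by independent per-axis `N(0, spread_sd^2)` offsets and is
#' interpolated with a Catmull-Rom spline sampled densely enough that point
#' spacing never exceeds 1 mm.  Per-point FA is drawn from
#' `N(fa_mean, fa_sd^2)` clipped into (0, 1).  Waypoints are additionally
#' jittered per subject by `N(0, jitter_sd^2)` (inter-subject anatomy),
#' reproducibly from the subject seed.
#'
#' @param spec a [cohort_spec()].
#' @param head the subject's [head_model()].
#' @param rng_seed integer seed making the tractogram deterministic.
#' @param group group label used to apply planted effects and recorded in
#'   the output.
#' @param subject subject label recorded in the output.
#' @return a [tractogram()].
#' @export
generate_tractogram <- function(spec, head, rng_seed, group = "control",
                                subject = NA_character_) {
  stopifnot(inherits(spec, "cohort_spec"))
  bundles <- bundles_for_group(spec, group)
  cent <- spec$parcellation$centroids
  with_seed(rng_seed, {
    pts_list <- list(); fa_list <- list(); npts <- integer(0); bname <- character(0)
    for (b in bundles) {
      if (b$n_streamlines == 0L) next
      ctrl <- rbind(cent[b$node_a, ],
                    if (length(b$waypoints)) do.call(rbind, b$waypoints),
                    cent[b$node_b, ])
      k <- nrow(ctrl)
      ## subject-level anatomical jitter of interior waypoints
      if (k > 2L && spec$jitter_sd > 0)
        ctrl[2:(k - 1), ] <- ctrl[2:(k - 1), , drop = FALSE] +
          matrix(stats::rnorm(3 * (k - 2), sd = spec$jitter_sd), k - 2, 3)
      base_len <- polyline_length(ctrl)
      m <- max(b$points_per_streamline,
               ceiling(3 * (base_len + 6 * b$spread_sd)) + 1L)
      M <- catmull_rom_matrix(k, m)
      off <- if (b$spread_sd > 0)
        matrix(stats::rnorm(3 * k * b$n_streamlines, sd = b$spread_sd),
               k, 3 * b$n_streamlines)
      else matrix(0, k, 3 * b$n_streamlines)
      ctrl_all <- matrix(ctrl, k, 3 * b$n_streamlines) + off
      pts_all <- M %*% ctrl_all                       # m x (3 n)
      pts <- matrix(0, m * b$n_streamlines, 3)
      for (ax in 1:3)
        pts[, ax] <- as.vector(pts_all[, seq(ax, 3 * b$n_streamlines, by = 3)])
      fa <- stats::rnorm(m * b$n_streamlines, b$fa_mean, b$fa_sd)
      fa <- pmin(pmax(fa, FA_CLIP[1]), FA_CLIP[2])
      pts_list[[length(pts_list) + 1L]] <- pts
      fa_list[[length(fa_list) + 1L]] <- fa
      npts <- c(npts, rep.int(m, b$n_streamlines))
      bname <- c(bname, rep.int(b$name, b$n_streamlines))
    }
    tractogram(do.call(rbind, c(pts_list, list(matrix(0, 0, 3)))),
               unlist(c(fa_list, list(numeric(0)))), npts,
               bundle = bname, head = head, group = group, subject = subject)
  })
}

#' Generate a full three-group cohort of synthetic tractograms
#'
#' Produces `3 * n_per_group` subjects labeled `control`, `left` and
#' `right` (lesion-side candidates; the lesion itself is applied by the
#' pipeline, not here).  The master seed fans out to per-subject head and
#' tractogram seeds through [split_seed()], so the cohort is a pure function
#' of `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @return list of [tractogram()] objects with `group`/`subject` labels and
#'   an attached per-subject `head_model`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(c("control", "left", "right"), each = spec$n_per_group)
  lapply(seq_along(groups), function(i) {
    head <- make_head_model(spec, i, split_seed(spec$seed, 2L * i))
    generate_tractogram(spec, head, split_seed(spec$seed, 2L * i + 1L),
                        group = groups[i],
                        subject = sprintf("%s_%02d", groups[i],
                                          ((i - 1L) %% spec$n_per_group) + 1L))
  })
}

## ---------------------------------------------------------------------------
## Default desk-scale study design.

#' Default parcellation and cohort design
#'
#' `default_parcellation()` lays out 12 cortical node centroids (6 per
#' hemisphere: four medial, two lateral) on a cortex shell inside the default
#' 80 mm scalp sphere.  `default_cohort_spec()` builds the desk-scale study
#' design around it: a deterministic redundant bundle architecture spanning
#' all nodes, a right anterior medial bundle complex (cingulum-like; the six
#' bundles form the complete graph on the four right medial nodes) routed
#' through the right Kocher-Monro instrument axis, its left mirror image
#' routed well clear of the left axis, broad callosal-fan-like commissural
#' bundles, and (optionally) low-count stochastic "minor" bundles whose
#' presence varies across subjects.
#'
#' The deliberate left/right asymmetry of the near-axis complex is the
#' planted analog of an anteroposterior paramedian bundle whose width is
#' comparable to the instrument's: the right complex is heavily transected by
#' the right instrument while the left trajectory meets no dense bundle.
#'
#' @param n_per_group subjects per group.
#' @param streamline_scale multiplies every bundle's streamline count
#'   (acquisition-profile knob).
#' @param jitter_sd inter-subject jitter (mm).
#' @param minor_bundles include the stochastic low-count bundles?
#' @param seed master cohort seed.
#' @param fa_sd per-point FA noise SD (acquisition-profile knob).
#' @return a [cohort_spec()] (`default_cohort_spec`) or a [parcellation()]
#'   (`default_parcellation`).
#' @export
default_cohort_spec <- function(n_per_group = 8, streamline_scale = 1,
                                jitter_sd = 0.5, minor_bundles = TRUE,
                                seed = 1L, fa_sd = 0.05) {
  parc <- default_parcellation()
  head <- head_model()
  cent <- parc$centroids
  n_of <- function(n) max(1L, as.integer(round(n * streamline_scale)))
  axis_pt <- function(ins, t) ins$entry + t * (ins$target - ins$entry)
  ins_r <- build_instrument(head, "right")
  ins_l <- build_instrument(head, "left")

  ## Right medial complex: K4 on nodes 7..10, each bundle crossing the right
  ## KM axis.  Distinct streamline counts keep the weight ranks stable.
  rk4 <- list(c(7L, 8L, 0.30, 60), c(7L, 9L, 0.40, 64), c(7L, 10L, 0.55, 68),
              c(8L, 9L, 0.45, 72), c(8L, 10L, 0.50, 76), c(9L, 10L, 0.60, 80))
  right_complex <- lapply(rk4, function(z)
    bundle_spec(z[1], z[2], n_of(z[4]), waypoints = list(axis_pt(ins_r, z[3])),
                spread_sd = 1.2, fa_mean = 0.55, fa_sd = fa_sd,
                name = sprintf("cingulum_r_%d_%d", z[1], z[2])))
  ## Left mirror complex routed ~10 mm clear of the left axis (displaced
  ## laterally and inferiorly, away from both instrument corridors).
  left_complex <- lapply(rk4, function(z) {
    wp <- axis_pt(ins_l, z[3])
    wp[1] <- -4          # paramedian corridor, ~10-18 mm medial of the axis
    wp[3] <- wp[3] - 5
    bundle_spec(z[1] - 6L, z[2] - 6L, n_of(z[4]), waypoints = list(wp),
                spread_sd = 1.2, fa_mean = 0.55, fa_sd = fa_sd,
                name = sprintf("cingulum_l_%d_%d", z[1] - 6L, z[2] - 6L))
  })
  ## Commissural callosal-fan-like bundles, crossing low near the midline.
  callosal <- list(
    bundle_spec(1L, 7L, n_of(150), waypoints = list(c(0, 35, 20)),
                spread_sd = 2, fa_mean = 0.60, fa_sd = fa_sd, name = "callosal_ant"),
    bundle_spec(4L, 10L, n_of(170), waypoints = list(c(0, -35, 22)),
                spread_sd = 2, fa_mean = 0.60, fa_sd = fa_sd, name = "callosal_post"),
    bundle_spec(2L, 8L, n_of(16), spread_sd = 1.5, fa_mean = 0.50,
                fa_sd = fa_sd, name = "callosal_sup"),
    bundle_spec(3L, 9L, n_of(14), spread_sd = 1.5, fa_mean = 0.50,
                fa_sd = fa_sd, name = "callosal_postsup"),
    bundle_spec(5L, 11L, n_of(10), spread_sd = 1.5, fa_mean = 0.50,
                fa_sd = fa_sd, name = "commissure_ant_lat"),
    bundle_spec(6L, 12L, n_of(12), spread_sd = 1.5, fa_mean = 0.50,
                fa_sd = fa_sd, name = "commissure_inf_lat"))
  ## Lateral association bundles and medial-lateral links (redundant backbone).
  assoc <- list(
    bundle_spec(11L, 12L, n_of(80), waypoints = list(c(55, 12, 8)),
                spread_sd = 1.5, fa_mean = 0.45, fa_sd = fa_sd, name = "assoc_r"),
    bundle_spec(5L, 6L, n_of(84), waypoints = list(c(-55, 12, 8)),
                spread_sd = 1.5, fa_mean = 0.45, fa_sd = fa_sd, name = "assoc_l"),
    bundle_spec(7L, 11L, n_of(56), waypoints = list(c(28, 38, 28)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "u_r_front"),
    bundle_spec(9L, 12L, n_of(48), waypoints = list(c(30, -18, 20)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "u_r_post"),
    bundle_spec(1L, 5L, n_of(52), waypoints = list(c(-28, 38, 28)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "u_l_front"),
    bundle_spec(3L, 6L, n_of(44), waypoints = list(c(-30, -18, 20)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "u_l_post"),
    bundle_spec(8L, 11L, n_of(36), spread_sd = 1.5, fa_mean = 0.42,
                fa_sd = fa_sd, name = "lat_r_cam"),
    bundle_spec(2L, 5L, n_of(38), spread_sd = 1.5, fa_mean = 0.42,
                fa_sd = fa_sd, name = "lat_l_cam"),
    bundle_spec(9L, 11L, n_of(30), waypoints = list(c(35, 5, 38)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "lat_r_pm"),
    bundle_spec(3L, 5L, n_of(32), waypoints = list(c(-35, 5, 38)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "lat_l_pm"),
    bundle_spec(10L, 12L, n_of(24), spread_sd = 1.5, fa_mean = 0.42,
                fa_sd = fa_sd, name = "lat_r_prec"),
    bundle_spec(4L, 6L, n_of(26), spread_sd = 1.5, fa_mean = 0.42,
                fa_sd = fa_sd, name = "lat_l_prec"),
    bundle_spec(7L, 12L, n_of(20), waypoints = list(c(35, 20, 5)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "lat_r_ram"),
    bundle_spec(1L, 6L, n_of(22), waypoints = list(c(-35, 20, 5)),
                spread_sd = 1.5, fa_mean = 0.42, fa_sd = fa_sd, name = "lat_l_ram"))
  minors <- if (minor_bundles) list(
    bundle_spec(2L, 6L, max(1L, n_of(2)), spread_sd = 2, fa_mean = 0.35,
                fa_sd = fa_sd, name = "minor_l"),
    bundle_spec(8L, 12L, max(1L, n_of(2)), spread_sd = 2, fa_mean = 0.35,
                fa_sd = fa_sd, name = "minor_r")) else list()
  cohort_spec(n_per_group = n_per_group, parcellation = parc,
              bundles = c(right_complex, left_complex, callosal, assoc, minors),
              head_template = head, jitter_sd = jitter_sd, seed = seed)
}

#' @rdname default_cohort_spec
#' @export
default_parcellation <- function() {
  right <- rbind(
    c(8, 45, 35),    # 7  rostral anterior medial
    c(10, 25, 52),   # 8  caudal anterior medial
    c(10, -25, 55),  # 9  posterior medial
    c(8, -45, 35),   # 10 precuneal medial
    c(45, 35, 25),   # 11 lateral frontal
    c(50, -10, -5))  # 12 lateral temporal
  left <- right * matrix(c(-1, 1, 1), 6, 3, byrow = TRUE)
  cent <- rbind(left, right)
  labels <- c(paste0("L_", c("ram", "cam", "pm", "prec", "latf", "latt")),
              paste0("R_", c("ram", "cam", "pm", "prec", "latf", "latt")))
  parcellation(cent, labels = labels, capture_radius = 4)
}
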