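#' Construct a spherical head model
#'
#' The head is modeled as a sphere (scalp) carrying the landmarks needed to
#' plan a frontal ventriculostomy: the nasion on the anterior midline of the
#' scalp, the left and right foramen of Monro targets in the interior, and
#' the midsagittal plane normal.  Coordinates are a right-handed RAS-like
#' millimetre frame: +x points to the subject's right, +y anterior,
#' +z superior; the midsagittal plane passes through `center` with normal
#' `midline_normal`.
#'
#' @param scalp_radius scalp sphere radius in mm.
#' @param center sphere center (3-vector, mm).
#' @param nasion scalp point at the anterior midline (3-vector, mm); must lie
#'   on the sphere to within 1e-6 mm.
#' @param foramen_left,foramen_right interior target points (3-vector, mm).
#' @param midline_normal unit normal of the midsagittal plane.
#' @return an object of class `head_model`.
#' @export
head_model <- function(scalp_radius = 80,
                       center = c(0, 0, 0),
                       nasion = center + c(0, scalp_radius, 0),
                       foramen_left = center + c(-4, 10, 5),
                       foramen_right = center + c(4, 10, 5),
                       midline_normal = c(1, 0, 0)) {
  center <- vec3(center, "center")
  nasion <- vec3(nasion, "nasion")
  foramen_left <- vec3(foramen_left, "foramen_left")
  foramen_right <- vec3(foramen_right, "foramen_right")
  midline_normal <- vec3(midline_normal, "midline_normal")
  if (!is.numeric(scalp_radius) || scalp_radius <= 0)
    stop("scalp_radius must be positive")
  if (abs(vnorm(nasion - center) - scalp_radius) > 1e-6)
    stop("nasion must lie on the scalp sphere (within 1e-6 mm)")
  if (abs(vnorm(midline_normal) - 1) > 1e-9)
    stop("midline_normal must have unit norm")
  for (f in list(foramen_left, foramen_right))
    if (vnorm(f - center) >= scalp_radius)
      stop("degenerate head: foramen of Monro outside the scalp sphere")
  structure(list(scalp_radius = scalp_radius, center = center,
                 nasion = nasion, foramen_left = foramen_left,
                 foramen_right = foramen_right,
                 midline_normal = midline_normal),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> scalp radius", x$scalp_radius, "mm, center",
      paste(signif(x$center, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Locate Kocher's point on the scalp
#'
#' Kocher's point is the classical ventriculostomy entry site, reached from
#' the nasion by a 10 cm posterior offset followed by a 3 cm lateral offset
#' toward the operated side.  Both offsets are interpreted as geodesic arc
#' lengths measured along the scalp surface (the surgical tape-measure
#' convention): the posterior walk follows the midsagittal great circle of
#' the scalp sphere, the lateral walk follows the great circle orthogonal to
#' it at the reached point.  The result therefore lies exactly on the scalp
#' sphere.
#'
#' @param head a [head_model()].
#' @param side `"left"` or `"right"`.
#' @param posterior_mm posterior geodesic arc length from the nasion (mm).
#' @param lateral_mm lateral geodesic arc length from the midline (mm).
#' @return scalp-surface point (3-vector, mm).
#' @export
kocher_point <- function(head, side = c("right", "left"),
                         posterior_mm = 100, lateral_mm = 30) {
  side <- match.arg(side)
  stopifnot(inherits(head, "head_model"))
  R <- head$scalp_radius
  theta <- posterior_mm / R
  phi <- lateral_mm / R
  if (theta > pi || phi > pi / 2)
    stop("head too small: offset arcs exceed the hemisphere circumference")
  u <- unitize(head$nasion - head$center)           # toward nasion
  s <- c(0, 0, 1)                                   # superior axis
  w <- s - sum(s * u) * u
  if (vnorm(w) < 1e-9) stop("nasion coincides with the superior pole")
  w <- unitize(w)                                   # superior, tangent at nasion
  e3 <- cross3(u, w)                                # lateral tangent direction
  sgn <- if (side == "right") 1 else -1
  if (sum(e3 * head$midline_normal) < 0) e3 <- -e3  # +e3 = subject's right
  p1 <- cos(theta) * u + sin(theta) * w             # after posterior arc
  q <- cos(phi) * p1 + sin(phi) * sgn * e3          # after lateral arc
  head$center + R * q
}

#' Build the virtual Kocher-Monro instrument
#'
#' The instrument is a finite cylinder whose axis runs from Kocher's point on
#' the scalp to the ipsilateral foramen of Monro.  The default radius of
#' 2 mm corresponds to a conservative 4 mm instrument diameter.
#'
#' @inheritParams kocher_point
#' @param radius cylinder radius in mm (> 0).
#' @return an object of class `virtual_instrument` with fields `entry`,
#'   `target`, `radius`, `side`.
#' @export
build_instrument <- function(head, side = c("right", "left"), radius = 2,
                             posterior_mm = 100, lateral_mm = 30) {
  side <- match.arg(side)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("instrument radius must be a positive scalar (mm)")
  entry <- kocher_point(head, side, posterior_mm, lateral_mm)
  target <- if (side == "right") head$foramen_right else head$foramen_left
  if (vnorm(entry - target) < 1e-9) stop("degenerate instrument: entry equals target")
  structure(list(entry = entry, target = target, radius = radius, side = side),
            class = "virtual_instrument")
}

#' @export
print.virtual_instrument <- function(x, ...) {
  cat(sprintf("<virtual_instrument> %s, radius %.2f mm, axis length %.1f mm\n",
              x$side, x$radius, vnorm(x$entry - x$target)))
  invisible(x)
}

## Minimum distances between each row-segment (p0[i,] -> p1[i,]) and the
## single segment q0 -> q1.  Vectorized two-pass clamped (Lumelsky) solution
## of the quadratic; exact up to floating point.
segment_segment_distance <- function(p0, p1, q0, q1) {
  u <- p1 - p0
  v <- q1 - q0
  r <- p0 - matrix(q0, nrow(p0), 3, byrow = TRUE)
  a <- rowSums(u * u)
  b <- as.vector(u %*% v)
  cc <- sum(v * v)
  d <- rowSums(u * r)
  e <- as.vector(r %*% v)
  den <- a * cc - b * b
  s <- (b * e - cc * d) / den
  s[!(den > 1e-12 * pmax(a * cc, 1e-300))] <- 0
  s <- pmin(pmax(s, 0), 1)
  t <- if (cc > 0) (b * s + e) / cc else rep(0, length(s))
  t <- pmin(pmax(t, 0), 1)
  s <- (b * t - d) / a
  s[!is.finite(s)] <- 0
  s <- pmin(pmax(s, 0), 1)
  w <- r + u * s - outer(t, v)
  sqrt(rowSums(w * w))
}

## Minimum distance from a polyline (matrix of points) to the instrument axis.
polyline_axis_distance <- function(pts, instrument) {
  p <- nrow(pts)
  if (p < 2L) stop("streamline must have at least 2 points")
  min(segment_segment_distance(pts[-p, , drop = FALSE], pts[-1, , drop = FALSE],
                               instrument$entry, instrument$target))
}

#' Does the instrument transect a streamline?
#'
#' A streamline is transected when the minimum Euclidean distance between its
#' polyline and the finite instrument axis segment is strictly less than the
#' cylinder radius (capped cylinder; boundary contact at exactly the radius
#' does not count).  The distance is the exact polyline-segment to
#' axis-segment minimum, not a sampled approximation.
#'
#' @param streamline numeric matrix of polyline points (rows, mm), >= 2 rows.
#' @param instrument a [build_instrument()] result.
#' @return list with `transected` (logical) and `min_distance` (mm).
#' @export
transects <- function(streamline, instrument) {
  streamline <- as.matrix(streamline)
  stopifnot(inherits(instrument, "virtual_instrument"), ncol(streamline) == 3L)
  d <- polyline_axis_distance(streamline, instrument)
  list(transected = d < instrument$radius, min_distance = d)
}

#' Remove the streamlines a virtual instrument transects
#'
#' Simulates the tissular disconnection of the instrument pass: every
#' streamline whose polyline comes strictly closer to the instrument axis
#' than the cylinder radius is removed from the tractogram.
#'
#' @param tractogram a [tractogram()].
#' @param instrument a [build_instrument()] result.
#' @return list with `tractogram` (the surviving streamlines) and `report`,
#'   a `transection_report` holding per-streamline minimum distances, the
#'   transected index set and the instrument.
#' @export
apply_lesion <- function(tractogram, instrument) {
  stopifnot(inherits(tractogram, "tractogram"),
            inherits(instrument, "virtual_instrument"))
  ns <- n_streamlines(tractogram)
  if (ns == 0L) {
    report <- structure(list(transected_ids = integer(0),
                             min_distance = numeric(0),
                             instrument = instrument),
                        class = "transection_report")
    return(list(tractogram = tractogram, report = report))
  }
  pts <- tractogram$points
  np <- nrow(pts)
  sid <- rep.int(seq_len(ns), tractogram$npts)
  seg_keep <- sid[-np] == sid[-1]        # drop inter-streamline joins
  dseg <- segment_segment_distance(pts[-np, , drop = FALSE][seg_keep, , drop = FALSE],
                                   pts[-1, , drop = FALSE][seg_keep, , drop = FALSE],
                                   instrument$entry, instrument$target)
  sid2 <- sid[-np][seg_keep]
  o <- order(sid2, dseg)                 # first row per streamline = its minimum
  first <- !duplicated(sid2[o])
  dmin <- numeric(ns)
  dmin[sid2[o][first]] <- dseg[o][first]
  transected <- which(dmin < instrument$radius)
  out <- subset_streamlines(tractogram, setdiff(seq_len(ns), transected))
  report <- structure(list(transected_ids = transected, min_distance = dmin,
                           instrument = instrument),
                      class = "transection_report")
  list(tractogram = out, report = report)
}

#' @export
print.transection_report <- function(x, ...) {
  cat(sprintf("<transection_report> %d of %d streamlines transected (radius %.2f mm)\n",
              length(x$transected_ids), length(x$min_distance), x$instrument$radius))
  invisible(x)
}

#' Probabilistic map of a set of virtual instruments
#'
#' Rasterizes the cohort's instrument cylinders onto a regular grid: each
#' voxel holds the fraction of instruments whose cylinder contains the voxel
#' center (distance to the axis segment strictly below the radius, matching
#' the transection convention).
#'
#' @param instruments list of `virtual_instrument` objects (>= 1).
#' @param grid_spacing voxel edge length in mm.
#' @param padding extra margin around the instruments' bounding box (mm).
#' @return 3-D array with values in `[0, 1]`; attributes `origin` (mm
#'   coordinates of the first voxel center) and `spacing`.
#' @export
instrument_probability_map <- function(instruments, grid_spacing = 2,
                                       padding = grid_spacing) {
  stopifnot(length(instruments) >= 1L)
  ends <- do.call(rbind, lapply(instruments, function(i) rbind(i$entry, i$target)))
  rmax <- max(vapply(instruments, function(i) i$radius, 0))
  lo <- apply(ends, 2, min) - rmax - padding
  hi <- apply(ends, 2, max) + rmax + padding
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = grid_spacing))
  centers <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  acc <- numeric(nrow(centers))
  for (ins in instruments) {
    v <- ins$target - ins$entry
    cc <- sum(v * v)
    w <- sweep(centers, 2, ins$entry)
    t <- pmin(pmax(as.vector(w %*% v) / cc, 0), 1)
    dd <- w - outer(t, v)
    acc <- acc + (sqrt(rowSums(dd * dd)) < ins$radius)
  }
  map <- array(acc / length(instruments),
               dim = c(length(ax[[1]]), length(ax[[2]]), length(ax[[3]])))
  attr(map, "origin") <- lo
  attr(map, "spacing") <- rep(grid_spacing, 3)
  map
}
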