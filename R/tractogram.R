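#' Tractogram container
#'
#' A tractogram is one subject's set of streamlines.  Streamlines are stored
#' compactly: all points concatenated row-wise in one matrix, with a
#' per-streamline point count.  Each point carries a fractional-anisotropy
#' (FA) sample in (0, 1).
#'
#' @param points numeric matrix (total points x 3), mm.
#' @param fa numeric vector of per-point FA samples, same length as
#'   `nrow(points)`.
#' @param npts integer vector of per-streamline point counts (each >= 2),
#'   summing to `nrow(points)`.
#' @param bundle optional per-streamline bundle name (character).
#' @param head optional [head_model()] of the subject.
#' @param group,subject optional cohort bookkeeping labels.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(points, fa, npts, bundle = NULL, head = NULL,
                       group = NA_character_, subject = NA_character_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, length(fa) == nrow(points),
            sum(npts) == nrow(points), all(npts >= 2L))
  if (!is.null(bundle)) stopifnot(length(bundle) == length(npts))
  structure(list(points = points, fa = as.numeric(fa),
                 npts = as.integer(npts), bundle = bundle, head = head,
                 group = group, subject = subject),
            class = "tractogram")
}

#' @rdname tractogram
#' @param x a tractogram.
#' @export
n_streamlines <- function(x) length(x$npts)

streamline_slices <- function(x) {
  ends <- cumsum(x$npts)
  cbind(start = ends - x$npts + 1L, end = ends)
}

#' Extract one streamline's points (and FA) from a tractogram
#' @param x a tractogram.
#' @param i streamline index.
#' @return list with `points` (matrix) and `fa` (vector).
#' @export
streamline <- function(x, i) {
  sl <- streamline_slices(x)
  idx <- sl[i, 1]:sl[i, 2]
  list(points = x$points[idx, , drop = FALSE], fa = x$fa[idx])
}

#' Per-streamline polyline arc lengths (mm)
#' @param x a tractogram.
#' @export
streamline_lengths <- function(x) {
  if (n_streamlines(x) == 0L) return(numeric(0))
  np <- nrow(x$points)
  sid <- rep.int(seq_along(x$npts), x$npts)
  d <- x$points[-1, , drop = FALSE] - x$points[-np, , drop = FALSE]
  seg <- sqrt(rowSums(d * d))
  seg[sid[-np] != sid[-1]] <- 0
  as.vector(rowsum(seg, sid[-np]))
}

#' Keep a subset of streamlines
#' @param x a tractogram.
#' @param keep integer indices of streamlines to retain.
#' @export
subset_streamlines <- function(x, keep) {
  keep <- sort(unique(as.integer(keep)))
  sl <- streamline_slices(x)
  pidx <- unlist(lapply(keep, function(i) sl[i, 1]:sl[i, 2]), use.names = FALSE)
  if (length(keep) == 0L) pidx <- integer(0)
  tractogram(x$points[pidx, , drop = FALSE], x$fa[pidx], x$npts[keep],
             bundle = if (!is.null(x$bundle)) x$bundle[keep],
             head = x$head, group = x$group, subject = x$subject)
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> %d streamlines, %d points%s\n",
              n_streamlines(x), nrow(x$points),
              if (!is.na(x$group)) paste0(" (group ", x$group,
                                          ", subject ", x$subject, ")") else ""))
  invisible(x)
}

## Endpoint coordinates of all streamlines: list(first = matrix, last = matrix)
tractogram_endpoints <- function(x) {
  sl <- streamline_slices(x)
  list(first = x$points[sl[, 1], , drop = FALSE],
       last = x$points[sl[, 2], , drop = FALSE])
}
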