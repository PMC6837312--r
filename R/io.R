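## File interchange: TCK (MRtrix track file dialect), a neutral JSON dialect,
## TSV matrices/masks/reports, and an optional NIfTI probability-map writer.

#' Write / read tractograms as MRtrix TCK track files
#'
#' The TCK dialect written here is the MRtrix one: a text header starting
#' with `mrtrix tracks`, `key: value` lines including `datatype: Float32LE`
#' and the binary `file: . <offset>` pointer, an `END` line, then float32
#' little-endian xyz triplets with an all-NaN triplet between streamlines
#' and an all-Inf triplet at the end of the file.  Per-point FA does not fit
#' in a TCK file, so `write_tck()` writes a plain-text sidecar (one line of
#' space-separated FA values per streamline) next to it.
#'
#' @param x a [tractogram()].
#' @param path output `.tck` path.
#' @param fa_sidecar path of the FA sidecar (default `<path>.fa.txt`;
#'   `NULL` to skip).
#' @return `write_tck()` returns `path` invisibly; `read_tck()` returns a
#'   [tractogram()] (FA zero-filled when no sidecar is found).
#' @export
write_tck <- function(x, path, fa_sidecar = paste0(path, ".fa.txt")) {
  stopifnot(inherits(x, "tractogram"))
  fixed <- c("mrtrix tracks",
             "datatype: Float32LE",
             sprintf("count: %d", n_streamlines(x)),
             "vlconn: synthetic tractogram")
  offset <- 0L
  repeat {  # offset digits feed back into the header length
    header <- c(fixed, sprintf("file: . %d", offset), "END")
    need <- sum(nchar(header, type = "bytes")) + length(header)
    if (need == offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  sl <- streamline_slices(x)
  for (i in seq_len(n_streamlines(x))) {
    writeBin(as.vector(t(x$points[sl[i, 1]:sl[i, 2], , drop = FALSE])),
             con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  if (!is.null(fa_sidecar)) {
    fa_lines <- vapply(seq_len(n_streamlines(x)), function(i)
      paste(format(x$fa[sl[i, 1]:sl[i, 2]], digits = 8, trim = TRUE),
            collapse = " "), "")
    writeLines(fa_lines, fa_sidecar)
  }
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path, fa_sidecar = paste0(path, ".fa.txt")) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw == charToRaw("\n"))
  header <- character(0)
  pos <- 1L
  for (e in nl) {
    header <- c(header, rawToChar(raw[pos:(e - 1L)]))
    pos <- e + 1L
    if (header[length(header)] == "END") break
  }
  if (header[1] != "mrtrix tracks") stop("not a TCK file")
  off_line <- grep("^file: \\.", header, value = TRUE)
  offset <- as.integer(sub("^file: \\. ", "", off_line[1]))
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric", size = 4,
                  n = (length(raw) - offset) / 4, endian = "little")
  trip <- matrix(vals, ncol = 3, byrow = TRUE)
  is_break <- apply(trip, 1, function(r) all(is.nan(r)))
  is_end <- apply(trip, 1, function(r) all(is.infinite(r)))
  trip <- trip[!is_end, , drop = FALSE]
  is_break <- is_break[!is_end]
  sid <- cumsum(c(TRUE, is_break[-length(is_break)]))
  pts <- trip[!is_break, , drop = FALSE]
  npts <- as.integer(table(sid[!is_break]))
  fa <- rep(0, nrow(pts))
  if (!is.null(fa_sidecar) && file.exists(fa_sidecar)) {
    fa <- as.numeric(unlist(lapply(readLines(fa_sidecar), function(l)
      strsplit(trimws(l), "\\s+")[[1]]), use.names = FALSE))
    stopifnot(length(fa) == nrow(pts))
  }
  tractogram(pts, fa, npts)
}

#' Tractogram round-trip through a neutral JSON dialect
#'
#' A self-describing alternative to TCK: streamlines are stored as lists of
#' `[x, y, z]` rows with a parallel `fa` list, keeping coordinates and FA in
#' one file.
#'
#' @param x a [tractogram()].
#' @param path output `.json` path.
#' @export
write_tractogram_json <- function(x, path) {
  stopifnot(inherits(x, "tractogram"))
  sl <- streamline_slices(x)
  obj <- list(
    format = "vlconn-tractogram",
    units = "mm",
    group = x$group, subject = x$subject,
    streamlines = lapply(seq_len(n_streamlines(x)), function(i) {
      idx <- sl[i, 1]:sl[i, 2]
      list(points = unname(x$points[idx, , drop = FALSE]), fa = x$fa[idx],
           bundle = if (!is.null(x$bundle)) x$bundle[i] else NULL)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tractogram_json
#' @export
read_tractogram_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  stopifnot(identical(obj$format, "vlconn-tractogram"))
  sls <- obj$streamlines
  pts <- do.call(rbind, sls$points)
  fa <- unlist(sls$fa, use.names = FALSE)
  npts <- vapply(sls$points, nrow, 0L)
  bundle <- if (!is.null(sls$bundle)) as.character(sls$bundle)
  tractogram(pts, fa, npts, bundle = bundle,
             group = if (is.null(obj$group)) NA_character_ else obj$group,
             subject = if (is.null(obj$subject)) NA_character_ else obj$subject)
}

#' Connectivity matrix / edge mask TSV round-trip
#'
#' Matrices are written as TSV with a header row of node labels and row
#' names in the first column; masks are written as 0/1.
#'
#' @param m matrix (numeric or logical).
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(unclass(m) * 1)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a transection report as TSV
#'
#' Columns: `streamline_id`, `min_distance_mm`, `transected`.
#'
#' @param report a `transection_report` from [apply_lesion()].
#' @param path output path.
#' @export
write_transection_report <- function(report, path) {
  stopifnot(inherits(report, "transection_report"))
  df <- data.frame(streamline_id = seq_along(report$min_distance),
                   min_distance_mm = report$min_distance,
                   transected = seq_along(report$min_distance) %in%
                     report$transected_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an instrument probability map as NIfTI
#'
#' Writes the [instrument_probability_map()] array as a float32 NIfTI volume
#' with the map's voxel spacing; requires the RNifti package.
#'
#' @param map array from [instrument_probability_map()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_probability_map <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required to write NIfTI maps")
  img <- RNifti::asNifti(unclass(aperm(map, c(1, 2, 3))),
                         pixdim = attr(map, "spacing"))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a cohort manifest as JSON
#'
#' Records the per-subject group labels, seeds and file paths of a cohort
#' written to disk.
#'
#' @param cohort list of tractograms from [generate_cohort()].
#' @param spec the [cohort_spec()] used.
#' @param dir output directory (created if needed); each subject is written
#'   as TCK + FA sidecar.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort, function(tr) {
    f <- file.path(dir, paste0(tr$subject, ".tck"))
    write_tck(tr, f)
    list(subject = tr$subject, group = tr$group, file = basename(f),
         n_streamlines = n_streamlines(tr))
  })
  manifest <- list(format = "vlconn-cohort", seed = spec$seed,
                   n_per_group = spec$n_per_group,
                   node_count = spec$parcellation$node_count,
                   coordinate_frame = "RAS mm, +x subject right",
                   subjects = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
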