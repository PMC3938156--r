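#' Construct a tractogram
#'
#' A set of streamlines with their provenance. Each streamline is an
#' n x 3 matrix of ordered positions in continuous 0-based voxel
#' coordinates.
#'
#' @param streamlines List of n x 3 numeric matrices (n >= 2 each).
#' @param voxel_dims Voxel dimensions (mm) of the grid the coordinates
#'   refer to.
#' @param affine Voxel-to-mm affine of that grid.
#' @param config Optional [run_config()] snapshot.
#' @param seed_mask_name Label of the seed region.
#' @param info Optional per-streamline tibble (seed index, termination
#'   reasons).
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, voxel_dims = c(1.88, 1.88, 3),
                       affine = NULL, config = NULL,
                       seed_mask_name = "seed", info = NULL) {
  if (is.null(affine)) affine <- diag(c(voxel_dims, 1))
  structure(list(streamlines = streamlines,
                 voxel_dims = as.numeric(voxel_dims),
                 affine = affine,
                 config = config,
                 seed_mask_name = seed_mask_name,
                 info = info),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, 1L))
  cat(sprintf("<tractogram> %d streamline(s), %d points, seed mask '%s'\n",
              length(x$streamlines), np, x$seed_mask_name))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Tidy a tractogram into one row per point
#'
#' @param x A [tractogram()].
#' @param ... Unused.
#' @return A tibble with columns `streamline`, `point`, `x`, `y`, `z`
#'   (voxel coordinates).
#' @export
tidy.tractogram <- function(x, ...) {
  purrr::imap(x$streamlines, function(m, i) {
    tibble(streamline = i, point = seq_len(nrow(m)),
           x = m[, 1], y = m[, 2], z = m[, 3])
  }) |> purrr::list_rbind()
}

write_padded_char <- function(con, s, width) {
  r <- charToRaw(s)
  if (length(r) > width) r <- r[seq_len(width)]
  writeBin(c(r, raw(width - length(r))), con)
}

#' Write a tractogram to TrackVis TRK or MRtrix TCK
#'
#' TRK stores points in "voxel-mm" (voxel coordinate times voxel size);
#' TCK stores world coordinates obtained through the affine. Both are the
#' formats' native conventions, so files open directly in external viewers.
#'
#' @param tract A [tractogram()].
#' @param path Output path.
#' @param format `"trk"` or `"tck"`.
#' @export
write_tractogram <- function(tract, path, format = c("trk", "tck")) {
  if (!format[1] %in% c("trk", "tck")) {
    abort(sprintf("unknown tractogram format '%s' (use 'trk' or 'tck').",
                  format[1]))
  }
  format <- format[1]
  if (format == "trk") write_trk(tract, path) else write_tck(tract, path)
  invisible(path)
}

write_trk <- function(tract, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  vd <- tract$voxel_dims
  dims <- attr(tract, "grid_shape") %||% c(0L, 0L, 0L)
  write_padded_char(con, "TRACK", 6)
  writeBin(as.integer(dims), con, size = 2, endian = "little")
  writeBin(as.numeric(vd), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")        # origin
  writeBin(0L, con, size = 2, endian = "little")                # n_scalars
  writeBin(raw(200), con)                                       # scalar names
  writeBin(0L, con, size = 2, endian = "little")                # n_properties
  writeBin(raw(200), con)                                       # property names
  writeBin(as.numeric(t(tract$affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                       # reserved
  write_padded_char(con, "RAS", 4)                              # voxel_order
  writeBin(raw(4), con)                                         # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")        # orientation
  writeBin(raw(2), con)                                         # pad1
  writeBin(raw(6), con)                                         # invert/swap
  writeBin(length(tract$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                # version
  writeBin(1000L, con, size = 4, endian = "little")             # hdr_size
  for (m in tract$streamlines) {
    writeBin(nrow(m), con, size = 4, endian = "little")
    mm <- sweep(m, 2, vd, `*`)                                  # voxel-mm
    writeBin(as.numeric(t(mm)), con, size = 4, endian = "little")
  }
}

write_tck <- function(tract, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(tract$streamlines)))
  # world coordinates: affine maps voxel *index* (centre i+0.5 -> index i)
  body_offset_line <- function(off) sprintf("file: . %d", off)
  # bytes before the binary body: header lines + their newlines + "END\n"
  fixed <- sum(nchar(hdr)) + length(hdr) + nchar("END") + 1
  off_line <- body_offset_line(0)
  repeat {
    off <- fixed + nchar(off_line) + 1
    new_line <- body_offset_line(off)
    if (nchar(new_line) == nchar(off_line)) { off_line <- new_line; break }
    off_line <- new_line
  }
  writeLines(c(hdr, off_line, "END"), con, sep = "\n")
  A <- tract$affine
  for (m in tract$streamlines) {
    idx <- cbind(m - 0.5, 1)
    w <- idx %*% t(A)
    writeBin(as.numeric(t(w[, 1:3, drop = FALSE])), con, size = 4,
             endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}

#' Read a TRK or TCK tractogram back into voxel coordinates
#'
#' @param path File path.
#' @param format `"trk"` or `"tck"`; guessed from the extension by default.
#' @param voxel_dims,affine Grid geometry used to convert the file's native
#'   coordinates back to voxel space (TCK needs the affine; TRK the voxel
#'   size, which is also stored in its header).
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, format = NULL,
                            voxel_dims = NULL, affine = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("trk", "tck")) abort("unknown tractogram format.")
  if (format == "trk") read_trk(path) else read_tck(path, affine)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (rawToChar(magic[1:5]) != "TRACK") abort("not a TRK file.")
  invisible(readBin(con, "integer", 3, size = 2, endian = "little"))
  vd <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  ns <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  np <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  aff <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 2, size = 4, endian = "little"))
  sl <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    pts <- matrix(readBin(con, "numeric", n * (3 + ns), size = 4,
                          endian = "little"), ncol = 3 + ns, byrow = TRUE)
    if (np > 0) invisible(readBin(con, "numeric", np, size = 4,
                                  endian = "little"))
    sl[[i]] <- sweep(pts[, 1:3, drop = FALSE], 2, vd, `/`)
  }
  tractogram(sl, voxel_dims = vd, affine = aff)
}

read_tck <- function(path, affine = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) abort("truncated TCK header.")
    if (ln == "END") break
    lines <- c(lines, ln)
  }
  if (!identical(lines[1], "mrtrix tracks")) abort("not a TCK file.")
  off <- as.integer(sub("^file: \\. ", "", lines[grepl("^file: ", lines)]))
  seek(con, off)
  vals <- readBin(con, "numeric", file.size(path), size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  if (is.null(affine)) affine <- diag(4)
  Ainv <- solve(affine)
  sl <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur)) sl[[length(sl) + 1]] <- do.call(rbind, cur)
      cur <- NULL
    } else {
      v <- Ainv %*% c(p, 1)
      cur <- c(cur, list(v[1:3] + 0.5))
    }
  }
  vd <- sqrt(colSums(affine[1:3, 1:3]^2))
  tractogram(sl, voxel_dims = vd, affine = affine)
}

#' Write keyed records as a TSV table
#'
#' @param records A data frame / tibble (or list of uniform named lists).
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) records <- dplyr::bind_rows(records)
  readr::write_tsv(records, path)
  invisible(path)
}
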