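CURV_MAGIC <- as.raw(c(0xff, 0xff, 0xff))
SURF_TRIANGLE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))
CURV_OLD_MAGIC_MAX <- 0xfffffd  # anything else with 3-byte int header: old dialect

read_int3 <- function(con) {
  b <- readBin(con, "raw", n = 3L)
  if (length(b) < 3L) stopf("unexpected end of file in header")
  b
}

#' Read FreeSurfer morph data ("curv" format)
#'
#' New-format curv only (3-byte magic `0xFFFFFF`, big-endian int32
#' vertex/face/values-per-vertex header, float32 values). The rare old
#' two-byte-count dialect is rejected with a message rather than guessed at.
#'
#' @param path File path.
#' @param expected_n Optional vertex count to validate against.
#' @return Numeric vector of per-vertex values.
#' @export
read_curv <- function(path, expected_n = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (!identical(magic, CURV_MAGIC))
    stopf("'%s' is not new-format curv (magic 0x%s; old-format curv unsupported)",
          path, paste(format(magic), collapse = ""))
  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
  if (length(hdr) < 3L) stopf("truncated curv header in '%s'", path)
  vnum <- hdr[1L]; vals_per <- hdr[3L]
  if (vals_per != 1L)
    stopf("curv '%s' has %d values per vertex; only 1 supported", path, vals_per)
  vals <- readBin(con, "numeric", n = vnum, size = 4L, endian = "big")
  if (length(vals) != vnum)
    stopf("truncated curv '%s': %d of %d values", path, length(vals), vnum)
  if (!is.null(expected_n) && vnum != expected_n)
    stopf("curv '%s' has %d vertices, expected %d", path, vnum, expected_n)
  vals
}

#' Write FreeSurfer morph data ("curv" format)
#'
#' @param values Numeric per-vertex values (stored as big-endian float32).
#' @param path Output path.
#' @param fnum Face count recorded in the header (informational; default 0).
#' @return `path`, invisibly.
#' @export
write_curv <- function(values, path, fnum = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CURV_MAGIC, con)
  writeBin(as.integer(c(length(values), fnum, 1L)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer binary surface (triangle format)
#'
#' @param path File path.
#' @param hemisphere Hemisphere tag to attach (`"left"`/`"right"`).
#' @return A [surface_mesh()].
#' @export
read_surface <- function(path, hemisphere = "left") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (!identical(magic, SURF_TRIANGLE_MAGIC))
    stopf("'%s' is not a triangle-format FreeSurfer surface", path)
  # comment line terminated by "\n\n"
  comment <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (!length(b)) stopf("truncated surface header in '%s'", path)
    comment <- c(comment, b)
    nc <- length(comment)
    if (nc >= 2L && comment[nc] == as.raw(10L) && comment[nc - 1L] == as.raw(10L))
      break
  }
  hdr <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  vnum <- hdr[1L]; fnum <- hdr[2L]
  v <- readBin(con, "numeric", n = 3L * vnum, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * fnum, size = 4L, endian = "big")
  if (length(v) != 3L * vnum || length(f) != 3L * fnum)
    stopf("truncated surface '%s'", path)
  surface_mesh(matrix(v, ncol = 3L, byrow = TRUE),
               matrix(f, ncol = 3L, byrow = TRUE) + 1L,
               hemisphere = hemisphere)
}

#' Write a FreeSurfer binary surface (triangle format)
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SURF_TRIANGLE_MAGIC, con)
  writeChar("created by cortexstage\n\n", con, eos = NULL)
  writeBin(as.integer(c(n_vertices(mesh), nrow(mesh$faces))), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer label file as a vertex mask
#'
#' @param path File path.
#' @param n_vertices Total vertex count of the bound mesh.
#' @return Logical vertex mask.
#' @export
read_label <- function(path, n_vertices) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#"))
    stopf("'%s' is not a FreeSurfer ASCII label file", path)
  count <- as.integer(lines[2L])
  body <- utils::read.table(text = lines[-(1:2)], col.names =
                              c("vertex", "x", "y", "z", "value"))
  if (nrow(body) != count)
    stopf("label '%s' declares %d vertices but has %d", path, count, nrow(body))
  idx <- body$vertex + 1L        # file is 0-based
  if (any(idx < 1L | idx > n_vertices))
    stopf("label '%s' has vertex indices outside [0, %d)", path, n_vertices)
  mask <- logical(n_vertices)
  mask[idx] <- TRUE
  mask
}

#' Write a vertex mask as a FreeSurfer label file
#'
#' @param mask Logical vertex mask.
#' @param mesh The bound [surface_mesh()] (for coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label <- function(mask, mesh, path) {
  idx <- which(as.logical(mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#!ascii label, from cortexstage (%s hemisphere)",
                     mesh$hemisphere), con)
  writeLines(as.character(length(idx)), con)
  if (length(idx)) {
    v <- mesh$vertices[idx, , drop = FALSE]
    writeLines(sprintf("%d  %.3f  %.3f  %.3f %.10f",
                       idx - 1L, v[, 1L], v[, 2L], v[, 3L], 0), con)
  }
  invisible(path)
}
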