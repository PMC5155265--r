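#' Read an STL file
#'
#' Reads binary or ASCII stereolithography files (auto-detected) into a
#' [triangle_mesh()]. STL stores each facet with its own vertex copies;
#' exactly-coincident copies are welded within `merge_tol` so that
#' edge-manifold checks are meaningful. Coordinates are taken as millimetres.
#'
#' @param path file path.
#' @param merge_tol vertex welding tolerance in mm (default 1e-8).
#' @return a `triangle_mesh`.
#' @export
read_stl <- function(path, merge_tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  size <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 512))
  is_ascii <- length(grepRaw("^\\s*solid", head)) > 0 &&
    length(grepRaw("facet", head)) > 0
  if (is_ascii) {
    close(con)
    on.exit()
    return(read_stl_ascii(path, merge_tol))
  }
  if (size < 84)
    stop("STL parse error at byte 0: file too short for binary header",
         call. = FALSE)
  seek(con, 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (ntri < 0 || 84 + 50 * as.numeric(ntri) != size)
    stop(sprintf(
      "STL parse error at byte 80: record count %d inconsistent with file size %d",
      ntri, size), call. = FALSE)
  raw <- readBin(con, "raw", n = 50 * ntri)
  dim(raw) <- c(50, ntri)
  fl <- readBin(as.vector(raw[1:48, ]), "numeric", n = 12 * ntri, size = 4,
                endian = "little")
  fl <- matrix(fl, nrow = 12)
  verts <- matrix(as.vector(fl[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  merge_mesh_vertices(triangle_mesh(verts, faces), merge_tol)
}

read_stl_ascii <- function(path, merge_tol) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nfacet <- length(grep("^\\s*facet\\s", lines))
  if (length(vl) == 0 || length(vl) %% 3 != 0 || length(vl) != 3 * nfacet)
    stop(sprintf(
      "STL parse error at byte 0: ASCII file has %d vertex lines for %d facets",
      length(vl), nfacet), call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (anyNA(verts))
    stop("STL parse error at byte 0: non-numeric vertex coordinates",
         call. = FALSE)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  merge_mesh_vertices(triangle_mesh(verts, faces), merge_tol)
}

#' Write an STL file
#'
#' Binary (default, 80-byte "splintforge" header) or ASCII dialect. A
#' write-read-write roundtrip of a binary file is byte-identical:
#' coordinates are stored as 32-bit floats and facet normals are recomputed
#' deterministically from them.
#'
#' @param mesh a non-empty [triangle_mesh()].
#' @param path output file path.
#' @param dialect "binary" or "ascii".
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot_mesh(mesh)
  dialect <- match.arg(dialect)
  if (nrow(mesh$faces) == 0)
    stop("refusing to write an empty mesh", call. = FALSE)
  # quantize to float32 before computing normals, so write-read-write is
  # byte-identical
  V <- mesh$vertices
  V <- matrix(readBin(writeBin(as.vector(V), raw(), size = 4,
                               endian = "little"),
                      "numeric", n = length(V), size = 4,
                      endian = "little"), ncol = 3)
  mesh$vertices <- V
  n <- face_normals(mesh)
  F <- mesh$faces
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- c(charToRaw("splintforge"), raw(80 - nchar("splintforge")))
    count <- writeBin(as.integer(nrow(F)), raw(), size = 4, endian = "little")
    # 12 floats per facet: normal then the three vertices, then 2 attr bytes
    block <- t(cbind(n, V[F[, 1], , drop = FALSE], V[F[, 2], , drop = FALSE],
                     V[F[, 3], , drop = FALSE]))
    fl <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
    dim(fl) <- c(48L, nrow(F))
    out <- matrix(as.raw(0), 50L, nrow(F))
    out[1:48, ] <- fl
    writeBin(c(header, count, as.vector(out)), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid splintforge", con)
    fmt <- function(v) paste(sprintf("%.9g", v), collapse = " ")
    for (i in seq_len(nrow(F))) {
      writeLines(c(
        paste0("  facet normal ", fmt(n[i, ])),
        "    outer loop",
        paste0("      vertex ", fmt(V[F[i, 1], ])),
        paste0("      vertex ", fmt(V[F[i, 2], ])),
        paste0("      vertex ", fmt(V[F[i, 3], ])),
        "    endloop",
        "  endfacet"
      ), con)
    }
    writeLines("endsolid splintforge", con)
  }
  invisible(path)
}
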