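#' Triangle mesh objects
#'
#' A `triangle_mesh` is the universal geometry carrier of splintforge: an
#' indexed triangle surface with vertex coordinates in millimetres. It is a
#' plain list with a numeric `vertices` matrix (n x 3) and an integer `faces`
#' matrix (m x 3, 1-based, counter-clockwise seen from outside for an
#' outward-oriented surface).
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates, mm.
#' @param faces integer matrix (m x 3) of vertex indices (1-based).
#' @return an object of class `triangle_mesh`.
#' @examples
#' cube <- make_box(c(0, 0, 0), c(1, 1, 1))
#' mesh_volume(cube)
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face index out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      stop("face repeats a vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "triangle_mesh: %d vertices, %d faces%s\n",
    nrow(x$vertices), nrow(x$faces),
    if (nrow(x$faces) > 0 && is_watertight(x)) ", watertight" else ""
  ))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param x object to test.
#' @export
is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' An empty mesh (no vertices, no faces).
#' @return an empty `triangle_mesh`.
#' @export
empty_mesh <- function() {
  triangle_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
}

stopifnot_mesh <- function(mesh) {
  if (!is_triangle_mesh(mesh)) stop("not a triangle_mesh", call. = FALSE)
  invisible(mesh)
}

# undirected edge keys as doubles (exact for < 2^26 vertices)
edge_keys <- function(faces, n_vertices) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  L <- n_vertices + 1
  list(
    directed = e[, 1] * L + e[, 2],
    undirected = pmin(e[, 1], e[, 2]) * L + pmax(e[, 1], e[, 2])
  )
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces traversed in opposite directions (closed, edge-manifold,
#' consistently oriented). An empty mesh is vacuously watertight.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical flag.
#' @export
is_watertight <- function(mesh) {
  stopifnot_mesh(mesh)
  if (nrow(mesh$faces) == 0) return(TRUE)
  k <- edge_keys(mesh$faces, nrow(mesh$vertices))
  if (anyDuplicated(k$directed) > 0) return(FALSE)
  all(tabulate(match(k$undirected, unique(k$undirected))) == 2L)
}

#' Signed enclosed volume
#'
#' Volume by the divergence theorem (sum of signed tetrahedron volumes
#' against the origin). Positive for a watertight, outward-oriented mesh;
#' the sign flips when all faces are reversed.
#'
#' @param mesh a [triangle_mesh()].
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot_mesh(mesh)
  if (nrow(mesh$faces) == 0) return(0)
  V <- mesh$vertices
  a <- V[mesh$faces[, 1], , drop = FALSE]
  b <- V[mesh$faces[, 2], , drop = FALSE]
  c <- V[mesh$faces[, 3], , drop = FALSE]
  cx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  cy <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  cz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

#' Total surface area
#' @param mesh a [triangle_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot_mesh(mesh)
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(numeric(0))
  V <- mesh$vertices
  a <- V[mesh$faces[, 1], , drop = FALSE]
  u <- V[mesh$faces[, 2], , drop = FALSE] - a
  w <- V[mesh$faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

face_normals <- function(mesh) {
  V <- mesh$vertices
  a <- V[mesh$faces[, 1], , drop = FALSE]
  u <- V[mesh$faces[, 2], , drop = FALSE] - a
  w <- V[mesh$faces[, 3], , drop = FALSE] - a
  n <- cbind(
    u[, 2] * w[, 3] - u[, 3] * w[, 2],
    u[, 3] * w[, 1] - u[, 1] * w[, 3],
    u[, 1] * w[, 2] - u[, 2] * w[, 1]
  )
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_centroids <- function(mesh) {
  V <- mesh$vertices
  (V[mesh$faces[, 1], , drop = FALSE] +
     V[mesh$faces[, 2], , drop = FALSE] +
     V[mesh$faces[, 3], , drop = FALSE]) / 3
}

mesh_bbox <- function(mesh) {
  if (nrow(mesh$vertices) == 0)
    return(list(lo = c(0, 0, 0), hi = c(0, 0, 0), diag = 0))
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  list(lo = lo, hi = hi, diag = sqrt(sum((hi - lo)^2)))
}

#' Rigid translation of a mesh
#' @param mesh a [triangle_mesh()].
#' @param offset numeric length-3 translation, mm.
#' @return translated `triangle_mesh`.
#' @export
translate_mesh <- function(mesh, offset) {
  stopifnot_mesh(mesh)
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), `+`)
  mesh
}

#' Reverse the orientation of all faces
#' @param mesh a [triangle_mesh()].
#' @return mesh with flipped face windings.
#' @export
reverse_faces <- function(mesh) {
  stopifnot_mesh(mesh)
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

# concatenate meshes without any welding
concat_meshes <- function(...) {
  ms <- list(...)
  ms <- ms[vapply(ms, function(m) nrow(m$faces) > 0, logical(1))]
  if (length(ms) == 0) return(empty_mesh())
  off <- 0L
  V <- NULL
  F <- NULL
  for (m in ms) {
    V <- rbind(V, m$vertices)
    F <- rbind(F, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  triangle_mesh(V, F)
}

#' Weld coincident vertices
#'
#' Merges vertices closer than `tol` (union-find over a spatial grid) and
#' drops faces that become degenerate. Needed after STL reading (where each
#' facet stores its own vertex copies) and after Boolean assembly.
#'
#' @param mesh a [triangle_mesh()].
#' @param tol merge tolerance, mm.
#' @return welded `triangle_mesh`.
#' @export
merge_mesh_vertices <- function(mesh, tol) {
  stopifnot_mesh(mesh)
  if (nrow(mesh$vertices) == 0) return(mesh)
  res <- cpp_merge_vertices(mesh$vertices, mesh$faces, tol)
  F <- res$faces
  keep <- F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3]
  m <- triangle_mesh(res$vertices, F[keep, , drop = FALSE])
  drop_unused_vertices(m)
}

drop_unused_vertices <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(empty_mesh())
  used <- sort(unique(as.vector(mesh$faces)))
  idx <- integer(nrow(mesh$vertices))
  idx[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(idx[mesh$faces], ncol = 3))
}

#' Euler characteristic V - E + F
#' @param mesh a [triangle_mesh()].
#' @return integer Euler characteristic (2 for a sphere-like solid).
#' @export
euler_characteristic <- function(mesh) {
  stopifnot_mesh(mesh)
  if (nrow(mesh$faces) == 0) return(0L)
  k <- edge_keys(mesh$faces, nrow(mesh$vertices))
  nrow(mesh$vertices) - length(unique(k$undirected)) + nrow(mesh$faces)
}

#' Axis-aligned box mesh
#'
#' A 12-triangle watertight, outward-oriented box; handy as a fixture and
#' used by the phantom generators.
#'
#' @param lo,hi opposite corners, mm.
#' @return a `triangle_mesh`.
#' @export
make_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  V <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(V) <- NULL
  # corners indexed by bits (x=1, y=2, z=4), quads per face, CCW from outside
  quads <- rbind(
    c(1, 3, 4, 2),  # z = lo (viewed from below outside)
    c(5, 6, 8, 7),  # z = hi
    c(1, 2, 6, 5),  # y = lo
    c(3, 7, 8, 4),  # y = hi
    c(1, 5, 7, 3),  # x = lo
    c(2, 4, 8, 6)   # x = hi
  )
  F <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  m <- triangle_mesh(V, F)
  if (mesh_volume(m) < 0) m <- reverse_faces(m)
  m
}
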