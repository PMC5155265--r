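# Triangle-mesh Boolean engine: split both meshes along their intersection
# curve, classify the resulting cells by signed distance to the other solid,
# and assemble the kept cells into a watertight result.

seam_eps <- function(A, B = NULL) {
  V <- A$vertices
  if (!is.null(B)) V <- rbind(V, B$vertices)
  if (nrow(V) == 0) return(1e-9)
  d <- sqrt(sum((apply(V, 2, max) - apply(V, 2, min))^2))
  max(1e-7 * d, 1e-12)
}

#' Split two meshes along their intersection curve
#'
#' Computes all pairwise triangle-triangle intersection segments, re-triangulates
#' every intersected face so the segments become mesh edges, and chains the
#' segments into seam polylines. Non-intersected faces pass through untouched;
#' splitting only re-triangulates, so surface areas are conserved.
#'
#' @param A,B watertight, outward-oriented [triangle_mesh()]es. Coplanar
#'   overlapping contacts are supported: coplanar faces are split along each
#'   other's edges so the covered regions become separate cells.
#' @return a `split_pair`: list with `A_split`, `B_split` (meshes refined so
#'   the seam is embedded) and `seam` (list of polyline matrices, closed
#'   loops where chaining succeeded).
#' @export
split_at_intersection <- function(A, B) {
  sc <- split_core(A, B)
  structure(list(A_split = sc$A_split, B_split = sc$B_split, seam = sc$seam),
            class = "split_pair")
}

# full splitting machinery: also returns per-face provenance and the
# coplanar-overlap pair list needed for Boolean classification
split_core <- function(A, B) {
  stopifnot_mesh(A); stopifnot_mesh(B)
  if (!is_watertight(A) || !is_watertight(B))
    stop("split_at_intersection requires watertight (closed) meshes",
         call. = FALSE)
  eps <- seam_eps(A, B)
  passthrough <- function() {
    list(A_split = A, B_split = B, seam = list(),
         A_orig = seq_len(nrow(A$faces)), B_orig = seq_len(nrow(B$faces)),
         cop_pairs = matrix(integer(0), ncol = 2), eps = eps)
  }
  if (nrow(A$faces) == 0 || nrow(B$faces) == 0) return(passthrough())
  pairs <- cpp_box_pairs(A$vertices, A$faces, B$vertices, B$faces, eps)
  if (nrow(pairs) == 0) return(passthrough())
  sr <- cpp_tritri_segments(A$vertices, A$faces, B$vertices, B$faces, pairs,
                            eps)
  if (length(sr$faceA) == 0 && length(sr$copA_face) == 0 &&
        length(sr$copB_face) == 0)
    return(passthrough())
  segA <- rbind(sr$segments, sr$copA_segs)
  facA <- c(sr$faceA, sr$copA_face)
  segB <- rbind(sr$segments, sr$copB_segs)
  facB <- c(sr$faceB, sr$copB_face)
  As <- cpp_split_faces(A$vertices, A$faces, facA, segA, eps)
  Bs <- cpp_split_faces(B$vertices, B$faces, facB, segB, eps)
  list(
    A_split = triangle_mesh(As$vertices, As$faces),
    B_split = triangle_mesh(Bs$vertices, Bs$faces),
    seam = chain_segments_3d(sr$segments, eps),
    A_orig = As$orig_face, B_orig = Bs$orig_face,
    cop_pairs = sr$cop_pairs, eps = eps
  )
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("split_pair: A %d faces, B %d faces, %d seam polyline(s)\n",
              nrow(x$A_split$faces), nrow(x$B_split$faces), length(x$seam)))
  invisible(x)
}

# chain 3D segments (n x 6) into polylines by welding endpoints within tol;
# endpoint lookup scans the 8 quantization cells around each query point so
# matches never straddle a cell boundary
chain_segments_3d <- function(segs, tol) {
  n <- nrow(segs)
  if (n == 0) return(list())
  cell <- 2 * tol
  P <- rbind(segs[, 1:3, drop = FALSE], segs[, 4:6, drop = FALSE])
  keys <- paste(floor(P[, 1] / cell), floor(P[, 2] / cell),
                floor(P[, 3] / cell))
  lookup <- split(seq_len(2 * n), keys)  # endpoint id s + (e-1)*n
  used <- logical(n)
  find_partner <- function(cur) {
    ks <- unique(paste(
      rep(floor((cur[1] + c(-tol, tol)) / cell), each = 4),
      rep(rep(floor((cur[2] + c(-tol, tol)) / cell), each = 2), 2),
      rep(floor((cur[3] + c(-tol, tol)) / cell), 4)
    ))
    best <- NULL
    bestd <- 2 * tol
    for (k in ks) {
      for (id in lookup[[k]]) {
        cs <- ((id - 1) %% n) + 1
        if (used[cs]) next
        d <- sqrt(sum((P[id, ] - cur)^2))
        if (d < bestd) { bestd <- d; best <- c(cs, if (id > n) 2L else 1L) }
      }
    }
    best
  }
  loops <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    pts <- segs[s0, 1:3]
    seg <- s0; endi <- 2L
    used[s0] <- TRUE
    closed <- FALSE
    repeat {
      cur <- if (endi == 1L) segs[seg, 1:3] else segs[seg, 4:6]
      pts <- rbind(pts, cur)
      nxt <- find_partner(cur)
      if (is.null(nxt)) {
        closed <- sqrt(sum((cur - segs[s0, 1:3])^2)) <= 4 * tol
        break
      }
      used[nxt[1]] <- TRUE
      seg <- nxt[1]
      endi <- if (nxt[2] == 1L) 2L else 1L
    }
    loops[[length(loops) + 1]] <- structure(pts, closed = closed,
                                            dimnames = NULL)
  }
  loops
}

#' Extract mesh cells by signed distance to a reference solid
#'
#' Keeps the faces whose centroid has nonnegative (outside/on) or
#' nonpositive (inside/on) signed distance to the reference mesh, with a
#' boundary tolerance of 1e-6 of the bounding-box diagonal. Cells adjacent
#' to the intersection seam are classified by their centroid — strictly off
#' the seam after splitting — never by their (distance-zero) seam vertices.
#'
#' @param mesh the (already split) [triangle_mesh()] to filter.
#' @param reference a watertight [triangle_mesh()] defining inside/outside.
#' @param keep "nonnegative" or "nonpositive".
#' @return the kept sub-mesh.
#' @export
classify_cells <- function(mesh, reference,
                           keep = c("nonnegative", "nonpositive")) {
  keep <- match.arg(keep)
  stopifnot_mesh(mesh)
  if (!is_watertight(reference))
    stop("reference mesh must be watertight", call. = FALSE)
  if (nrow(mesh$faces) == 0) return(mesh)
  if (nrow(reference$faces) == 0) {
    return(if (keep == "nonnegative") mesh else empty_mesh())
  }
  eps_cls <- 1e-6 * seam_eps(mesh, reference) / 1e-7
  cen <- face_centroids(mesh)
  d <- cpp_nearest_distance(reference$vertices, reference$faces, cen)
  w <- cpp_winding_number(reference$vertices, reference$faces, cen)
  sd <- ifelse(w > 0.5, -d, d)
  sel <- if (keep == "nonnegative") sd >= -eps_cls else sd <= eps_cls
  drop_unused_vertices(
    triangle_mesh(mesh$vertices, mesh$faces[sel, , drop = FALSE])
  )
}

# keep/drop decision for one side of a Boolean, with coplanar-coverage
# handling: a cell of `mesh` whose parent face overlaps a coplanar face of
# the reference is classified by normal agreement, not by (zero) distance
boolean_classify <- function(mesh, orig_face, reference, cop_partners,
                             side, op, eps) {
  m <- nrow(mesh$faces)
  if (m == 0) return(logical(0))
  eps_cls <- 10 * eps  # 1e-6 of the bounding-box diagonal
  cen <- face_centroids(mesh)
  d <- cpp_nearest_distance(reference$vertices, reference$faces, cen)
  w <- cpp_winding_number(reference$vertices, reference$faces, cen)
  sd <- ifelse(w > 0.5, -d, d)
  keepdist <- switch(paste(side, op),
    "A difference" = sd >= -eps_cls,
    "A union" = sd >= -eps_cls,
    "A intersection" = sd <= eps_cls,
    "B difference" = sd <= eps_cls,
    "B union" = sd >= -eps_cls,
    "B intersection" = sd <= eps_cls
  )
  if (length(cop_partners) == 0) return(keepdist)
  nrm <- face_normals(mesh)
  rn <- face_normals(reference)
  RV <- reference$vertices
  RF <- reference$faces
  for (i in which(as.character(orig_face) %in% names(cop_partners))) {
    partners <- cop_partners[[as.character(orig_face[i])]]
    covered <- FALSE
    same <- TRUE
    for (b in partners) {
      p0 <- RV[RF[b, 1], ]; p1 <- RV[RF[b, 2], ]; p2 <- RV[RF[b, 3], ]
      nb <- rn[b, ]
      if (abs(sum((cen[i, ] - p0) * nb)) > eps_cls) next
      # 2D barycentric containment in the partner's dominant plane
      ax <- which.max(abs(nb))
      keepax <- setdiff(1:3, ax)
      q <- cen[i, keepax]; a <- p0[keepax]; bb <- p1[keepax]; cc <- p2[keepax]
      o <- function(u, v, x) (v[1] - u[1]) * (x[2] - u[2]) -
        (v[2] - u[2]) * (x[1] - u[1])
      oT <- o(a, bb, cc)
      if (oT == 0) next
      s0 <- o(a, bb, q) / oT; s1 <- o(bb, cc, q) / oT; s2 <- o(cc, a, q) / oT
      if (s0 >= -1e-7 && s1 >= -1e-7 && s2 >= -1e-7) {
        covered <- TRUE
        same <- sum(nrm[i, ] * nb) > 0
        break
      }
    }
    if (covered) {
      keepdist[i] <- if (side == "B") FALSE
      else switch(op, difference = !same, union = same, intersection = same)
    }
  }
  keepdist
}

# canonical face parity for cancelling-pair removal
face_parity <- function(F) {
  lo <- max.col(-F)  # column of the smallest index per row
  rot <- function(f, k) f[((seq_len(3) + k - 2) %% 3) + 1]
  out <- matrix(0L, nrow(F), 3)
  for (i in seq_len(nrow(F))) out[i, ] <- rot(F[i, ], lo[i])
  list(key = paste(out[, 1], pmin(out[, 2], out[, 3]),
                   pmax(out[, 2], out[, 3])),
       parity = ifelse(out[, 2] < out[, 3], 1L, -1L))
}

# remove pairs of identical faces with opposite orientation (zero-thickness
# fins left by collapsed near-coincident sheets)
cancel_opposite_faces <- function(mesh) {
  if (nrow(mesh$faces) < 2) return(mesh)
  fp <- face_parity(mesh$faces)
  keep <- rep(TRUE, nrow(mesh$faces))
  for (grp in split(seq_len(nrow(mesh$faces)), fp$key)) {
    if (length(grp) < 2) next
    pos <- grp[fp$parity[grp] > 0]
    neg <- grp[fp$parity[grp] < 0]
    nc <- min(length(pos), length(neg))
    if (nc > 0) keep[c(pos[seq_len(nc)], neg[seq_len(nc)])] <- FALSE
  }
  if (all(keep)) return(mesh)
  drop_unused_vertices(
    triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
  )
}

finalize_boolean <- function(mesh, eps) {
  if (nrow(mesh$faces) == 0) return(empty_mesh())
  out <- cancel_opposite_faces(merge_mesh_vertices(mesh, eps))
  for (pass in 1:3) {
    if (is_watertight(out) || nrow(out$faces) == 0) break
    fixed <- cpp_fix_tjunctions(out$vertices, out$faces, eps)
    out <- cancel_opposite_faces(
      merge_mesh_vertices(triangle_mesh(fixed$vertices, fixed$faces), eps)
    )
  }
  out
}

#' Boolean operations on watertight triangle meshes
#'
#' Difference keeps the cells of A at nonnegative signed distance from B
#' together with the cells of B at nonpositive distance from A (the latter
#' with orientation reversed so the result stays outward); union keeps the
#' mutually-outside cells; intersection the mutually-inside cells. Seam
#' vertices are shared between the two patches, so a valid result is
#' watertight.
#'
#' Exactly coplanar overlapping contacts (common in CAD fixtures and
#' identical-operand cases) are handled exactly: coplanar faces are split
#' along each other's edges and the covered cells classified by normal
#' agreement, so A - A is exactly empty and shared-face solids subtract
#' cleanly. As a last resort a deterministic tiny perturbation of B
#' (translation of 1e-9 of the bounding-box diagonal, fixed seed) is retried
#' once when the assembled result fails the watertightness check.
#'
#' @param A,B watertight, outward-oriented [triangle_mesh()]es.
#' @param op "difference", "union" or "intersection".
#' @param jitter allow the perturbation fallback (default TRUE).
#' @return the result `triangle_mesh` (empty result is an empty mesh, not an
#'   error).
#' @export
mesh_boolean <- function(A, B, op = c("difference", "union", "intersection"),
                         jitter = TRUE) {
  op <- match.arg(op)
  stopifnot_mesh(A); stopifnot_mesh(B)
  if (nrow(A$faces) == 0)
    return(switch(op, difference = empty_mesh(), intersection = empty_mesh(),
                  union = B))
  if (nrow(B$faces) == 0)
    return(switch(op, difference = A, intersection = empty_mesh(), union = A))
  if (!is_watertight(A) || !is_watertight(B))
    stop("mesh_boolean requires watertight meshes", call. = FALSE)

  out <- boolean_once(A, B, op)
  if (!is_watertight(out) && jitter) {
    delta <- with_seed(0, stats::runif(3, -1, 1))
    delta <- delta / sqrt(sum(delta^2)) * 1e-9 * (seam_eps(A, B) / 1e-7)
    out2 <- boolean_once(A, translate_mesh(B, delta), op)
    if (is_watertight(out2)) out <- out2
  }
  out
}

boolean_once <- function(A, B, op) {
  sc <- split_core(A, B)
  # coplanar partner map: original face id -> overlapped faces of the other
  partA <- partB <- list()
  if (nrow(sc$cop_pairs) > 0) {
    partA <- split(sc$cop_pairs[, 2], sc$cop_pairs[, 1])
    partB <- split(sc$cop_pairs[, 1], sc$cop_pairs[, 2])
  }
  selA <- boolean_classify(sc$A_split, sc$A_orig, B, partA, "A", op, sc$eps)
  selB <- boolean_classify(sc$B_split, sc$B_orig, A, partB, "B", op, sc$eps)
  Apart <- drop_unused_vertices(triangle_mesh(
    sc$A_split$vertices, sc$A_split$faces[selA, , drop = FALSE]))
  Bpart <- drop_unused_vertices(triangle_mesh(
    sc$B_split$vertices, sc$B_split$faces[selB, , drop = FALSE]))
  if (op == "difference") Bpart <- reverse_faces(Bpart)
  finalize_boolean(concat_meshes(Apart, Bpart), sc$eps)
}
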