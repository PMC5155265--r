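# Undercut elimination: swept-silhouette "temporary model" construction
# (slice -> accumulate -> rasterize -> morphology -> isosurface) and its
# subtraction from the splint.

#' Planar contour stack of a mesh along a direction
#'
#' Cuts the mesh with planes orthogonal to `direction` at fixed `spacing`,
#' spanning the mesh extent. Each slice holds the closed intersection loops,
#' consistently oriented (counter-clockwise = material inside,
#' clockwise = hole). Slices are ordered by decreasing coordinate along the
#' direction: the first slice is the far end in the removal direction.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param direction slicing/removal direction (3-vector, normalized).
#' @param spacing plane spacing, mm (> 0).
#' @return a `contour_stack`.
#' @export
slice_contours <- function(mesh, direction, spacing) {
  stopifnot_mesh(mesh)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (!is_watertight(mesh))
    stop("slice_contours requires a watertight mesh (open loops otherwise)",
         call. = FALSE)
  d <- unit3(direction)
  R <- rotation_to_z(d)
  Vr <- mesh$vertices %*% t(R)
  zmin <- min(Vr[, 3]); zmax <- max(Vr[, 3])
  extent <- max(zmax - zmin, spacing)
  ztol <- 1e-7 * extent
  top <- zmax - spacing / 2
  if (top < zmin) top <- (zmin + zmax) / 2
  zs <- seq(top, zmin, by = -spacing)
  # nudge planes that graze a vertex
  vz <- sort(unique(Vr[, 3]))
  for (i in seq_along(zs)) {
    for (pass in 1:3) {
      j <- findInterval(zs[i], vz)
      near <- c(if (j >= 1) vz[j], if (j < length(vz)) vz[j + 1])
      if (length(near) && min(abs(near - zs[i])) < ztol) {
        zs[i] <- zs[i] + 2 * ztol
      } else break
    }
  }
  qtol <- max(1e-9 * mesh_bbox(mesh)$diag, 1e-12)
  res <- cpp_slice_mesh(Vr, mesh$faces, zs, qtol)
  if (any(res$n_open > 0))
    stop("open contour loops encountered while slicing", call. = FALSE)
  slices <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    slices[[i]] <- list(offset = zs[i], loops = orient_loops(res$loops[[i]]))
  }
  structure(
    list(direction = d, spacing = spacing, slices = slices, frame = R),
    class = "contour_stack"
  )
}

#' @export
print.contour_stack <- function(x, ...) {
  nl <- sum(vapply(x$slices, function(s) length(s$loops), integer(1)))
  cat(sprintf("contour_stack: %d slices, %d loops, spacing %g mm\n",
              length(x$slices), nl, x$spacing))
  invisible(x)
}

# even-odd point-in-polygon (single point, loop matrix k x 2)
point_in_loop <- function(pt, P) {
  k <- nrow(P)
  x0 <- P[, 1]; y0 <- P[, 2]
  x1 <- P[c(2:k, 1), 1]; y1 <- P[c(2:k, 1), 2]
  up <- (y0 <= pt[2]) & (pt[2] < y1)
  dn <- (y1 <= pt[2]) & (pt[2] < y0)
  sel <- up | dn
  if (!any(sel)) return(FALSE)
  t <- (pt[2] - y0[sel]) / (y1[sel] - y0[sel])
  xc <- x0[sel] + (x1[sel] - x0[sel]) * t
  (sum(xc > pt[1]) %% 2) == 1
}

loop_area <- function(P) {
  k <- nrow(P)
  x <- P[, 1]; y <- P[, 2]
  xn <- x[c(2:k, 1)]; yn <- y[c(2:k, 1)]
  sum(x * yn - xn * y) / 2
}

# outer loops CCW (even nesting depth), holes CW (odd depth)
orient_loops <- function(loops) {
  nl <- length(loops)
  if (nl == 0) return(loops)
  depth <- integer(nl)
  if (nl > 1) {
    for (i in seq_len(nl)) {
      pt <- loops[[i]][1, ]
      for (j in seq_len(nl)) {
        if (i != j && point_in_loop(pt, loops[[j]]))
          depth[i] <- depth[i] + 1L
      }
    }
  }
  for (i in seq_len(nl)) {
    a <- loop_area(loops[[i]])
    ccw_wanted <- depth[i] %% 2 == 0
    if ((a > 0) != ccw_wanted)
      loops[[i]] <- loops[[i]][rev(seq_len(nrow(loops[[i]]))), , drop = FALSE]
  }
  loops
}

#' Cumulative sweep accumulation of a contour stack
#'
#' Marching opposite to the removal direction (from the first, far-end
#' slice), each output slice receives the union of all slices before it:
#' the occupancy of output slice i is the union of input slices 1..i. The
#' union is realized by appending the consistently-oriented contours and
#' filling with the nonzero winding rule at rasterization, so once a column
#' is occupied it stays occupied.
#'
#' @param stack a [slice_contours()] result (slices ordered first = far end).
#' @return the accumulated `contour_stack`.
#' @export
accumulate_sweep <- function(stack) {
  if (!inherits(stack, "contour_stack")) stop("not a contour_stack",
                                              call. = FALSE)
  offs <- vapply(stack$slices, `[[`, numeric(1), "offset")
  if (length(offs) > 1 && any(diff(offs) >= 0))
    stop("slices must be ordered by strictly decreasing offset", call. = FALSE)
  acc <- list()
  for (i in seq_along(stack$slices)) {
    acc <- c(acc, stack$slices[[i]]$loops)
    stack$slices[[i]]$loops <- acc
  }
  attr(stack, "accumulated") <- TRUE
  stack
}

#' Axis-aligned occupancy volumes
#'
#' A `binary_volume` is an isotropic occupancy grid: `origin` is the world
#' position of the centre of voxel (1,1,1) in the stack's (possibly rotated)
#' frame, `spacing` the voxel edge, `values` a 0/1 array. Volumes carry a
#' one-voxel zero padding on all six faces so extracted isosurfaces are
#' closed.
#'
#' @param origin numeric length-3 centre of the first voxel, mm.
#' @param spacing voxel size, mm.
#' @param values 0/1 3D array.
#' @param frame optional 3x3 rotation mapping world to volume coordinates.
#' @return a `binary_volume`.
#' @export
binary_volume <- function(origin, spacing, values, frame = NULL) {
  stopifnot(length(dim(values)) == 3, spacing > 0)
  storage.mode(values) <- "double"
  if (any(values != 0 & values != 1)) stop("values must be 0/1", call. = FALSE)
  structure(
    list(origin = as.numeric(origin), spacing = spacing,
         dims = dim(values), values = values, frame = frame),
    class = "binary_volume"
  )
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("binary_volume: %d x %d x %d voxels at %g mm, %d occupied\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, sum(x$values)))
  invisible(x)
}

#' Rasterize a contour stack into a binary volume
#'
#' Fills each slice's polygons at voxel centres (nonzero winding rule, holes
#' supported) and stacks the slabs into a volume whose extent is the stack's
#' bounding box plus a one-voxel zero pad. Voxel layers map to the nearest
#' slice plane.
#'
#' @param stack a [contour_stack].
#' @param spacing voxel size, mm.
#' @return a [binary_volume()].
#' @export
rasterize_stack <- function(stack, spacing) {
  if (!inherits(stack, "contour_stack")) stop("not a contour_stack",
                                              call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  allp <- do.call(rbind, unlist(lapply(stack$slices, `[[`, "loops"),
                                recursive = FALSE))
  offs <- vapply(stack$slices, `[[`, numeric(1), "offset")
  if (is.null(allp) || nrow(allp) == 0) {
    vals <- array(0, c(3, 3, 3))
    return(binary_volume(c(0, 0, 0) - spacing, spacing, vals,
                         frame = stack$frame))
  }
  xmin <- min(allp[, 1]); xmax <- max(allp[, 1])
  ymin <- min(allp[, 2]); ymax <- max(allp[, 2])
  zmin <- min(offs); zmax <- max(offs)
  ncx <- floor((xmax - xmin) / spacing + 1e-9) + 1
  ncy <- floor((ymax - ymin) / spacing + 1e-9) + 1
  ncz <- floor((zmax - zmin) / spacing + 1e-9) + 1
  dims <- c(ncx, ncy, ncz) + 2
  if (prod(dims) > 512^3)
    stop(sprintf(
      "voxel volume %d x %d x %d exceeds the 512^3 memory guard; increase voxel spacing",
      dims[1], dims[2], dims[3]), call. = FALSE)
  vals <- array(0, dims)
  xs <- xmin + (seq_len(ncx) - 1) * spacing
  ys <- ymin + (seq_len(ncy) - 1) * spacing
  zs <- zmin + (seq_len(ncz) - 1) * spacing
  epsb <- 1e-6 * spacing
  sl_of_layer <- vapply(zs, function(z) which.min(abs(offs - z)), integer(1))
  filled <- list()
  for (k in seq_len(ncz)) {
    si <- sl_of_layer[k]
    key <- as.character(si)
    if (is.null(filled[[key]])) {
      loops <- stack$slices[[si]]$loops
      filled[[key]] <- if (length(loops) == 0) {
        matrix(FALSE, ncx, ncy)
      } else {
        cpp_fill_polygons(loops, xs, ys, epsb)
      }
    }
    vals[2:(ncx + 1), 2:(ncy + 1), k + 1] <- filled[[key]] * 1
  }
  binary_volume(c(xmin, ymin, zmin) - spacing, spacing, vals,
                frame = stack$frame)
}

shift_array <- function(a, axis, by) {
  out <- array(0, dim(a))
  n <- dim(a)[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  idx_src <- lapply(dim(a), seq_len)
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

dilate6 <- function(a) {
  out <- a
  for (ax in 1:3) for (by in c(-1, 1)) out <- pmax(out, shift_array(a, ax, by))
  out
}

erode6 <- function(a) {
  out <- a
  for (ax in 1:3) for (by in c(-1, 1)) out <- pmin(out, shift_array(a, ax, by))
  out
}

dilate26 <- function(a) {
  out <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- pmax(out, shift_array(shift_array(shift_array(a, 1, dx), 2, dy),
                                 3, dz))
  }
  out
}

repad_volume <- function(vol) {
  v <- vol$values
  d <- dim(v)
  boundary_occ <- sum(v[1, , ], v[d[1], , ], v[, 1, ], v[, d[2], ],
                      v[, , 1], v[, , d[3]])
  if (boundary_occ == 0) return(vol)
  nv <- array(0, d + 2)
  nv[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  binary_volume(vol$origin - vol$spacing, vol$spacing, nv, frame = vol$frame)
}

#' Morphological closing of a binary volume
#'
#' Dilation followed by erosion with a 6-connected (face-adjacent)
#' structuring element, applied `iterations` times, to heal rasterization
#' gaps before isosurface extraction. The zero padding is preserved
#' (re-padded if a dilation reaches the boundary).
#'
#' @param volume a [binary_volume()].
#' @param iterations non-negative closing count.
#' @return the closed `binary_volume`.
#' @export
close_volume <- function(volume, iterations = 1) {
  if (!inherits(volume, "binary_volume")) stop("not a binary_volume",
                                               call. = FALSE)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  for (i in seq_len(iterations)) {
    volume$values <- dilate6(volume$values)
    volume <- repad_volume(volume)
    volume$values <- erode6(volume$values)
  }
  volume
}

#' Isosurface extraction from a binary volume
#'
#' Extracts the closed, outward-oriented isosurface at level `iso` by a
#' fixed tetrahedral decomposition of each grid cell (an unambiguous,
#' complementary-safe marching-cubes variant); vertices lie on cell-edge
#' crossings by linear interpolation. Requires the one-voxel zero padding so
#' every surface is closed.
#'
#' @param volume a padded [binary_volume()].
#' @param iso iso level (default 0.5).
#' @return a watertight `triangle_mesh` (empty for an all-zero volume).
#' @export
marching_cubes <- function(volume, iso = 0.5) {
  if (!inherits(volume, "binary_volume")) stop("not a binary_volume",
                                               call. = FALSE)
  v <- volume$values
  d <- dim(v)
  if (sum(v[1, , ], v[d[1], , ], v[, 1, ], v[, d[2], ], v[, , 1],
          v[, , d[3]]) > 0)
    stop("volume boundary is occupied (unpadded); re-pad before extraction",
         call. = FALSE)
  if (sum(v) == 0) return(empty_mesh())
  res <- cpp_marching_tets(as.vector(v), d[1], d[2], d[3], volume$origin,
                           volume$spacing, iso)
  V <- res$vertices
  if (!is.null(volume$frame)) V <- V %*% volume$frame
  m <- triangle_mesh(V, res$faces)
  if (mesh_volume(m) < 0) m <- reverse_faces(m)
  m
}

#' Swept-silhouette temporary model of a solid along a removal direction
#'
#' Reconstructs the solid swept by the input model as it travels along the
#' removal direction: contours are sliced, accumulated cumulatively from the
#' far end, extended by `extension` mm opposite the removal direction so the
#' swept solid clears the splint, rasterized, morphologically closed, and
#' isosurfaced. Subtracting this temporary model from a splint removes every
#' undercut with respect to the direction.
#'
#' @param mesh watertight [triangle_mesh()] (the dentition model).
#' @param removal_direction the draw direction (3-vector).
#' @param slice_spacing contour plane spacing, mm (default 0.5).
#' @param voxel_spacing voxel size, mm (default 0.25).
#' @param closing_iterations morphological closings (default 1).
#' @param extension extra sweep length opposite the removal direction, mm;
#'   defaults to the model extent along the direction.
#' @param clearance_voxels extra 26-connected dilations of the occupancy
#'   grid (default 0); used by [eliminate_interference()] as a seating
#'   clearance.
#' @return watertight `triangle_mesh` of the temporary (swept) model.
#' @export
sweep_model <- function(mesh, removal_direction, slice_spacing = 0.5,
                        voxel_spacing = 0.25, closing_iterations = 1,
                        extension = NULL, clearance_voxels = 0) {
  d <- unit3(removal_direction)
  stack <- accumulate_sweep(slice_contours(mesh, d, slice_spacing))
  offs <- vapply(stack$slices, `[[`, numeric(1), "offset")
  if (is.null(extension)) extension <- max(offs) - min(offs)
  if (extension > 0) {
    last <- stack$slices[[length(stack$slices)]]
    n_extra <- ceiling(extension / slice_spacing - 1e-9)
    extra <- min(offs) - slice_spacing * seq_len(n_extra)
    for (z in extra)
      stack$slices[[length(stack$slices) + 1]] <-
        list(offset = z, loops = last$loops)
  }
  vol <- close_volume(rasterize_stack(stack, voxel_spacing),
                      closing_iterations)
  if (clearance_voxels > 0) {
    for (i in seq_len(clearance_voxels)) {
      vol$values <- dilate26(vol$values)
      vol <- repad_volume(vol)
    }
  }
  marching_cubes(vol)
}

#' Remove splint undercuts along a removal direction
#'
#' Builds the swept temporary model of the dentition along the removal
#' direction (with a one-voxel seating clearance by default) and subtracts
#' it from the splint, so the result can be removed along the direction
#' without interference.
#'
#' @param splint,teeth watertight [triangle_mesh()]es.
#' @param removal_direction the draw direction (3-vector).
#' @param clearance_voxels 26-connected clearance dilations (default 1).
#' @inheritParams sweep_model
#' @return the interference-free splint as a `triangle_mesh`.
#' @export
eliminate_interference <- function(splint, teeth, removal_direction,
                                   slice_spacing = 0.5, voxel_spacing = 0.25,
                                   closing_iterations = 1, extension = NULL,
                                   clearance_voxels = 1) {
  stopifnot_mesh(splint); stopifnot_mesh(teeth)
  if (nrow(splint$faces) == 0) return(empty_mesh())
  tmp <- sweep_model(teeth, removal_direction, slice_spacing, voxel_spacing,
                     closing_iterations, extension, clearance_voxels)
  mesh_boolean(splint, tmp, "difference")
}
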