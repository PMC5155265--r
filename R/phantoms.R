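# Deterministic synthetic geometry standing in for patient-derived meshes:
# cone frusta (the canonical undercut shape), the analytic swept "standard
# model", and a toy dental arch with undercut teeth plus its splint plan.

#' Cone frustum phantom
#'
#' A watertight frustum with axis +z and base at z = 0. With
#' `r_top > r_bottom` this is the canonical "big-end-up" undercut shape used
#' to validate the sweep pipeline.
#'
#' @param r_bottom,r_top radii, mm (non-negative, not both zero).
#' @param height frustum height, mm (> 0).
#' @param n_segments circumferential resolution (>= 3).
#' @return a watertight `triangle_mesh`.
#' @export
make_cone_frustum <- function(r_bottom, r_top, height, n_segments = 64) {
  if (r_bottom < 0 || r_top < 0 || (r_bottom == 0 && r_top == 0))
    stop("radii must be non-negative and not both zero", call. = FALSE)
  if (height <= 0) stop("height must be > 0", call. = FALSE)
  if (n_segments < 3) stop("n_segments must be >= 3", call. = FALSE)
  n <- as.integer(n_segments)
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- function(r, z) cbind(r * cos(th), r * sin(th), z)
  nxt <- c(2:n, 1)

  if (r_bottom > 0 && r_top > 0) {
    V <- rbind(ring(r_bottom, 0), ring(r_top, height), c(0, 0, 0),
               c(0, 0, height))
    cb <- 2L * n + 1L; ct <- 2L * n + 2L
    i <- seq_len(n)
    F <- rbind(
      cbind(i, nxt, n + nxt), cbind(i, n + nxt, n + i),  # side
      cbind(cb, nxt, i),                                 # bottom cap
      cbind(ct, n + i, n + nxt)                          # top cap
    )
  } else if (r_top == 0) {
    V <- rbind(ring(r_bottom, 0), c(0, 0, height), c(0, 0, 0))
    apex <- n + 1L; cb <- n + 2L
    i <- seq_len(n)
    F <- rbind(cbind(i, nxt, apex), cbind(cb, nxt, i))
  } else {
    V <- rbind(ring(r_top, height), c(0, 0, 0), c(0, 0, height))
    apex <- n + 1L; ct <- n + 2L
    i <- seq_len(n)
    F <- rbind(cbind(nxt, i, apex), cbind(ct, i, nxt))
  }
  m <- triangle_mesh(V, F)
  if (mesh_volume(m) < 0) m <- reverse_faces(m)
  m
}

#' Icosphere phantom
#'
#' A watertight geodesic sphere obtained by subdividing an icosahedron and
#' projecting onto the sphere; the standard near-uniform faceted sphere for
#' volume and surface-distance validation.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions subdivision rounds (0 = icosahedron).
#' @param center centre, mm.
#' @return a watertight `triangle_mesh`.
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nV <- nrow(V)
    ekey <- function(a, b) pmin(a, b) * (nV + 1) + pmax(a, b)
    edges <- rbind(cbind(F[, 1], F[, 2]), cbind(F[, 2], F[, 3]),
                   cbind(F[, 3], F[, 1]))
    keys <- ekey(edges[, 1], edges[, 2])
    uk <- unique(keys)
    mididx <- nV + match(keys, uk)
    first <- !duplicated(keys)
    mids <- (V[edges[first, 1], , drop = FALSE] +
               V[edges[first, 2], , drop = FALSE]) / 2
    V <- rbind(V, mids)
    m12 <- mididx[seq_len(nrow(F))]
    m23 <- mididx[nrow(F) + seq_len(nrow(F))]
    m31 <- mididx[2 * nrow(F) + seq_len(nrow(F))]
    F <- rbind(cbind(F[, 1], m12, m31), cbind(F[, 2], m23, m12),
               cbind(F[, 3], m31, m23), cbind(m12, m23, m31))
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, as.numeric(center), `+`)
  m <- triangle_mesh(V, F)
  if (mesh_volume(m) < 0) m <- reverse_faces(m)
  m
}

#' Analytic standard swept model
#'
#' The ground-truth comparator for [sweep_model()] on a frustum: a cylinder
#' with the radius of the first contour cut by the slicing plane, spanning
#' the frustum height plus any sweep extension below the base.
#'
#' @param r_first_contour radius of the first (far-end) contour, mm.
#' @param height frustum height, mm.
#' @param n_segments circumferential resolution.
#' @param extension extra length below the base, mm.
#' @return a watertight cylinder `triangle_mesh`.
#' @export
make_standard_swept <- function(r_first_contour, height, n_segments = 64,
                                extension = 0) {
  m <- make_cone_frustum(r_first_contour, r_first_contour,
                         height + extension, n_segments)
  translate_mesh(m, c(0, 0, -extension))
}

#' Specification of the toy dental-arch phantom
#'
#' Two jaws, each a curved ridge block carrying `n_teeth` frustum teeth
#' placed along a semicircular arch. Crown radius exceeds base radius, so
#' every tooth has an undercut with respect to vertical removal; the jaws
#' face each other across `jaw_gap`.
#'
#' @param n_teeth teeth per jaw.
#' @param arch_radius arch centreline radius, mm.
#' @param tooth_base_radius,tooth_crown_radius frustum radii, mm
#'   (crown > base).
#' @param tooth_height tooth height, mm.
#' @param jaw_gap occlusal gap between crown tips, mm.
#' @param n_segments circumferential mesh resolution of the teeth.
#' @param seed placement seed (reserved for jitter; placement is
#'   deterministic).
#' @return an `arch_phantom_spec`.
#' @export
arch_phantom_spec <- function(n_teeth = 6, arch_radius = 30,
                              tooth_base_radius = 2, tooth_crown_radius = 3,
                              tooth_height = 6, jaw_gap = 10,
                              n_segments = 24, seed = 1) {
  if (tooth_crown_radius <= tooth_base_radius)
    stop("crown radius must exceed base radius (undercut required)",
         call. = FALSE)
  vals <- c(n_teeth, arch_radius, tooth_base_radius, tooth_crown_radius,
            tooth_height, jaw_gap, n_segments)
  if (any(vals <= 0)) stop("all dimensions must be positive", call. = FALSE)
  structure(
    list(n_teeth = as.integer(n_teeth), arch_radius = arch_radius,
         tooth_base_radius = tooth_base_radius,
         tooth_crown_radius = tooth_crown_radius,
         tooth_height = tooth_height, jaw_gap = jaw_gap,
         n_segments = as.integer(n_segments), seed = seed),
    class = "arch_phantom_spec"
  )
}

arch_angles <- function(spec) {
  seq(pi * 5 / 6, pi * 1 / 6, length.out = spec$n_teeth)
}

arch_ridge_geom <- function(spec) {
  list(width = 2 * spec$tooth_crown_radius + 2,
       height = 4,
       sink = 0.5,
       theta = seq(pi * 5 / 6 + 0.12, pi * 1 / 6 - 0.12, length.out = 49))
}

# one jaw: curved ridge block united with its frustum teeth; `upper` selects
# the maxilla (teeth pointing down, big end down)
make_jaw <- function(spec, upper) {
  g <- arch_ridge_geom(spec)
  ang <- arch_angles(spec)
  R <- spec$arch_radius
  gap2 <- spec$jaw_gap / 2
  h <- spec$tooth_height
  chord <- 2 * R * sin(abs(diff(ang[1:2])) / 2)
  if (spec$n_teeth > 1 && chord < 2 * spec$tooth_crown_radius + 0.2)
    stop("overlapping teeth: crowns wider than their arch spacing",
         call. = FALSE)
  s <- if (upper) 1 else -1
  # ridge block: annular-sector tube; teeth sink 0.5 mm into it
  z0 <- s * (gap2 + h - g$sink)
  z1 <- z0 + s * g$height
  zlo <- min(z0, z1); zhi <- max(z0, z1)
  th <- g$theta
  arc <- function(r, z) cbind(r * cos(th), r * sin(th), z)
  ridge <- closed_tube(
    arc(R - g$width / 2, zlo), arc(R - g$width / 2, zhi),
    arc(R + g$width / 2, zhi), arc(R + g$width / 2, zlo)
  )
  jaw <- ridge
  for (a in ang) {
    tooth <- if (upper) {
      # big end (crown) down, tip plane at z = +gap/2
      translate_mesh(
        make_cone_frustum(spec$tooth_crown_radius, spec$tooth_base_radius,
                          h, spec$n_segments),
        c(R * cos(a), R * sin(a), gap2))
    } else {
      # big end up, tip plane at z = -gap/2
      translate_mesh(
        make_cone_frustum(spec$tooth_base_radius, spec$tooth_crown_radius,
                          h, spec$n_segments),
        c(R * cos(a), R * sin(a), -gap2 - h))
    }
    jaw <- mesh_boolean(jaw, tooth, "union")
  }
  jaw
}

#' Toy dental-arch phantom
#'
#' Builds the two jaw solids of the [arch_phantom_spec()]: each jaw is the
#' Boolean union of a curved ridge block and its frustum teeth, watertight
#' and deterministic (identical output for identical spec and seed).
#'
#' @param spec an [arch_phantom_spec()].
#' @return list with `maxilla` and `mandible` `triangle_mesh`es.
#' @export
make_arch_phantom <- function(spec) {
  if (!inherits(spec, "arch_phantom_spec"))
    stop("not an arch_phantom_spec", call. = FALSE)
  list(maxilla = make_jaw(spec, upper = TRUE),
       mandible = make_jaw(spec, upper = FALSE))
}

# world coordinates of the crown tip centres of one jaw
crown_tips <- function(spec, upper) {
  ang <- arch_angles(spec)
  z <- if (upper) spec$jaw_gap / 2 else -spec$jaw_gap / 2
  cbind(spec$arch_radius * cos(ang), spec$arch_radius * sin(ang), z)
}

#' Auto-generated splint plan for the arch phantom
#'
#' Places one up line and one down line per tooth position: anchors on the
#' arch centreline just beyond the crown tips, bucco-lingual (radial) axes,
#' and extents covering the ridge width plus a margin, so the built splint
#' base encloses every crown tip.
#'
#' @param spec an [arch_phantom_spec()].
#' @param samples_per_span spline samples per span (default 10).
#' @return a [splint_plan()].
#' @export
make_plan_for_arch <- function(spec, samples_per_span = 10) {
  if (!inherits(spec, "arch_phantom_spec"))
    stop("not an arch_phantom_spec", call. = FALSE)
  g <- arch_ridge_geom(spec)
  ang <- arch_angles(spec)
  # swing the end lines past the last teeth so the end caps clear the crowns
  margin <- 0.08
  ang[1] <- ang[1] + margin
  ang[length(ang)] <- ang[length(ang)] - margin
  R <- spec$arch_radius
  half <- g$width / 2 + 1
  z_up <- spec$jaw_gap / 2 + 2
  z_dn <- -spec$jaw_gap / 2 - 2
  mk <- function(z) lapply(ang, function(a) {
    landmark_line(anchor = c(R * cos(a), R * sin(a), z),
                  direction = c(cos(a), sin(a), 0),
                  inner_length = half, outside_length = half)
  })
  splint_plan(up_lines = mk(z_up), down_lines = mk(z_dn),
              samples_per_span = samples_per_span)
}
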