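# Initial splint construction: interpolating spline resampling of landmark
# lines and ruled-surface sheet assembly into a closed solid.

# Chordal (chord-length parameterized) Catmull-Rom through the rows of P,
# sampled with `per_span` sub-intervals per span; interpolates every input
# point exactly. End ghost points extrapolate the quadratic through the
# first/last three points, which keeps end spans as accurate as interior
# ones on smooth arches.
catmull_rom_resample <- function(P, per_span) {
  k <- nrow(P)
  chord <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-k, , drop = FALSE])^2))
  if (any(chord < 1e-12))
    stop("coincident consecutive anchors (zero chord)", call. = FALSE)
  tk <- c(0, cumsum(chord))
  g0 <- if (k >= 3) 3 * P[1, ] - 3 * P[2, ] + P[3, ] else 2 * P[1, ] - P[2, ]
  g1 <- if (k >= 3) 3 * P[k, ] - 3 * P[k - 1, ] + P[k - 2, ]
        else 2 * P[k, ] - P[k - 1, ]
  Pg <- rbind(g0, P, g1)
  c0 <- max(sqrt(sum((g0 - P[1, ])^2)), 1e-12)
  c1 <- max(sqrt(sum((g1 - P[k, ])^2)), 1e-12)
  tg <- c(tk[1] - c0, tk, tk[k] + c1)

  out <- matrix(0, (k - 1) * per_span + 1, 3)
  row <- 1L
  for (j in seq_len(k - 1)) {
    i <- j + 1L  # ghost-padded index of span start
    t0 <- tg[i - 1]; t1 <- tg[i]; t2 <- tg[i + 1]; t3 <- tg[i + 2]
    P0 <- Pg[i - 1, ]; P1 <- Pg[i, ]; P2 <- Pg[i + 1, ]; P3 <- Pg[i + 2, ]
    nlast <- if (j == k - 1) per_span else per_span - 1L
    for (s in 0:nlast) {
      t <- t1 + (t2 - t1) * s / per_span
      if (s == 0) {
        out[row, ] <- P1
      } else if (s == per_span) {
        out[row, ] <- P2
      } else {
        # Barry-Goldman pyramid
        A1 <- (t1 - t) / (t1 - t0) * P0 + (t - t0) / (t1 - t0) * P1
        A2 <- (t2 - t) / (t2 - t1) * P1 + (t - t1) / (t2 - t1) * P2
        A3 <- (t3 - t) / (t3 - t2) * P2 + (t - t2) / (t3 - t2) * P3
        B1 <- (t2 - t) / (t2 - t0) * A1 + (t - t0) / (t2 - t0) * A2
        B2 <- (t3 - t) / (t3 - t1) * A2 + (t - t1) / (t3 - t1) * A3
        out[row, ] <- (t2 - t) / (t2 - t1) * B1 + (t - t1) / (t2 - t1) * B2
      }
      row <- row + 1L
    }
  }
  out
}

#' Resample a series of landmark lines into dense endpoint splines
#'
#' Fits two interpolating parametric splines (chordal Catmull-Rom) — one
#' through all inner endpoints and one through all outside endpoints of the
#' ordered lines — and samples both on the same per-span parameter grid,
#' giving `(length(lines) - 1) * samples_per_span + 1` aligned point pairs.
#' The original endpoints are reproduced exactly.
#'
#' @param lines list of >= 2 [landmark_line()]s, ordered along the arch.
#' @param samples_per_span sub-intervals per consecutive-line span (>= 2).
#' @param spline_kind interpolating spline family ("catmull-rom").
#' @return list with matrices `inner` and `outer` (aligned samples).
#' @export
resample_line_series <- function(lines, samples_per_span = 10,
                                 spline_kind = "catmull-rom") {
  if (length(lines) < 2) stop("need at least 2 lines", call. = FALSE)
  if (samples_per_span < 2) stop("samples_per_span must be >= 2", call. = FALSE)
  match.arg(spline_kind, "catmull-rom")
  ep <- lapply(lines, line_points)
  inner <- do.call(rbind, lapply(ep, `[[`, "inner"))
  outer <- do.call(rbind, lapply(ep, `[[`, "outer"))
  list(inner = catmull_rom_resample(inner, samples_per_span),
       outer = catmull_rom_resample(outer, samples_per_span))
}

#' Ruled strip between two aligned sample polylines
#'
#' Connects corresponding samples of two polylines with straight rungs and
#' triangulates each quad along a fixed diagonal, producing an open strip of
#' exactly `2 * (n - 1)` triangles whose boundary is the two polylines plus
#' the two end rungs.
#'
#' @param samplesA,samplesB numeric matrices (n x 3) with equal n >= 2.
#' @return an open `triangle_mesh` strip.
#' @export
ruled_strip <- function(samplesA, samplesB) {
  samplesA <- matrix(as.numeric(samplesA), ncol = 3)
  samplesB <- matrix(as.numeric(samplesB), ncol = 3)
  n <- nrow(samplesA)
  if (nrow(samplesB) != n) stop("mismatched sample counts", call. = FALSE)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  triangle_mesh(rbind(samplesA, samplesB), strip_faces(0L, n, n))
}

# faces of a ruled strip between vertex ranges offA+1..offA+n, offB+1..offB+n
strip_faces <- function(offA, offB, n) {
  i <- seq_len(n - 1)
  rbind(
    cbind(offA + i, offA + i + 1, offB + i + 1),
    cbind(offA + i, offB + i + 1, offB + i)
  )
}

#' Build the closed initial splint solid from a plan
#'
#' Resamples the up-line and down-line endpoint splines, then assembles six
#' boundary sheets into a single watertight outward-oriented solid: the top
#' sheet (up inner to up outer), bottom sheet (down inner to down outer),
#' inner and outer walls (up to down on each side), and two planar end caps.
#' All sheets share their boundary vertices, so there are no T-junctions.
#'
#' @param plan a [splint_plan()].
#' @return a watertight `triangle_mesh` with positive volume.
#' @export
build_initial_splint <- function(plan) {
  if (!inherits(plan, "splint_plan")) stop("not a splint_plan", call. = FALSE)
  check_arch_order(plan$up_lines)
  check_arch_order(plan$down_lines)
  up <- resample_line_series(plan$up_lines, plan$samples_per_span,
                             plan$spline_kind)
  dn <- resample_line_series(plan$down_lines, plan$samples_per_span,
                             plan$spline_kind)
  # sheets: top (up inner-outer), outer wall, bottom, inner wall, end caps
  m <- closed_tube(up$inner, up$outer, dn$outer, dn$inner)
  if (!is_watertight(m))
    stop("internal error: splint base is not watertight", call. = FALSE)
  eps <- 1e-7 * mesh_bbox(m)$diag
  if (cpp_self_intersects(m$vertices, m$faces, eps))
    stop(paste0("splint base self-intersects; adjust line positions, ",
                "lengths or directions"), call. = FALSE)
  m
}

# closed solid swept by the quad cross-section (A_i, B_i, C_i, D_i) along
# aligned sample paths: four ruled sheets sharing boundary vertices plus two
# planar end caps; outward orientation enforced by the volume sign
closed_tube <- function(A, B, C, D) {
  n <- nrow(A)
  V <- rbind(A, B, C, D)
  oA <- 0L; oB <- n; oC <- 2L * n; oD <- 3L * n
  F <- rbind(
    strip_faces(oA, oB, n),
    strip_faces(oB, oC, n),
    strip_faces(oC, oD, n),
    strip_faces(oD, oA, n),
    c(oA + 1, oB + 1, oC + 1), c(oA + 1, oC + 1, oD + 1),
    c(oA + n, oD + n, oC + n), c(oA + n, oC + n, oB + n)
  )
  m <- triangle_mesh(V, F)
  if (mesh_volume(m) < 0) m <- reverse_faces(m)
  m
}

# ordering along the arch: consecutive anchor chords must not backtrack
check_arch_order <- function(lines) {
  A <- do.call(rbind, lapply(lines, `[[`, "anchor"))
  if (nrow(A) < 3) return(invisible(TRUE))
  d <- A[-1, , drop = FALSE] - A[-nrow(A), , drop = FALSE]
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  if (any(dots <= 0))
    stop("lines are not ordered along the arch (backtracking anchors)",
         call. = FALSE)
  invisible(TRUE)
}
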