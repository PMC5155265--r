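circle_lines <- function(radius = 30, n = 8, span = pi, z = 0, half = 2) {
  ang <- seq(pi / 2 + span / 2, pi / 2 - span / 2, length.out = n)
  lapply(ang, function(a) {
    landmark_line(c(radius * cos(a), radius * sin(a), z),
                  c(cos(a), sin(a), 0), half, half)
  })
}

test_that("resampling interpolates knots exactly and respects linear cases", {
  l1 <- landmark_line(c(0, 0, 0), c(0, 0, 1), 1, 1)
  l2 <- landmark_line(c(10, 0, 0), c(0, 0, 1), 1, 1)
  rs <- resample_line_series(list(l1, l2), samples_per_span = 5)
  expect_equal(nrow(rs$inner), 6)
  # two lines: samples are affine combinations of the endpoints
  expect_equal(rs$inner[, 2], rep(0, 6))
  expect_equal(rs$inner[, 3], rep(-1, 6))
  expect_true(all(diff(rs$inner[, 1]) > 0))
  expect_equal(rs$inner[1, ], c(0, 0, -1))
  expect_equal(rs$inner[6, ], c(10, 0, -1))

  # collinear equally-spaced anchors stay collinear
  ls <- lapply(seq(0, 8, by = 2), function(x)
    landmark_line(c(x, 2 * x, 0), c(0, 0, 1), 1, 1))
  rs2 <- resample_line_series(ls, samples_per_span = 4)
  expect_lt(max(abs(rs2$outer[, 2] - 2 * rs2$outer[, 1])), 1e-9)

  # coincident consecutive anchors are a zero chord
  expect_error(
    resample_line_series(list(l1, l1), samples_per_span = 3), "zero chord")
})

test_that("spline resampling of circular arches stays on the circle", {
  lines <- circle_lines(radius = 30, n = 8)
  rs <- resample_line_series(lines, samples_per_span = 20)
  r_in <- sqrt(rowSums(rs$inner[, 1:2]^2))
  r_out <- sqrt(rowSums(rs$outer[, 1:2]^2))
  expect_lt(max(abs(r_in - 28)), 0.25)
  expect_lt(max(abs(r_out - 32)), 0.25)
  # the picked endpoints themselves are reproduced exactly
  idx <- seq(1, nrow(rs$inner), by = 20)
  ep <- t(vapply(lines, function(l) line_points(l)$inner, numeric(3)))
  expect_equal(rs$inner[idx, ], ep, tolerance = 1e-9)
})

test_that("ruled strips have exact counts, boundaries and areas", {
  n <- 11
  A <- cbind(seq(0, 5, length.out = n), 0, 0)
  B <- cbind(seq(0, 5, length.out = n), 2, 0)
  st <- ruled_strip(A, B)
  expect_equal(nrow(st$faces), 2 * (n - 1))
  expect_equal(mesh_area(st), 10, tolerance = 1e-9)
  expect_error(ruled_strip(A, B[-1, ]), "mismatch")
  st2 <- ruled_strip(A[1:2, ], B[1:2, ])
  expect_equal(nrow(st2$faces), 2)
})

test_that("skew ruled strip area matches the quadrature oracle", {
  a0 <- c(0, 0, 0); a1 <- c(1, 0, 0)
  b0 <- c(0, 1, 0); b1 <- c(1, 1, 1)
  n <- 201
  t <- seq(0, 1, length.out = n)
  A <- outer(1 - t, a0) + outer(t, a1)
  B <- outer(1 - t, b0) + outer(t, b1)
  st <- ruled_strip(A, B)
  # 200-point midpoint quadrature of the strip's area element: each quad
  # contributes du/2 (|A' x r| + |B' x r|) with rung r(u) = B(u) - A(u)
  u <- (seq_len(200) - 0.5) / 200
  ap <- a1 - a0; bp <- b1 - b0
  r <- outer(rep(1, 200), b0 - a0) + outer(u, bp - ap)
  cr1 <- cbind(ap[2] * r[, 3] - ap[3] * r[, 2],
               ap[3] * r[, 1] - ap[1] * r[, 3],
               ap[1] * r[, 2] - ap[2] * r[, 1])
  cr2 <- cbind(bp[2] * r[, 3] - bp[3] * r[, 2],
               bp[3] * r[, 1] - bp[1] * r[, 3],
               bp[1] * r[, 2] - bp[2] * r[, 1])
  area_strip <- mean(sqrt(rowSums(cr1^2)) + sqrt(rowSums(cr2^2))) / 2
  expect_equal(mesh_area(st), area_strip, tolerance = 1e-3)
  # and it is bounded below by the smooth bilinear patch area
  g <- expand.grid(u = u, v = u)
  Su <- outer(1 - g$v, ap) + outer(g$v, bp)
  Sv <- outer(rep(1, nrow(g)), b0 - a0) + outer(g$u, bp - ap)
  cr <- cbind(Su[, 2] * Sv[, 3] - Su[, 3] * Sv[, 2],
              Su[, 3] * Sv[, 1] - Su[, 1] * Sv[, 3],
              Su[, 1] * Sv[, 2] - Su[, 2] * Sv[, 1])
  expect_gte(mesh_area(st), mean(sqrt(rowSums(cr^2))) - 1e-6)
})

test_that("the degenerate parallel-line plan builds an analytic box", {
  mk_row <- function(y) lapply(seq(0, 12, by = 3), function(x)
    landmark_line(c(x, y, 0), c(0, 0, 1), 2, 1))
  plan <- splint_plan(mk_row(0), mk_row(4), samples_per_span = 10)
  box <- build_initial_splint(plan)
  expect_true(is_watertight(box))
  n <- (5 - 1) * 10 + 1
  expect_equal(nrow(box$faces), 4 * 2 * (n - 1) + 4)  # strip-count law
  expect_lt(abs(mesh_volume(box) - 12 * 4 * 3) / (12 * 4 * 3), 0.001)
})

test_that("arch plans build watertight solids with spherical topology", {
  up <- circle_lines(30, 8, z = 3)
  dn <- circle_lines(30, 8, z = -3)
  plan <- splint_plan(up, dn, samples_per_span = 10)
  m <- build_initial_splint(plan)
  expect_true(is_watertight(m))
  expect_gt(mesh_volume(m), 0)
  expect_equal(euler_characteristic(m), 2L)
  n <- (8 - 1) * 10 + 1
  expect_equal(nrow(m$faces), 8 * (n - 1) + 4)

  # sheet boundary vertices lie on the generating splines
  rs <- resample_line_series(up, 10)
  expect_lt(max(splintforge:::unsigned_distance(
    m, rbind(rs$inner, rs$outer))), 1e-9)

  # reversing both list orders gives a congruent solid
  plan_r <- splint_plan(rev(up), rev(dn), samples_per_span = 10)
  m_r <- build_initial_splint(plan_r)
  expect_equal(mesh_volume(m_r), mesh_volume(m), tolerance = 1e-9)
})

test_that("refining the sampling converges (Cauchy) on box and arch", {
  up <- circle_lines(30, 6, z = 3)
  dn <- circle_lines(30, 6, z = -3)
  vols <- vapply(c(5, 10, 20), function(s) {
    mesh_volume(build_initial_splint(splint_plan(up, dn, s)))
  }, numeric(1))
  expect_lt(abs(vols[3] - vols[2]), abs(vols[2] - vols[1]))
})

test_that("disordered or self-intersecting plans are rejected", {
  up <- circle_lines(30, 6, z = 3)
  dn <- circle_lines(30, 6, z = -3)
  bad <- splint_plan(up[c(1, 3, 2, 4, 5, 6)], dn, samples_per_span = 5)
  expect_error(build_initial_splint(bad), "ordered")
  # inner extents reaching past the arch centre fold the inner wall onto
  # itself
  fold <- splint_plan(circle_lines(10, 8, span = 1.8 * pi, z = 1, half = 14),
                      circle_lines(10, 8, span = 1.8 * pi, z = -1, half = 14),
                      samples_per_span = 8)
  expect_error(build_initial_splint(fold), "self-intersect")
})
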