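test_that("splitting is the identity for disjoint solids", {
  A <- make_box(c(0, 0, 0), c(1, 1, 1))
  B <- make_box(c(3, 3, 3), c(4, 4, 4))
  sp <- split_at_intersection(A, B)
  expect_identical(sp$A_split$faces, A$faces)
  expect_identical(sp$A_split$vertices, A$vertices)
  expect_identical(sp$B_split, B)
  expect_length(sp$seam, 0)
})

test_that("splitting conserves area and embeds the seam in both surfaces", {
  A <- make_box(c(0, 0, 0), c(1, 1, 1))
  B <- translate_mesh(make_box(c(0, 0, 0), c(1, 1, 1)),
                      c(0.5, 0.21, -0.37))  # generic overlap
  sp <- split_at_intersection(A, B)
  expect_equal(mesh_area(sp$A_split), mesh_area(A), tolerance = 1e-7)
  expect_equal(mesh_area(sp$B_split), mesh_area(B), tolerance = 1e-7)
  seam_pts <- do.call(rbind, sp$seam)
  expect_gt(nrow(seam_pts), 0)
  eps <- splintforge:::seam_eps(A, B)
  expect_lt(max(splintforge:::unsigned_distance(A, seam_pts)), eps)
  expect_lt(max(splintforge:::unsigned_distance(B, seam_pts)), eps)
})

test_that("a sphere pushed through a cube face leaves a circular seam", {
  A <- make_box(c(0, 0, 0), c(1, 1, 1))
  B <- make_icosphere(0.4, 3, center = c(0.9, 0.5, 0.5))
  sp <- split_at_intersection(A, B)
  loops <- Filter(function(l) isTRUE(attr(l, "closed")), sp$seam)
  expect_length(loops, 1)
  L <- loops[[1]]
  len <- sum(sqrt(rowSums((L[-1, , drop = FALSE] -
                             L[-nrow(L), , drop = FALSE])^2)))
  r <- sqrt(0.4^2 - 0.1^2)  # circle where the sphere pierces x = 1
  expect_lt(abs(len - 2 * pi * r) / (2 * pi * r), 0.01)
})

test_that("cell extraction follows the signed-distance predicate", {
  A <- make_box(c(0, 0, 0), c(1, 1, 1))
  far <- make_box(c(5, 5, 5), c(6, 6, 6))
  expect_equal(nrow(classify_cells(far, A, "nonnegative")$faces), 12)
  expect_equal(nrow(classify_cells(far, A, "nonpositive")$faces), 0)
  inner <- make_box(c(0.3, 0.3, 0.3), c(0.6, 0.6, 0.6))
  expect_equal(nrow(classify_cells(inner, A, "nonnegative")$faces), 0)
  expect_equal(nrow(classify_cells(inner, A, "nonpositive")$faces), 12)

  # kept area of the split mesh equals the sampled outside-area fraction
  B <- translate_mesh(make_box(c(0, 0, 0), c(1, 1, 1)),
                      c(0.5, 0.21, -0.37))
  sp <- split_at_intersection(A, B)
  kept <- classify_cells(sp$A_split, B, "nonnegative")
  pts <- sample_surface_r(A, 4e4, seed = 5)
  frac_out <- mean(!parity_inside(B, pts))
  expect_equal(mesh_area(kept), mesh_area(A) * frac_out, tolerance = 0.02)
})

test_that("boolean identities hold on analytic box arithmetic", {
  A <- make_box(c(0, 0, 0), c(1, 1, 1))
  B <- make_box(c(0.5, 0, 0), c(1.5, 1, 1))
  C <- make_box(c(3, 3, 3), c(4, 4, 4))

  expect_lt(abs(mesh_volume(mesh_boolean(A, A, "difference"))), 1e-6)
  expect_equal(mesh_volume(mesh_boolean(A, C, "difference")), 1)
  expect_equal(mesh_volume(mesh_boolean(A, C, "union")), 2)

  d <- mesh_boolean(A, B, "difference")
  i <- mesh_boolean(A, B, "intersection")
  u <- mesh_boolean(A, B, "union")
  expect_equal(mesh_volume(d), 0.5, tolerance = 1e-6)
  expect_equal(mesh_volume(i), 0.5, tolerance = 1e-6)
  expect_equal(mesh_volume(u), 1.5, tolerance = 1e-6)
  for (m in list(d, i, u)) {
    expect_true(is_watertight(m))
    expect_gte(mesh_volume(m), 0)
  }
  # conservation and De Morgan volume identities
  expect_equal(mesh_volume(d) + mesh_volume(i), mesh_volume(A),
               tolerance = 1e-6)
  expect_equal(mesh_volume(u),
               mesh_volume(A) + mesh_volume(B) - mesh_volume(i),
               tolerance = 1e-6)
  # idempotence
  expect_equal(mesh_volume(mesh_boolean(A, A, "union")), 1, tolerance = 1e-6)
})

test_that("boolean volumes track the column-integral oracle on random pairs", {
  for (seed in 1:5) {
    A <- random_phantom(1000 + seed)
    B <- random_phantom(2000 + seed)
    # recentre B near A's centroid so the pair genuinely overlaps
    shift <- colMeans(A$vertices) - colMeans(B$vertices) +
      c(0.3, -0.2, 0.25)
    B <- translate_mesh(B, shift)
    vref <- boolean_oracle_adaptive(A, B)
    for (op in c("difference", "union", "intersection")) {
      res <- mesh_boolean(A, B, op)
      expect_true(is_watertight(res))
      scale <- max(vref[[op]], mesh_volume(A) * 0.05)
      expect_lt(abs(mesh_volume(res) - vref[[op]]) / scale, 0.01)
    }
  }
})

test_that("empty operands give the documented degenerate results", {
  A <- make_box(c(0, 0, 0), c(1, 1, 1))
  e <- empty_mesh()
  expect_equal(mesh_volume(mesh_boolean(e, A, "difference")), 0)
  expect_equal(mesh_volume(mesh_boolean(A, e, "difference")), 1)
  expect_equal(mesh_volume(mesh_boolean(A, e, "union")), 1)
  expect_equal(nrow(mesh_boolean(A, e, "intersection")$faces), 0)
  open <- triangle_mesh(A$vertices, A$faces[-1, ])
  expect_error(mesh_boolean(A, open, "difference"), "watertight")
})
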