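test_that("signed distance matches symmetry and on-surface cases", {
  ic <- make_icosphere(1, 3)
  ctr <- signed_distance(ic, rbind(c(0, 0, 0)))$values
  # centre of a faceted unit sphere: inside, at one chord-sagitta error
  expect_lt(abs(ctr + 1), 0.01)
  expect_lt(ctr, 0)
  # a mesh vertex as query point is on the surface
  v <- signed_distance(ic, ic$vertices[c(1, 5, 17), , drop = FALSE])$values
  expect_lt(max(abs(v)), 1e-9)
})

test_that("signed distance magnitude and sign agree with brute force", {
  ic <- make_icosphere(1, 1)
  set.seed(7)
  P <- matrix(runif(600, -1.5, 1.5), ncol = 3)
  sd <- signed_distance(ic, P)$values
  expect_equal(abs(sd), brute_distance(ic, P), tolerance = 1e-9)
  expect_equal(sd < 0, unname(parity_inside(ic, P)))
})

test_that("signed distance refuses open meshes", {
  cube <- make_box(c(0, 0, 0), c(1, 1, 1))
  open <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(signed_distance(open, rbind(c(0, 0, 0))), "watertight")
})

test_that("mean surface distance: identity, analytic shells, determinism", {
  s1 <- make_icosphere(10, 3)
  expect_lt(mean_surface_distance(s1, s1, 2000, seed = 4), 1e-9)
  s2 <- make_icosphere(10.5, 3)
  d <- mean_surface_distance(s1, s2, 20000, seed = 0)
  expect_lt(abs(d - 0.5), 0.01)  # faceting tolerance
  expect_identical(mean_surface_distance(s1, s2, 5000, seed = 3),
                   mean_surface_distance(s1, s2, 5000, seed = 3))
  expect_error(mean_surface_distance(empty_mesh(), s1), "non-empty")
})

test_that("mean surface distance converges within Monte-Carlo error", {
  set.seed(11)
  A <- random_phantom(101)
  B <- random_phantom(202)
  d_small <- mean_surface_distance(A, B, 1e4, seed = 1)
  # large-sample reference with an independent sampler
  pa <- sample_surface_r(A, 2e5, seed = 21)
  pb <- sample_surface_r(B, 2e5, seed = 22)
  da <- brute_distance_fast(B, pa)
  db <- brute_distance_fast(A, pb)
  ref <- (mean(da) + mean(db)) / 2
  se <- sqrt(stats::var(da) / length(da) + stats::var(db) / length(db)) / 2 +
    sqrt((stats::var(da) + stats::var(db)) / 2 / 1e4)
  expect_lt(abs(d_small - ref), 3 * se)
})
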