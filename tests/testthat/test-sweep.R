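slice_total_area <- function(slice) {
  if (length(slice$loops) == 0) return(0)
  sum(vapply(slice$loops, function(L) splintforge:::loop_area(L), numeric(1)))
}

test_that("contour slices reproduce analytic cross-sections", {
  fr <- make_cone_frustum(8, 12, 20, 128)
  st <- slice_contours(fr, c(0, 0, 1), 1)
  for (s in st$slices) {
    expect_length(s$loops, 1)
    r_expect <- 8 + (12 - 8) * s$offset / 20
    r_mean <- mean(sqrt(rowSums(
      sweep(s$loops[[1]], 2, c(0, 0), `-`)^2)))
    expect_lt(abs(r_mean - r_expect), 0.02)  # chord sagitta at 128 segments
  }
  # ordering: first slice is the far end along the direction
  offs <- vapply(st$slices, `[[`, numeric(1), "offset")
  expect_true(all(diff(offs) < 0))

  cube <- make_box(c(0, 0, 0), c(7, 7, 5))
  stc <- slice_contours(cube, c(0, 0, 1), 0.8)
  areas <- vapply(stc$slices, slice_total_area, numeric(1))
  expect_equal(areas, rep(49, length(areas)), tolerance = 1e-9)

  open <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(slice_contours(open, c(0, 0, 1), 1), "watertight")
})

test_that("sweep accumulation is a cumulative union from the far end", {
  # big-end-up frustum: every accumulated slice equals the first disc
  fr <- make_cone_frustum(8, 12, 20, 64)
  acc <- accumulate_sweep(slice_contours(fr, c(0, 0, 1), 1))
  vol <- rasterize_stack(acc, 0.5)
  occ <- apply(vol$values, 3, sum)
  core <- occ[occ > 0]
  expect_lt(diff(range(core)) / max(core), 0.02)
  r_first <- 8 + (12 - 8) * acc$slices[[1]]$offset / 20
  expect_equal(max(core) * 0.5^2, pi * r_first^2, tolerance = 0.03)

  # a monotone stack (cylinder) is a fixpoint up to occupancy
  cyl <- make_cone_frustum(6, 6, 10, 64)
  st <- slice_contours(cyl, c(0, 0, 1), 1)
  acc2 <- accumulate_sweep(st)
  v1 <- rasterize_stack(st, 0.5)
  v2 <- rasterize_stack(acc2, 0.5)
  expect_identical(v1$values, v2$values)
})

test_that("accumulation matches the brute-force cumulative OR on random stacks", {
  set.seed(33)
  # random axis-aligned squares, one per slice, as a synthetic contour stack
  n <- 20
  slices <- lapply(seq_len(n), function(i) {
    k <- sample(3, 1)
    loops <- lapply(seq_len(k), function(j) {
      c0 <- runif(2, -6, 4)
      sz <- runif(2, 1, 4)
      rbind(c0, c0 + c(sz[1], 0), c0 + sz, c0 + c(0, sz[2]))
    })
    list(offset = n - i, loops = loops)
  })
  stack <- structure(list(direction = c(0, 0, 1), spacing = 1,
                          slices = slices, frame = diag(3)),
                     class = "contour_stack")
  acc <- accumulate_sweep(stack)
  v_in <- rasterize_stack(stack, 0.5)
  v_acc <- rasterize_stack(acc, 0.5)
  # brute-force cumulative OR along z, marching from the far (max offset) end
  ref <- v_in$values
  for (k in seq(dim(ref)[3] - 1, 1)) {
    ref[, , k] <- pmax(ref[, , k], ref[, , k + 1])
  }
  # padding layers are outside every slice; compare the slab region
  expect_identical(v_acc$values[, , -c(1, dim(ref)[3])],
                   ref[, , -c(1, dim(ref)[3])])
})

test_that("rasterization counts voxels inclusively and matches disc areas", {
  sq <- list(offset = 0,
             loops = list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))))
  stack <- structure(list(direction = c(0, 0, 1), spacing = 1,
                          slices = list(sq), frame = diag(3)),
                     class = "contour_stack")
  vol <- rasterize_stack(stack, 0.5)
  expect_equal(sum(vol$values), 21 * 21)

  empty <- structure(list(direction = c(0, 0, 1), spacing = 1,
                          slices = list(list(offset = 0, loops = list())),
                          frame = diag(3)),
                     class = "contour_stack")
  expect_equal(sum(rasterize_stack(empty, 0.5)$values), 0)

  r <- 5
  th <- seq(0, 2 * pi, length.out = 257)[-1]
  disc <- list(offset = 0, loops = list(cbind(r * cos(th), r * sin(th))))
  dstack <- structure(list(direction = c(0, 0, 1), spacing = 1,
                           slices = list(disc), frame = diag(3)),
                      class = "contour_stack")
  dvol <- rasterize_stack(dstack, r / 20)
  expect_lt(abs(sum(dvol$values) * (r / 20)^2 - pi * r^2) / (pi * r^2), 0.03)
})

test_that("morphological closing preserves solids and fills interior holes", {
  z <- array(0, c(5, 5, 5))
  expect_equal(sum(close_volume(binary_volume(c(0, 0, 0), 1, z), 2)$values), 0)

  solid <- array(0, c(9, 9, 9))
  solid[3:7, 3:7, 3:7] <- 1
  bv <- binary_volume(c(0, 0, 0), 1, solid)
  expect_identical(close_volume(bv, 1)$values, solid)

  holed <- solid
  holed[5, 5, 5] <- 0
  closed <- close_volume(binary_volume(c(0, 0, 0), 1, holed), 1)
  expect_identical(closed$values, solid)
})

test_that("isosurface extraction is watertight and accurate", {
  z <- array(0, c(4, 4, 4))
  expect_equal(nrow(marching_cubes(binary_volume(c(0, 0, 0), 1, z))$faces), 0)

  one <- array(0, c(3, 3, 3)); one[2, 2, 2] <- 1
  m1 <- marching_cubes(binary_volume(c(0, 0, 0), 0.25, one))
  expect_true(is_watertight(m1))
  expect_gt(mesh_volume(m1), 0)
  expect_lte(mesh_volume(m1), 8 * 0.25^3)

  bad <- array(1, c(3, 3, 3))
  expect_error(marching_cubes(binary_volume(c(0, 0, 0), 1, bad)), "unpadded")

  sp <- make_icosphere(10, 4)
  vol <- rasterize_stack(slice_contours(sp, c(0, 0, 1), 0.25), 0.25)
  mc <- marching_cubes(vol)
  expect_true(is_watertight(mc))
  expect_lte(mean_surface_distance(mc, sp, 10000, seed = 2), 0.25)
})

test_that("swept models reproduce analytic silhouettes", {
  # a sphere sweeps to a hemisphere-capped cylinder (capsule silhouette)
  r <- 8
  sp <- make_icosphere(r, 4)
  sw <- sweep_model(sp, c(0, 0, 1), 0.4, 0.25, 1, extension = 0)
  expect_true(is_watertight(sw))
  v_analytic <- 2 / 3 * pi * r^3 + pi * r^2 * r
  expect_lt(abs(mesh_volume(sw) - v_analytic) / v_analytic, 0.03)

  # a cylinder swept along its own axis is unchanged
  cyl <- make_cone_frustum(6, 6, 12, 64)
  swc <- sweep_model(cyl, c(0, 0, 1), 0.4, 0.25, 1, extension = 0)
  expect_lt(mean_surface_distance(swc, cyl, 5000, seed = 1), 0.25)
})

test_that("sweep growth, column monotonicity and idempotence hold", {
  fr <- make_cone_frustum(5, 8, 12, 48)
  d <- c(0, 0, 1)
  sw <- sweep_model(fr, d, 0.5, 0.3, 1, extension = 0)
  expect_gte(mesh_volume(sw), mesh_volume(fr) - 0.3 * mesh_area(fr))

  # monotone columns on the rasterized accumulated stack
  acc <- accumulate_sweep(slice_contours(fr, d, 0.5))
  vol <- rasterize_stack(acc, 0.3)
  v <- vol$values
  # once occupied marching opposite to d (decreasing z), a column stays
  # occupied: inside the slab (pads excluded), every column is 0...0 1...1
  ok <- TRUE
  nz <- dim(v)[3]
  for (i in seq_len(dim(v)[1])) for (j in seq_len(dim(v)[2])) {
    if (any(diff(rev(v[i, j, 2:(nz - 1)])) < 0)) ok <- FALSE
  }
  expect_true(ok)

  sw2 <- sweep_model(sw, d, 0.5, 0.3, 1, extension = 0)
  expect_lt(mean_surface_distance(sw2, sw, 5000, seed = 9), 0.3)

  # halving the voxel size improves agreement with the pipeline's limiting
  # object: the cylinder at the first-contour radius over the sliced span
  offs <- vapply(acc$slices, `[[`, numeric(1), "offset")
  r_first <- 5 + 3 * max(offs) / 12
  std <- translate_mesh(
    make_standard_swept(r_first, max(offs) - min(offs), 128),
    c(0, 0, min(offs)))
  e_coarse <- mean_surface_distance(
    sweep_model(fr, d, 0.5, 0.5, 1, extension = 0), std, 5000, seed = 3)
  e_fine <- mean_surface_distance(
    sweep_model(fr, d, 0.5, 0.25, 1, extension = 0), std, 5000, seed = 3)
  expect_lt(e_fine, e_coarse)
})

test_that("interference elimination handles trivial and peg dentitions", {
  expect_equal(nrow(eliminate_interference(
    empty_mesh(), make_cone_frustum(2, 3, 5), c(0, 0, 1))$faces), 0)

  # cylindrical pegs carry no undercut: eliminating interference reduces to
  # the plain Boolean difference up to voxel resolution
  splint <- make_box(c(-10, -10, 0), c(10, 10, 8))
  pegs <- splintforge:::concat_meshes(
    translate_mesh(make_cone_frustum(3, 3, 14, 32), c(-4, 0, -3)),
    translate_mesh(make_cone_frustum(2.5, 2.5, 14, 32), c(5, 2, -3))
  )
  plain <- mesh_boolean(splint, pegs, "difference")
  elim <- eliminate_interference(splint, pegs, c(0, 0, 1),
                                 voxel_spacing = 0.3, clearance_voxels = 1)
  expect_true(is_watertight(elim))
  # clearance removes at most ~1 voxel of skin around the pegs
  vol_clearance <- 2 * pi * (3 + 2.5) * 8 * 0.6
  expect_lt(abs(mesh_volume(elim) - mesh_volume(plain)), vol_clearance)
})

test_that("oversized voxel volumes trip the memory guard", {
  big <- make_box(c(0, 0, 0), c(60, 60, 60))
  expect_error(sweep_model(big, c(0, 0, 1), 1, 0.05), "memory guard")
})
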