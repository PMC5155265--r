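test_that("frusta and cylinders match their analytic volumes", {
  cyl <- make_cone_frustum(5, 5, 10, 256)
  expect_lt(abs(mesh_volume(cyl) - pi * 25 * 10) / (pi * 250), 0.001)
  fr <- make_cone_frustum(8, 12, 20, 256)
  va <- pi * 20 * (64 + 96 + 144) / 3
  expect_lt(abs(mesh_volume(fr) - va) / va, 0.001)
  for (m in list(cyl, fr, make_cone_frustum(0, 4, 6, 32),
                 make_cone_frustum(4, 0, 6, 32)))
    expect_true(is_watertight(m))
  expect_error(make_cone_frustum(0, 0, 5), "not both zero")
  expect_error(make_cone_frustum(1, 2, -1), "height")
})

test_that("the standard swept model is the first-contour cylinder", {
  std <- make_standard_swept(12, 20, 256)
  expect_lt(abs(mesh_volume(std) - pi * 144 * 20) / (pi * 144 * 20), 0.001)
  # same shape as the constant-radius frustum
  expect_lt(mean_surface_distance(
    std, make_cone_frustum(12, 12, 20, 256), 5000, seed = 1), 1e-6)
  # constant radius at every slicing level, up to the 256-gon chord sagitta
  st <- slice_contours(std, c(0, 0, 1), 2.5)
  sagitta <- 12 * (1 - cos(pi / 256))
  for (s in st$slices) {
    r <- sqrt(rowSums(s$loops[[1]]^2))
    expect_lt(max(abs(r - 12)), sagitta + 1e-9)
  }
  # extension grows the cylinder below the base
  ext <- make_standard_swept(12, 20, 64, extension = 5)
  expect_equal(min(ext$vertices[, 3]), -5)
})

test_that("the arch phantom is deterministic, watertight and undercut", {
  spec <- small_arch_spec()
  ph1 <- make_arch_phantom(spec)
  ph2 <- make_arch_phantom(spec)
  expect_identical(ph1$maxilla$vertices, ph2$maxilla$vertices)
  expect_identical(ph1$mandible$faces, ph2$mandible$faces)
  expect_true(is_watertight(ph1$maxilla))
  expect_true(is_watertight(ph1$mandible))

  # slicing from the crown toward the base: strictly decreasing tooth area
  gap2 <- spec$jaw_gap / 2
  ridge_top <- -(gap2 + spec$tooth_height - 0.5)
  st <- slice_contours(ph1$mandible, c(0, 0, 1), 0.8)
  band <- Filter(function(s) {
    s$offset < -gap2 - 0.1 && s$offset > ridge_top + 0.1
  }, st$slices)
  expect_gte(length(band), 3)
  areas <- vapply(band, function(s)
    sum(abs(vapply(s$loops, splintforge:::loop_area, numeric(1)))),
    numeric(1))
  # slices come ordered from the crown end downward
  expect_true(all(diff(areas) < 0))

  expect_error(
    make_arch_phantom(arch_phantom_spec(n_teeth = 12, arch_radius = 12)),
    "overlapping teeth")
  expect_error(arch_phantom_spec(tooth_base_radius = 3,
                                 tooth_crown_radius = 2), "crown")
})

test_that("auto-generated plans enclose every crown tip", {
  spec <- small_arch_spec()
  plan <- make_plan_for_arch(spec)
  expect_length(plan$up_lines, spec$n_teeth)
  expect_length(plan$down_lines, spec$n_teeth)
  base <- build_initial_splint(plan)
  expect_true(is_watertight(base))
  tips <- rbind(splintforge:::crown_tips(spec, TRUE),
                splintforge:::crown_tips(spec, FALSE))
  expect_lt(max(signed_distance(base, tips)$values), 0)
})

test_that("the full phantom pipeline runs end to end", {
  spec <- small_arch_spec()
  ph <- make_arch_phantom(spec)
  base <- build_initial_splint(make_plan_for_arch(spec))
  s1 <- mesh_boolean(base, ph$maxilla, "difference")
  splint <- mesh_boolean(s1, ph$mandible, "difference")
  expect_true(is_watertight(s1))
  expect_true(is_watertight(splint))
  expect_lt(mesh_volume(splint), mesh_volume(base))
  expect_gt(mesh_volume(splint), 0)
})
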