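test_that("binary STL roundtrip preserves canonical solids", {
  cube <- make_box(c(0, 0, 0), c(1, 1, 1))
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, p)
  m <- read_stl(p)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_equal(mesh_volume(m), 1)
})

test_that("ASCII STL of a single triangle reads back", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid tri",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid tri"
  ), p)
  m <- read_stl(p)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_equal(mesh_area(m), 0.5)
})

test_that("roundtrip of a large phantom stays within float32 precision", {
  sp <- make_icosphere(13.7, 5)  # > 10,000 faces
  expect_gt(nrow(sp$faces), 10000)
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(sp, p)
  m <- read_stl(p)
  expect_equal(nrow(m$faces), nrow(sp$faces))
  # match vertices by nearest coordinates after the welding permutation
  d <- splintforge:::unsigned_distance(sp, m$vertices)
  expect_lte(max(d), 1e-5)
})

test_that("write-read-write produces byte-identical binary STL", {
  fr <- make_cone_frustum(8, 12, 20, 64)
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(fr, p1)
  write_stl(read_stl(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("ASCII dialect roundtrips through the reader", {
  fr <- make_cone_frustum(3, 5, 7, 16)
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(fr, p, dialect = "ascii")
  m <- read_stl(p)
  expect_equal(nrow(m$faces), nrow(fr$faces))
  expect_equal(mesh_volume(m), mesh_volume(fr), tolerance = 1e-6)
})

test_that("malformed input and empty output are rejected with clear errors", {
  expect_error(write_stl(empty_mesh(), tempfile()), "empty")
  p <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(rep(0, 100)), p)  # binary header claiming records it lacks
  expect_error(read_stl(p), "byte 80")
  p2 <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(1:10), p2)
  expect_error(read_stl(p2), "byte 0")
  expect_error(read_stl(file.path(tempdir(), "nope.stl")), "not found")
})
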