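arch_fixture <- function(dir) {
  spec <- small_arch_spec()
  ph <- make_arch_phantom(spec)
  write_stl(ph$maxilla, file.path(dir, "maxilla.stl"))
  write_stl(ph$mandible, file.path(dir, "mandible.stl"))
  write_splint_plan(make_plan_for_arch(spec), file.path(dir, "plan.json"))
  spec
}

test_that("the design pipeline runs end to end and reports consistently", {
  td <- withr::local_tempdir()
  arch_fixture(td)
  cfg <- run_config(
    maxilla = file.path(td, "maxilla.stl"),
    mandible = file.path(td, "mandible.stl"),
    plan = file.path(td, "plan.json"),
    output = file.path(td, "splint.stl"),
    report = file.path(td, "report.json")
  )
  rep <- design_splint(cfg)
  expect_true(file.exists(cfg$output))
  expect_true(rep$final_splint$watertight)
  expect_gt(rep$final_splint$volume_mm3, 0)
  expect_true(all(c("read_plan", "initial_splint", "boolean_difference",
                    "write_stl") %in% names(rep$stages)))

  # Table-1-style accounting: counts must match the written file
  m <- read_stl(cfg$output)
  expect_equal(nrow(m$faces), rep$final_splint$cells)
  expect_equal(nrow(m$vertices), rep$final_splint$points)
  jr <- jsonlite::read_json(file.path(td, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(jr$final_splint$cells, rep$final_splint$cells)
})

test_that("design output is byte-identical across runs", {
  td <- withr::local_tempdir()
  arch_fixture(td)
  mk <- function(out) {
    design_splint(run_config(
      maxilla = file.path(td, "maxilla.stl"),
      mandible = file.path(td, "mandible.stl"),
      plan = file.path(td, "plan.json"),
      output = out
    ))
    readBin(out, "raw", file.size(out))
  }
  expect_identical(mk(file.path(td, "a.stl")), mk(file.path(td, "b.stl")))
})

test_that("stage failures name the failing stage", {
  td <- withr::local_tempdir()
  arch_fixture(td)
  cfg <- run_config(
    maxilla = file.path(td, "maxilla.stl"),
    mandible = file.path(td, "mandible.stl"),
    plan = file.path(td, "nonexistent.json"),
    output = file.path(td, "x.stl")
  )
  expect_error(design_splint(cfg), "plan")
  expect_error(run_config(maxilla = "a", mandible = "b", plan = "c",
                          output = "d", slice_spacing = -1), "positive")
  expect_error(run_config(maxilla = "a", mandible = "b", plan = "c",
                          output = "d", removal_direction = c(0, 0, 0)),
               "non-zero")
})

test_that("the command-line interface drives the same pipeline", {
  cli <- system.file("cli", "splintforge.R", package = "splintforge")
  expect_true(nzchar(cli))
  td <- withr::local_tempdir()
  arch_fixture(td)

  run <- function(...) {
    suppressWarnings(system2("Rscript", c(cli, ...), stdout = TRUE,
                             stderr = TRUE))
  }
  out <- run("design", "--maxilla", file.path(td, "maxilla.stl"),
             "--mandible", file.path(td, "mandible.stl"),
             "--plan", file.path(td, "plan.json"),
             "-o", file.path(td, "cli.stl"))
  expect_null(attr(out, "status"))
  expect_true(is_watertight(read_stl(file.path(td, "cli.stl"))))

  # cone phantom + measure subcommands
  run("phantom", "cone", "--r-bottom", "8", "--r-top", "12",
      "--height", "20", "-o", file.path(td, "cone.stl"))
  cone <- read_stl(file.path(td, "cone.stl"))
  va <- pi * 20 * (64 + 96 + 144) / 3
  expect_lt(abs(mesh_volume(cone) - va) / va, 0.01)
  msd <- run("measure", file.path(td, "cone.stl"), file.path(td, "cone.stl"))
  expect_equal(as.numeric(msd[length(msd)]), 0, tolerance = 1e-6)

  # a missing plan exits non-zero and names the plan
  bad <- run("design", "--maxilla", file.path(td, "maxilla.stl"),
             "--mandible", file.path(td, "mandible.stl"),
             "--plan", file.path(td, "missing.json"),
             "-o", file.path(td, "y.stl"))
  expect_equal(attr(bad, "status"), 1)
  expect_true(any(grepl("plan", bad)))
})
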