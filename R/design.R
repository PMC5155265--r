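# End-to-end splint design: base construction, Boolean subtraction of the
# jaws, optional undercut elimination, STL export and a machine-readable run
# report.

#' Run configuration for the end-to-end design pipeline
#'
#' @param maxilla,mandible paths to the jaw STL files.
#' @param plan path to a `splintplan/1` JSON file.
#' @param output path for the final splint STL.
#' @param deundercut apply the interference-elimination pass (default FALSE).
#' @param removal_direction draw direction for the undercut pass.
#' @param slice_spacing,voxel_spacing,closing_iterations,extension,
#'   clearance_voxels sweep parameters, see [sweep_model()] and
#'   [eliminate_interference()].
#' @param report optional path for the JSON run report.
#' @return a `run_config`.
#' @export
run_config <- function(maxilla, mandible, plan, output,
                       deundercut = FALSE, removal_direction = c(0, 0, 1),
                       slice_spacing = 0.5, voxel_spacing = 0.25,
                       closing_iterations = 1, extension = NULL,
                       clearance_voxels = 1, report = NULL) {
  nums <- c(slice_spacing, voxel_spacing)
  if (any(nums <= 0) || closing_iterations < 0 || clearance_voxels < 0)
    stop("sweep parameters must be positive", call. = FALSE)
  unit3(removal_direction)  # validates non-zero
  structure(
    list(maxilla = maxilla, mandible = mandible, plan = plan,
         output = output, deundercut = isTRUE(deundercut),
         removal_direction = as.numeric(removal_direction),
         slice_spacing = slice_spacing, voxel_spacing = voxel_spacing,
         closing_iterations = closing_iterations, extension = extension,
         clearance_voxels = clearance_voxels, report = report),
    class = "run_config"
  )
}

#' Design a dental splint end to end
#'
#' Chains the full pipeline: read the jaw meshes and the landmark plan,
#' build the initial splint base from ruled surfaces, subtract the
#' maxilla-mandibular model with the mesh Boolean, optionally remove
#' undercuts along the removal direction, and write the printable STL. The
#' run report records per-stage timings, cell/point counts of every mesh
#' and all parameters; identical inputs give byte-identical output files.
#'
#' @param config a [run_config()] (or a list coerced through it).
#' @return the run report (list), invisibly.
#' @export
design_splint <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  report <- list(parameters = config[setdiff(names(config), "report")],
                 stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    value
  }
  counts <- function(mesh) list(cells = nrow(mesh$faces),
                                points = nrow(mesh$vertices))

  if (!file.exists(config$plan))
    stop("stage 'read_plan' failed: plan file not found: ", config$plan,
         call. = FALSE)
  plan <- stage("read_plan", read_splint_plan(config$plan))
  maxilla <- stage("read_maxilla", read_stl(config$maxilla))
  mandible <- stage("read_mandible", read_stl(config$mandible))
  jaws <- concat_meshes(maxilla, mandible)
  report$input <- list(maxilla = counts(maxilla), mandible = counts(mandible),
                       maxilla_mandibular = counts(jaws))

  base <- stage("initial_splint", build_initial_splint(plan))
  report$initial_splint <- counts(base)

  splint <- stage("boolean_difference", {
    s <- mesh_boolean(base, maxilla, "difference")
    mesh_boolean(s, mandible, "difference")
  })

  if (config$deundercut) {
    splint <- stage("interference_elimination", eliminate_interference(
      splint, jaws, config$removal_direction,
      slice_spacing = config$slice_spacing,
      voxel_spacing = config$voxel_spacing,
      closing_iterations = config$closing_iterations,
      extension = config$extension,
      clearance_voxels = config$clearance_voxels
    ))
  }
  report$final_splint <- c(counts(splint),
                           list(volume_mm3 = mesh_volume(splint),
                                watertight = is_watertight(splint)))
  stage("write_stl", write_stl(splint, config$output))
  report$total_seconds <- proc.time()[["elapsed"]] - t_all
  if (!is.null(config$report))
    jsonlite::write_json(report, config$report, auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(report)
}
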