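#' Landmark lines and splint plans
#'
#' A `landmark_line` models one surgeon-picked point on the dentition: an
#' anchor point, a unit direction (the line's axis), and the two extents the
#' line reaches from the anchor along that axis. The derived endpoints are
#' `inner_point = anchor - inner_length * direction` and
#' `outside_point = anchor + outside_length * direction`.
#'
#' @param anchor numeric length-3 picked point, mm.
#' @param direction numeric length-3 axis; re-normalized to unit length.
#' @param inner_length,outside_length non-negative extents, mm (their sum
#'   must be positive).
#' @return an object of class `landmark_line`.
#' @export
landmark_line <- function(anchor, direction, inner_length, outside_length) {
  anchor <- as.numeric(anchor)
  if (length(anchor) != 3 || anyNA(anchor)) stop("bad anchor", call. = FALSE)
  direction <- unit3(direction)
  if (inner_length < 0 || outside_length < 0)
    stop("lengths must be non-negative", call. = FALSE)
  if (inner_length + outside_length <= 0)
    stop("degenerate line: inner_length + outside_length must be > 0",
         call. = FALSE)
  structure(
    list(anchor = anchor, direction = direction,
         inner_length = as.numeric(inner_length),
         outside_length = as.numeric(outside_length)),
    class = "landmark_line"
  )
}

#' @export
print.landmark_line <- function(x, ...) {
  cat(sprintf("landmark_line: anchor (%.3g, %.3g, %.3g), lengths %.3g/%.3g\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$inner_length, x$outside_length))
  invisible(x)
}

#' @rdname landmark_line
#' @param line a `landmark_line`.
#' @return `line_points()`: list with `inner` and `outer` endpoint
#'   coordinates.
#' @export
line_points <- function(line) {
  list(inner = line$anchor - line$inner_length * line$direction,
       outer = line$anchor + line$outside_length * line$direction)
}

#' Adjust a landmark line
#'
#' Returns a new line with the given fields replaced (position, length and
#' axis of a line are adjustable to shape the splint); the direction is
#' re-normalized and all invariants re-checked.
#'
#' @param line a [landmark_line()].
#' @param new_anchor,new_direction,new_inner_length,new_outside_length
#'   optional replacement fields.
#' @return a new `landmark_line`.
#' @export
adjust_line <- function(line, new_anchor = NULL, new_direction = NULL,
                        new_inner_length = NULL, new_outside_length = NULL) {
  landmark_line(
    anchor = new_anchor %||% line$anchor,
    direction = new_direction %||% line$direction,
    inner_length = new_inner_length %||% line$inner_length,
    outside_length = new_outside_length %||% line$outside_length
  )
}

#' @rdname landmark_line
#' @param up_lines,down_lines ordered lists of `landmark_line`s for the
#'   maxilla and mandible side (equal length, at least 2); ordering follows
#'   the dental arch.
#' @param samples_per_span spline samples per consecutive-line span
#'   (default 10).
#' @param spline_kind interpolating spline family; currently
#'   `"catmull-rom"` (chord-length parameterized).
#' @return `splint_plan()`: an object of class `splint_plan`.
#' @export
splint_plan <- function(up_lines, down_lines, samples_per_span = 10,
                        spline_kind = "catmull-rom") {
  check_lines <- function(ls, nm) {
    if (!is.list(ls) || length(ls) < 2 ||
          !all(vapply(ls, inherits, logical(1), "landmark_line")))
      stop(nm, " must be a list of >= 2 landmark_lines", call. = FALSE)
  }
  check_lines(up_lines, "up_lines")
  check_lines(down_lines, "down_lines")
  if (length(up_lines) != length(down_lines))
    stop("up_lines and down_lines must pair up (equal length)", call. = FALSE)
  if (samples_per_span < 2)
    stop("samples_per_span must be >= 2", call. = FALSE)
  spline_kind <- match.arg(spline_kind, "catmull-rom")
  structure(
    list(up_lines = up_lines, down_lines = down_lines,
         samples_per_span = as.integer(samples_per_span),
         spline_kind = spline_kind),
    class = "splint_plan"
  )
}

#' @export
print.splint_plan <- function(x, ...) {
  cat(sprintf("splint_plan: %d up / %d down lines, %d samples per span (%s)\n",
              length(x$up_lines), length(x$down_lines), x$samples_per_span,
              x$spline_kind))
  invisible(x)
}

#' Read / write a splint plan file
#'
#' Plans are stored as JSON (`"schema": "splintplan/1"`) with `up_lines` and
#' `down_lines` arrays of `{anchor, direction, inner_length, outside_length}`
#' entries.
#'
#' @param path file path.
#' @return a `splint_plan`.
#' @export
read_splint_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$schema) || j$schema != "splintplan/1")
    stop("plan file is not splintplan/1: ", path, call. = FALSE)
  as_line <- function(e) {
    landmark_line(unlist(e$anchor), unlist(e$direction),
                  e$inner_length, e$outside_length)
  }
  splint_plan(
    up_lines = lapply(j$up_lines, as_line),
    down_lines = lapply(j$down_lines, as_line),
    samples_per_span = j$samples_per_span %||% 10,
    spline_kind = j$spline_kind %||% "catmull-rom"
  )
}

#' @rdname read_splint_plan
#' @param plan a [splint_plan()].
#' @export
write_splint_plan <- function(plan, path) {
  as_entry <- function(l) {
    list(anchor = l$anchor, direction = l$direction,
         inner_length = l$inner_length, outside_length = l$outside_length)
  }
  jsonlite::write_json(
    list(schema = "splintplan/1",
         samples_per_span = plan$samples_per_span,
         spline_kind = plan$spline_kind,
         up_lines = lapply(plan$up_lines, as_entry),
         down_lines = lapply(plan$down_lines, as_entry)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
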