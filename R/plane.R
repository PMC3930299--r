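#' Cutting plane (point + unit normal)
#'
#' The neck cutting plane separates the aneurysm sac from the parent
#' vessel.  The normal is stored unit length and, by convention, oriented
#' toward the sac side.
#'
#' @param point a point on the plane (mm)
#' @param normal plane normal (any nonzero length; normalised on input)
#' @return object of class `plane3d` with `point` and unit `normal`
#' @export
plane3d <- function(point, normal) {
  point <- vec3(point, "plane point")
  normal <- vec3(normal, "plane normal")
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) abort_validation("plane normal is degenerate (zero length)")
  structure(list(point = point, normal = normal / len), class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("<plane3d: point (%.4g, %.4g, %.4g), normal (%.4g, %.4g, %.4g)>\n",
              x$point[1L], x$point[2L], x$point[3L],
              x$normal[1L], x$normal[2L], x$normal[3L]))
  invisible(x)
}

#' Plane through three points
#'
#' @param p1,p2,p3 non-collinear points (mm)
#' @param sac_point optional point on the sac side; if given, the normal is
#'   flipped if needed so it points toward it
#' @return a [plane3d()]
#' @export
plane_from_points <- function(p1, p2, p3, sac_point = NULL) {
  p1 <- vec3(p1); p2 <- vec3(p2); p3 <- vec3(p3)
  n <- cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-12) {
    abort_validation("three plane points are collinear")
  }
  if (!is.null(sac_point)) {
    sac_point <- vec3(sac_point, "sac-side point")
    if (sum(n * (sac_point - p1)) < 0) n <- -n
  }
  plane3d(p1, n)
}

#' Read a plane specification from JSON
#'
#' Accepts `{"point": [...], "normal": [...]}` or
#' `{"three_points": [[...],[...],[...]], "sac_point": [...]}` (the
#' `sac_point` orients the normal toward the sac).
#'
#' @param path path to a JSON file
#' @return a [plane3d()]; if the JSON carries a `sac_point`, it is attached
#'   as attribute `"sac_point"` (useful as an apex seed)
#' @export
plane_from_json <- function(path) {
  if (!file.exists(path)) abort_io("plane file not found: %s", path)
  spec <- tryCatch(jsonlite::fromJSON(path),
                   error = function(e) abort_io("cannot parse plane JSON %s: %s",
                                                path, conditionMessage(e)))
  pl <- if (!is.null(spec$point) && !is.null(spec$normal)) {
    plane3d(spec$point, spec$normal)
  } else if (!is.null(spec$three_points)) {
    tp <- spec$three_points
    if (is.data.frame(tp)) tp <- as.matrix(tp)
    if (!is.matrix(tp) || nrow(tp) != 3L) {
      abort_validation("three_points must be a 3 x 3 array")
    }
    plane_from_points(tp[1L, ], tp[2L, ], tp[3L, ], sac_point = spec$sac_point)
  } else {
    abort_validation("plane JSON needs point+normal or three_points: %s", path)
  }
  if (!is.null(spec$sac_point)) attr(pl, "sac_point") <- as.numeric(spec$sac_point)
  pl
}

#' Write a plane specification to JSON
#' @param plane a [plane3d()]
#' @param path output path
#' @param sac_point optional sac-side point recorded alongside
#' @return `path`, invisibly
#' @export
plane_to_json <- function(plane, path, sac_point = NULL) {
  spec <- list(point = plane$point, normal = plane$normal)
  if (!is.null(sac_point)) spec$sac_point <- as.numeric(sac_point)
  jsonlite::write_json(spec, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
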