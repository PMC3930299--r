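# Neck-frame construction, neck-curve extraction, sac/vessel separation.

PLANE_TOL <- 1e-6  # mm; "on the plane" tolerance, matches the STL weld

#' Place a model in the neck frame
#'
#' Applies the rigid transformation that makes the neck cutting plane
#' parallel to the XY plane: the plane normal is rotated onto +z by the
#' minimal (geodesic) rotation, with no additional in-plane rotation or
#' translation, so the transform is deterministic.  In the new frame the
#' plane is `{z = d}` with the sac on the `z > d` side.
#'
#' @param mesh a [triangle_mesh()]
#' @param plane a [plane3d()] with normal oriented toward the sac side
#' @return object of class `neck_frame`: list with `mesh` (transformed),
#'   `transform`, `d` (plane height in frame coordinates), and empty slots
#'   `neck_curve` filled by [extract_neck_curve()] and `labels` (mirrored in
#'   `mesh$labels`) filled by [split_sac()]
#' @export
build_neck_frame <- function(mesh, plane) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(plane, "plane3d"))
  R <- rotation_between(plane$normal, c(0, 0, 1))
  tf <- rigid_from_matrix(R)
  d <- sum(plane$point * plane$normal)
  structure(list(mesh = apply_transform(mesh, tf),
                 transform = tf, d = d, neck_curve = NULL),
            class = "neck_frame")
}

#' @export
print.neck_frame <- function(x, ...) {
  cat(sprintf("<neck_frame: d = %.6g mm, %d vertices%s%s>\n", x$d,
              n_vertices(x$mesh),
              if (!is.null(x$neck_curve)) ", neck curve extracted" else "",
              if (!is.null(x$mesh$labels)) ", sac labelled" else ""))
  invisible(x)
}

#' Extract the neck curve at the cutting plane
#'
#' Intersects the mesh with `{z = d}`, chains the intersection segments of
#' the crossing triangles into closed loops, and keeps the loop enclosing
#' the sac side.  Perimeter is the summed segment length; the centroid
#' (the "geometric center" of the neck, anchoring the scaling transform) is
#' the arc-length-weighted mean of the polyline, robust to non-uniform
#' tessellation.
#'
#' @param frame a [build_neck_frame()] result
#' @param inside_point optional sac-side point (frame coordinates) whose
#'   xy-projection selects among multiple loops; defaults to the centroid of
#'   the vertices above the plane
#' @return the input `neck_frame` with `$neck_curve` set: a `neck_curve`
#'   object with `points` (closed polyline, first row repeated last),
#'   `perimeter` (mm) and `centroid` (mm, on the plane)
#' @export
extract_neck_curve <- function(frame, inside_point = NULL) {
  stopifnot(inherits(frame, "neck_frame"))
  loops <- mesh_plane_loops(frame$mesh, frame$d)
  if (length(loops) == 0L) abort_validation("plane misses mesh")
  if (is.null(inside_point)) {
    above <- frame$mesh$vertices[, 3L] > frame$d + PLANE_TOL
    if (!any(above)) abort_validation("no vertices above the neck plane")
    inside_point <- colMeans(frame$mesh$vertices[above, , drop = FALSE])
  }
  lp <- select_loop(loops, inside_point, what = "neck")
  curve <- structure(
    list(points = rbind(lp$points, lp$points[1L, , drop = FALSE]),
         perimeter = lp$perimeter,
         centroid = lp$centroid),
    class = "neck_curve")
  frame$neck_curve <- curve
  frame
}

#' @export
print.neck_curve <- function(x, ...) {
  cat(sprintf("<neck_curve: %d points, perimeter %.6g mm, centroid (%.4g, %.4g, %.4g)>\n",
              nrow(x$points) - 1L, x$perimeter,
              x$centroid[1L], x$centroid[2L], x$centroid[3L]))
  invisible(x)
}

#' Label sac, vessel and neck vertices
#'
#' Faces lying strictly above the cutting plane are partitioned into
#' connected components; the component containing (the vertex nearest) the
#' apex seed is the sac.  A curved parent vessel may also rise above the
#' neck plane far from the sac, so membership is decided by seeded
#' connectivity, not by height alone.  Vertices on the plane (within
#' tolerance) are labelled `neck`; everything else is `vessel`.
#'
#' @param frame a `neck_frame`
#' @param apex_seed a point on the sac dome, strictly above the plane
#' @param seed_in_frame if `FALSE` (default) the seed is given in the
#'   original input coordinates and is transformed into the frame first
#' @return the `neck_frame` with `mesh$labels` filled
#' @export
split_sac <- function(frame, apex_seed, seed_in_frame = FALSE) {
  stopifnot(inherits(frame, "neck_frame"))
  apex_seed <- vec3(apex_seed, "apex seed")
  if (!seed_in_frame) apex_seed <- transform_points(frame$transform, apex_seed)
  d <- frame$d
  if (apex_seed[3L] <= d + PLANE_TOL) {
    abort_validation("apex seed lies on or below the neck plane (z = %.6g <= d = %.6g)",
                     apex_seed[3L], d)
  }
  v <- frame$mesh$vertices
  f <- frame$mesh$faces
  above_v <- v[, 3L] > d + PLANE_TOL
  above_f <- above_v[f[, 1L]] & above_v[f[, 2L]] & above_v[f[, 3L]]
  if (!any(above_f)) abort_validation("no faces strictly above the neck plane")
  fa <- f[above_f, , drop = FALSE]
  comp <- connected_components(nrow(v),
                               c(fa[, 1L], fa[, 2L], fa[, 3L]),
                               c(fa[, 2L], fa[, 3L], fa[, 1L]))
  # nearest above-plane vertex to the seed
  cand <- which(above_v)
  dif <- v[cand, , drop = FALSE] -
    matrix(apex_seed, length(cand), 3L, byrow = TRUE)
  seed_vertex <- cand[which.min(rowSums(dif * dif))]
  sac_comp <- comp[seed_vertex]
  in_above_face <- logical(nrow(v))
  in_above_face[as.vector(fa)] <- TRUE
  if (!in_above_face[seed_vertex]) {
    abort_validation("apex seed is not connected to any face above the plane")
  }
  sac <- in_above_face & comp == sac_comp
  labels <- rep("vessel", nrow(v))
  labels[sac] <- "sac"
  labels[abs(v[, 3L] - d) <= PLANE_TOL] <- "neck"
  bnd <- boundary_vertices(frame$mesh)
  if (length(bnd) > 0L && any(labels[bnd] == "sac")) {
    warning("sac component touches an open boundary ring; the parent vessel likely crosses the cutting plane",
            call. = FALSE)
  }
  frame$mesh$labels <- labels
  frame
}

#' Full neck-frame pipeline
#'
#' Convenience wrapper: [build_neck_frame()], [extract_neck_curve()] (loop
#' selected by the apex seed) and [split_sac()] in one call.
#'
#' @param mesh a [triangle_mesh()]
#' @param plane a [plane3d()] (normal toward the sac)
#' @param apex_seed point on the sac dome, in input coordinates
#' @return a fully populated `neck_frame`
#' @export
analyze_aneurysm <- function(mesh, plane, apex_seed) {
  frame <- build_neck_frame(mesh, plane)
  seed_f <- transform_points(frame$transform, vec3(apex_seed, "apex seed"))
  frame <- extract_neck_curve(frame, inside_point = seed_f)
  split_sac(frame, seed_f, seed_in_frame = TRUE)
}
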