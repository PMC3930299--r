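# Sac morphometry: height, perimeter-derived average neck diameter, ASR,
# classical aspect ratio, and the three measurement planes.

#' Measure sac morphometry
#'
#' Height `h` is the perpendicular distance from the neck plane to the sac
#' apex (the maximum of `z - d` over sac-labelled vertices).  The average
#' neck diameter is derived from the neck perimeter, `D = perimeter / pi`,
#' and the aneurysm size ratio is `ASR = h / D`.
#'
#' @param frame a `neck_frame` with neck curve extracted and sac labelled
#'   (see [analyze_aneurysm()])
#' @return object of class `sac_morphometry`: list with `h`, `neck_perimeter`,
#'   `D`, `ASR` (and `aspect_ratio`, the classical height / max-chord ratio)
#' @export
measure_sac <- function(frame) {
  stopifnot(inherits(frame, "neck_frame"))
  if (is.null(frame$neck_curve)) abort_validation("neck curve not extracted")
  if (is.null(frame$mesh$labels)) abort_validation("sac not labelled; run split_sac()")
  sac <- frame$mesh$labels == "sac"
  if (!any(sac)) abort_validation("no sac vertices above the plane")
  h <- max(frame$mesh$vertices[sac, 3L]) - frame$d
  if (h <= 0) abort_validation("sac height is non-positive")
  per <- frame$neck_curve$perimeter
  D <- per / pi
  structure(list(h = h,
                 neck_perimeter = per,
                 D = D,
                 ASR = h / D,
                 aspect_ratio = h / neck_width(frame$neck_curve)),
            class = "sac_morphometry")
}

#' @export
print.sac_morphometry <- function(x, ...) {
  cat(sprintf("<sac_morphometry: h = %.6g mm, neck perimeter = %.6g mm, D = %.6g mm, ASR = %.6g, aspect ratio = %.6g>\n",
              x$h, x$neck_perimeter, x$D, x$ASR, x$aspect_ratio))
  invisible(x)
}

#' Neck width: maximal in-plane chord of the neck polyline
#'
#' Rotation-independent by construction (projection-based width readings
#' depend on the viewing angle; the maximal chord does not).
#'
#' @param curve a `neck_curve`
#' @return scalar width (mm)
#' @export
neck_width <- function(curve) {
  stopifnot(inherits(curve, "neck_curve"))
  pts <- curve$points[-nrow(curve$points), 1:2, drop = FALSE]  # drop closing row
  if (nrow(pts) < 3L) abort_validation("degenerate neck polyline (< 3 points)")
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  dmat <- as.matrix(stats::dist(hp))
  max(dmat)
}

#' Classical aspect ratio (height / neck width)
#'
#' Provided for comparison with the ASR; the two agree exactly for circular
#' necks and differ otherwise.
#'
#' @param frame a measured `neck_frame` (neck curve + labels)
#' @return scalar aspect ratio
#' @export
classical_aspect_ratio <- function(frame) {
  measure_sac(frame)$aspect_ratio
}

#' The three measurement planes P1 (top), P2 (middle), P3 (neck)
#'
#' Parallel planes dividing the sac height into three equal intervals:
#' P3 on the neck plane (`z = d`), P2 at `z = d + h/3`, P1 at `z = d + 2h/3`,
#' each paired with its sac cross-section polygon for later field averaging.
#'
#' @param frame a measured `neck_frame`
#' @return object of class `measurement_planes`: list of three entries
#'   (`P1`, `P2`, `P3`), each with `z`, `plane` (a [plane3d()]) and
#'   `polygon` (closed polyline); plus `h` and `d`
#' @export
measurement_planes <- function(frame) {
  m <- measure_sac(frame)
  d <- frame$d
  h <- m$h
  sac_v <- frame$mesh$labels %in% c("sac", "neck")
  f <- frame$mesh$faces
  sac_faces <- which(sac_v[f[, 1L]] | sac_v[f[, 2L]] | sac_v[f[, 3L]])
  ref <- frame$neck_curve$centroid
  zs <- c(P1 = d + 2 * h / 3, P2 = d + h / 3, P3 = d)
  out <- lapply(seq_along(zs), function(i) {
    z <- zs[[i]]
    if (i == 3L) {
      poly <- frame$neck_curve$points
      per <- frame$neck_curve$perimeter
    } else {
      loops <- mesh_plane_loops(frame$mesh, z, face_idx = sac_faces)
      if (length(loops) == 0L) {
        abort_validation("measurement plane %s (z = %.4g) fails to intersect the sac",
                         names(zs)[i], z)
      }
      lp <- select_loop(loops, ref, what = names(zs)[i])
      poly <- rbind(lp$points, lp$points[1L, , drop = FALSE])
      per <- lp$perimeter
    }
    list(z = z,
         plane = plane3d(c(ref[1L], ref[2L], z), c(0, 0, 1)),
         polygon = poly,
         perimeter = per)
  })
  names(out) <- names(zs)
  structure(c(out, list(h = h, d = d)), class = "measurement_planes")
}

#' @export
print.measurement_planes <- function(x, ...) {
  cat(sprintf("<measurement_planes: h = %.6g mm; z(P1, P2, P3) = (%.6g, %.6g, %.6g)>\n",
              x$h, x$P1$z, x$P2$z, x$P3$z))
  invisible(x)
}
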