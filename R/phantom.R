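# Synthetic aneurysm phantom with closed-form morphometry.
#
# Geometry (neck plane = {z = 0}, sac side +z):
#   * vessel: a tube of length L along x with a flat top at z = -t_c
#     (cross-section: an ellipse with vertical semi-axis `vessel_radius`,
#     horizontal semi-axis widened when the sac is broad, cut by the
#     platform plane), closed by flat end caps;
#   * platform: the flat top carries an elliptical hole under the sac,
#     triangulated as an angular "zipper" annulus;
#   * collar: a short vertical elliptical cylinder from z = -t_c up to the
#     neck plane z = 0 -- its top ring lies exactly on the plane, so the
#     neck cross-section is the exact base ellipse and no mesh face is
#     coplanar with the cutting plane;
#   * sac: an exact half-ellipsoid dome, base semi-axes (r, r_y) on the
#     neck plane, polar semi-axis = sac height, apex vertex exact.
#
# Hence analytic ground truth: h = sac_height, neck perimeter = ellipse
# perimeter (2*pi*r for a circular neck), ASR = h / (perimeter / pi)
# = sac_height / (2 r) for circles.  The tessellated mesh measures the
# inscribed-polygon perimeter 2 n r sin(pi/n), converging monotonically
# from below as the tessellation n is refined.

# exact perimeter of an ellipse with semi-axes (a, b) by quadrature
ellipse_perimeter <- function(a, b) {
  if (a == b) return(2 * pi * a)
  f <- function(th) sqrt((a * sin(th))^2 + (b * cos(th))^2)
  4 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-12)$value
}

#' Generate a synthetic vessel-plus-sac phantom
#'
#' @param vessel_radius vessel half-diameter (mm); the default matches a
#'   typical intracranial inlet diameter of 3.478 mm
#' @param vessel_length tube length (mm)
#' @param sac_base_radius sac base semi-axis along the vessel (mm)
#' @param sac_base_radius_y sac base semi-axis across the vessel (mm);
#'   defaults to `sac_base_radius` (circular neck)
#' @param sac_height polar semi-axis of the half-ellipsoid sac (mm);
#'   equal to `sac_base_radius` gives a hemisphere (analytic ASR 0.5)
#' @param neck_offset sac centre along the tube (mm); default mid-length
#' @param tess tessellation level: segments per circle, >= 16
#' @param jitter_sd optional vertex jitter s.d. (mm) for robustness tests
#' @param seed RNG seed used when `jitter_sd > 0`
#' @return list with `mesh` (watertight [triangle_mesh()]), `plane` (the
#'   neck plane, normal toward the apex), `apex_seed` (the apex point) and
#'   `morphometry` (analytic: `h`, `neck_perimeter`, `D`, `ASR`, plus the
#'   tessellation-exact `polygon_perimeter` and `polygon_ASR`)
#' @export
make_phantom <- function(vessel_radius = 3.478 / 2,
                         vessel_length = 20,
                         sac_base_radius = 2,
                         sac_base_radius_y = sac_base_radius,
                         sac_height = 2,
                         neck_offset = vessel_length / 2,
                         tess = 64,
                         jitter_sd = 0,
                         seed = 1L) {
  build_phantom(vessel_radius, vessel_length, sac_base_radius,
                sac_base_radius_y, sac_height, neck_offset, tess,
                jitter_sd, seed, bend_radius = NULL)
}

#' Curved-vessel phantom
#'
#' Like [make_phantom()], but the tube arcs upward beyond the sac platform
#' so that part of the parent vessel surface rises above the neck plane far
#' from the sac -- the case where sac membership must be decided by seeded
#' connectivity rather than by height.
#'
#' @inheritParams make_phantom
#' @param bend_radius radius of the upward arc (mm); must exceed
#'   `vessel_radius`
#' @return as [make_phantom()]
#' @export
make_curved_phantom <- function(bend_radius,
                                vessel_radius = 3.478 / 2,
                                vessel_length = 20,
                                sac_base_radius = 2,
                                sac_base_radius_y = sac_base_radius,
                                sac_height = 2,
                                neck_offset = vessel_length / 2,
                                tess = 64,
                                jitter_sd = 0,
                                seed = 1L) {
  build_phantom(vessel_radius, vessel_length, sac_base_radius,
                sac_base_radius_y, sac_height, neck_offset, tess,
                jitter_sd, seed, bend_radius = bend_radius)
}

build_phantom <- function(Rv, L, r, ry, H, x0, tess, jitter_sd, seed,
                          bend_radius) {
  lens <- c(Rv, L, r, ry, H)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort_validation("all phantom lengths must be positive")
  }
  tess <- as.integer(tess)
  if (tess < 16L) abort_validation("tessellation must be >= 16")
  rmax <- max(r, ry)
  if (x0 - 1.1 * r < 0 || x0 + 1.1 * r > L) {
    abort_validation("sac (neck offset %.3g, radius %.3g) overlaps the tube ends",
                     x0, r)
  }
  t_c <- min(0.05 * H, 0.25 * Rv)           # collar depth below the plane
  A <- max(Rv, 1.3 * rmax)                  # horizontal semi-axis of the tube
  psi_c <- acos(t_c / Rv)
  w <- A * sin(psi_c)                       # platform half-width
  if (ry >= 0.98 * w) {
    abort_validation("sac base (ry = %.3g) too wide for the vessel platform (w = %.3g)",
                     ry, w)
  }

  n <- tess                                  # ring segments
  n_arc <- tess                              # cross-section arc points
  m <- max(8L, as.integer(round(tess / 4)))  # stations along the tube
  n_dome <- max(4L, as.integer(round(tess / 4)))

  s0 <- NULL
  if (!is.null(bend_radius)) {
    if (!is.finite(bend_radius) || bend_radius <= Rv) {
      abort_validation("bend radius (%.3g) must exceed the vessel radius (%.3g)",
                       bend_radius, Rv)
    }
    s0 <- x0 + 1.6 * r                       # bend starts beyond the platform
    if (s0 >= L - 2 * L / m) {
      abort_validation("tube too short for the requested bend: bend region would intersect the sac platform")
    }
  }

  ## ---- vertices -----------------------------------------------------
  phis <- seq(psi_c, -psi_c, length.out = n_arc)
  xs <- seq(0, L, length.out = m + 1L)
  arc_y <- A * sin(phis)
  arc_z <- -Rv * cos(phis)
  # arc grid: station-major, id(j, i) = (j-1)*n_arc + i for j in 1..m+1
  grid_x <- rep(xs, each = n_arc)
  grid_y <- rep(arc_y, times = m + 1L)
  grid_z <- rep(arc_z, times = m + 1L)
  V <- cbind(grid_x, grid_y, grid_z)
  id_arc <- function(j, i) (j - 1L) * n_arc + i

  cap0 <- nrow(V) + 1L
  V <- rbind(V, c(0, 0, -(Rv + t_c) / 2))
  capL <- nrow(V) + 1L
  V <- rbind(V, c(L, 0, -(Rv + t_c) / 2))

  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  hole0 <- nrow(V)
  V <- rbind(V, cbind(x0 + r * cos(theta), ry * sin(theta), -t_c))
  id_hole <- hole0 + seq_len(n)
  neck0 <- nrow(V)
  V <- rbind(V, cbind(x0 + r * cos(theta), ry * sin(theta), 0))
  id_neck <- neck0 + seq_len(n)

  psi_d <- seq(0, pi / 2, length.out = n_dome + 1L)
  ring_ids <- vector("list", n_dome + 1L)
  ring_ids[[1L]] <- id_neck
  for (l in 2:n_dome) {
    ps <- psi_d[l]
    base <- nrow(V)
    V <- rbind(V, cbind(x0 + r * cos(theta) * cos(ps),
                        ry * sin(theta) * cos(ps),
                        H * sin(ps)))
    ring_ids[[l]] <- base + seq_len(n)
  }
  apex <- nrow(V) + 1L
  V <- rbind(V, c(x0, 0, H))

  ## ---- faces --------------------------------------------------------
  fl <- list()
  # tube side strips
  j <- rep(1:m, each = n_arc - 1L)
  i <- rep(1:(n_arc - 1L), times = m)
  p00 <- id_arc(j, i); p10 <- id_arc(j + 1L, i)
  p11 <- id_arc(j + 1L, i + 1L); p01 <- id_arc(j, i + 1L)
  fl[[length(fl) + 1L]] <- cbind(p00, p10, p11)
  fl[[length(fl) + 1L]] <- cbind(p00, p11, p01)
  # end caps (fan over arc + closing chord)
  b0 <- id_arc(1L, 1:n_arc)
  bL <- id_arc(m + 1L, 1:n_arc)
  nxt <- c(2:n_arc, 1L)
  fl[[length(fl) + 1L]] <- cbind(cap0, b0, b0[nxt])
  fl[[length(fl) + 1L]] <- cbind(capL, bL[nxt], bL)
  # platform annulus: outer rectangle ring (CCW from +z) vs hole ring
  outer_ring <- c(id_arc(1:(m + 1L), n_arc),          # y = -w, x increasing
                  id_arc((m + 1L):1, 1L))             # y = +w, x decreasing
  fl[[length(fl) + 1L]] <- zip_rings(id_hole, outer_ring, V, c(x0, 0))
  # collar
  fl[[length(fl) + 1L]] <- ring_strip(id_hole, id_neck)
  # dome strips + apex fan
  for (l in 1:(n_dome - 1L)) {
    fl[[length(fl) + 1L]] <- ring_strip(ring_ids[[l]], ring_ids[[l + 1L]])
  }
  top_ring <- ring_ids[[n_dome]]
  fl[[length(fl) + 1L]] <- cbind(top_ring, top_ring[nxt_ring(n)], apex)

  faces <- do.call(rbind, fl)

  ## ---- optional bend and jitter ------------------------------------
  if (!is.null(bend_radius)) {
    dist <- pmax(V[, 1L] - s0, 0)
    s_cap <- pmin(dist, pi / 2 * bend_radius)
    V[, 3L] <- V[, 3L] + bend_radius * (1 - cos(s_cap / bend_radius))
  }
  if (jitter_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    V <- V + matrix(stats::rnorm(length(V), sd = jitter_sd), ncol = 3L)
    .Random.seed_restore(old)
  }

  mesh <- triangle_mesh(V, faces)
  per <- ellipse_perimeter(r, ry)
  # inscribed-polygon perimeter of the tessellated neck ring
  ring <- cbind(r * cos(theta), ry * sin(theta))
  seg <- ring[c(2:n, 1L), ] - ring
  poly_per <- sum(sqrt(rowSums(seg^2)))
  morph <- list(h = H,
                neck_perimeter = per,
                D = per / pi,
                ASR = H / (per / pi),
                polygon_perimeter = poly_per,
                polygon_ASR = H / (poly_per / pi))
  list(mesh = mesh,
       plane = plane3d(c(x0, 0, 0), c(0, 0, 1)),
       apex_seed = c(x0, 0, H),
       morphometry = morph)
}

nxt_ring <- function(n) c(2:n, 1L)

# outward-oriented quad strip between two stacked CCW rings (lower, upper)
ring_strip <- function(lower, upper) {
  n <- length(lower)
  nx <- nxt_ring(n)
  rbind(cbind(lower, lower[nx], upper[nx]),
        cbind(lower, upper[nx], upper))
}

# angular "zipper" triangulation of the annulus between a CCW inner ring
# and a CCW outer ring, both star-shaped about `center`; returns CCW
# triangles (normal +z)
zip_rings <- function(inner_idx, outer_idx, V, center) {
  ain <- atan2(V[inner_idx, 2L] - center[2L], V[inner_idx, 1L] - center[1L])
  aout <- atan2(V[outer_idx, 2L] - center[2L], V[outer_idx, 1L] - center[1L])
  oi <- order(ain); oo <- order(aout)
  inner_idx <- inner_idx[oi]; ain <- ain[oi]
  outer_idx <- outer_idx[oo]; aout <- aout[oo]
  ni <- length(inner_idx); no <- length(outer_idx)
  ainx <- c(ain, ain[1L] + 2 * pi)
  aoutx <- c(aout, aout[1L] + 2 * pi)
  tri <- matrix(0L, ni + no, 3L)
  ii <- 1L; io <- 1L; si <- 0L; so <- 0L; cnt <- 0L
  while (si < ni || so < no) {
    cand_i <- if (si < ni) ainx[ii + 1L] else Inf
    cand_o <- if (so < no) aoutx[io + 1L] else Inf
    cnt <- cnt + 1L
    if (cand_i <= cand_o) {
      nx <- if (ii == ni) 1L else ii + 1L
      tri[cnt, ] <- c(inner_idx[nx], inner_idx[ii], outer_idx[io])
      ii <- nx; si <- si + 1L
    } else {
      nx <- if (io == no) 1L else io + 1L
      tri[cnt, ] <- c(outer_idx[io], outer_idx[nx], inner_idx[ii])
      io <- nx; so <- so + 1L
    }
  }
  tri
}

# save/restore global RNG state around seeded jitter
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
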