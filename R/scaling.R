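# Height-graded anisotropic sac scaling.
#
# A sac point (x, y, z) above the neck plane, with neck centroid
# (x_m, y_m, z_m) and sac height h, maps to
#   x_t - x_m = [1 + a (z - z_m) (k - 1) / h] (x - x_m)
#   y_t - y_m = [1 + b (z - z_m) (k - 1) / h] (y - y_m)
#   z_t - z_m = [1 + c (z - z_m) (k - 1) / h] (z - z_m)
# so the deformation grades with height: zero at the neck, maximal at the
# dome, emulating the observation that aneurysm expansion rate grows from
# neck to fundus.  With c = 1 the apex height maps exactly to k * h while
# the neck and parent vessel are untouched.

#' Scaling parameters
#'
#' @param k height scaling factor (ratio of scaled to original sac height
#'   when `c = 1`)
#' @param a,b,c dimensionless gradation coefficients along x, y, z
#'   (defaults 2, 2, 1)
#' @param x_m,y_m,z_m neck centroid anchor (mm); `z_m` is the plane height
#' @param h pre-scaling sac height (mm), > 0
#' @return object of class `scaling_params`
#' @export
scaling_params <- function(k, a = 2, b = 2, c = 1,
                           x_m = 0, y_m = 0, z_m = 0, h = 1) {
  if (!is.finite(h) || h <= 0) abort_validation("sac height h must be > 0")
  if (!is.finite(k) || k <= 0) abort_validation("scaling factor k must be > 0")
  structure(list(a = a, b = b, c = c, k = k,
                 x_m = x_m, y_m = y_m, z_m = z_m, h = h),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("<scaling_params: k = %.6g, (a, b, c) = (%g, %g, %g), anchor (%.4g, %.4g, %.4g), h = %.6g mm>\n",
              x$k, x$a, x$b, x$c, x$x_m, x$y_m, x$z_m, x$h))
  invisible(x)
}

# parameters anchored at a measured frame (neck centroid + current height)
params_from_frame <- function(frame, k, a = 2, b = 2, c = 1) {
  m <- measure_sac(frame)
  ctr <- frame$neck_curve$centroid
  scaling_params(k, a, b, c,
                 x_m = ctr[1L], y_m = ctr[2L], z_m = frame$d, h = m$h)
}

#' Scale points by the height-graded transformation
#'
#' Rows with `z <= z_m` pass through unchanged (the transform is defined
#' above the neck plane only; gating by sac membership is the caller's
#' responsibility, see [scale_sac()]).
#'
#' @param points n x 3 matrix (or a single length-3 point)
#' @param params a [scaling_params()]
#' @return mapped points, same shape
#' @export
scale_points <- function(points, params) {
  stopifnot(inherits(params, "scaling_params"))
  single <- is.null(dim(points))
  if (single) points <- matrix(points, 1L, 3L)
  u <- points[, 3L] - params$z_m
  g <- pmax(u, 0) * (params$k - 1) / params$h  # graded factor argument
  out <- cbind(params$x_m + (1 + params$a * g) * (points[, 1L] - params$x_m),
               params$y_m + (1 + params$b * g) * (points[, 2L] - params$y_m),
               params$z_m + (1 + params$c * g) * u)
  if (single) out[1L, ] else out
}

#' @rdname scale_points
#' @param point a single length-3 point with `z > z_m`
#' @export
scale_point <- function(point, params) {
  scale_points(vec3(point, "point"), params)
}

#' Feasibility report for scaling parameters
#'
#' The transformation is injective on the sac column only while every
#' scaling factor stays positive: the lateral factors at the apex,
#' `1 + a (k - 1)` and `1 + b (k - 1)`, and the derivative of the z-map,
#' whose minimum over the sac height is `min(1, 1 + 2 c (k - 1))`.  With
#' the default (a, b, c) = (2, 2, 1), any k <= 0.5 drives the apex lateral
#' factor to zero or below and would invert the mesh.
#'
#' @param params a [scaling_params()]
#' @return list with `lateral_x`, `lateral_y`, `min_z_derivative`,
#'   `feasible`, class `scaling_feasibility`
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "scaling_params"))
  lx <- 1 + params$a * (params$k - 1)
  ly <- 1 + params$b * (params$k - 1)
  dz <- min(1, 1 + 2 * params$c * (params$k - 1))
  structure(list(lateral_x = lx, lateral_y = ly, min_z_derivative = dz,
                 feasible = lx > 0 && ly > 0 && dz > 0),
            class = "scaling_feasibility")
}

#' @export
print.scaling_feasibility <- function(x, ...) {
  cat(sprintf("<scaling_feasibility: lateral (x, y) = (%.6g, %.6g), min dz = %.6g -> %s>\n",
              x$lateral_x, x$lateral_y, x$min_z_derivative,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}

#' Solve the height scaling factor for a target ASR
#'
#' The neck diameter is invariant under sac scaling and the apex height
#' maps to `(1 + c (k - 1)) h`, so the ASR scales by `1 + c (k - 1)`.
#' Solving for the target gives
#' `k = 1 + (target / current - 1) / c`, which reduces to
#' `k = target / current` for the default `c = 1`.
#'
#' @param current_asr measured ASR of the model, > 0
#' @param target_asr desired ASR, > 0
#' @param c vertical gradation coefficient (default 1)
#' @return scalar k
#' @export
solve_k <- function(current_asr, target_asr, c = 1) {
  if (!is.finite(current_asr) || current_asr <= 0) {
    abort_validation("current ASR must be > 0")
  }
  if (!is.finite(target_asr) || target_asr <= 0) {
    abort_validation("target ASR must be > 0")
  }
  1 + (target_asr / current_asr - 1) / c
}

# minimal number of equal geometric steps k^(1/n) whose per-step factors all
# exceed `margin`
stepwise_n <- function(k, a, b, c, margin = 0.05) {
  step_ok <- function(ks) {
    min(1 + a * (ks - 1), 1 + b * (ks - 1), 1 + 2 * c * (ks - 1)) > margin
  }
  for (n in 1:64) {
    if (step_ok(k^(1 / n))) return(n)
  }
  abort_infeasible("no feasible geometric decomposition of k = %.6g within 64 steps", k)
}

#' Scale the aneurysm sac of a neck-frame model
#'
#' Applies the height-graded transformation to sac-labelled vertices above
#' the neck plane; neck and vessel vertices (and the mesh topology) are
#' untouched, so the parent artery and the aneurysm neck are kept constant.
#' Either `k` or `target_asr` must be given; with `target_asr` the factor is
#' solved from the re-measured current ASR.
#'
#' In `strict` mode infeasible parameters (see [validate_params()]) raise an
#' error.  In `stepwise` mode an infeasible single-step k is decomposed into
#' the minimal number of equal geometric steps `k^(1/n)`, each applied with
#' re-measured height and anchors, so any positive target remains reachable
#' without inverting the mesh.
#'
#' @param frame a measured `neck_frame` (see [analyze_aneurysm()])
#' @param k height scaling factor; alternative to `target_asr`
#' @param target_asr desired ASR; alternative to `k`
#' @param a,b,c gradation coefficients (defaults 2, 2, 1)
#' @param mode `"strict"` or `"stepwise"`
#' @param margin per-step factor margin for stepwise decomposition
#' @return the scaled `neck_frame`, with attributes `"params"` (the
#'   [scaling_params()] of the first step) and `"steps"` (number of steps)
#' @export
scale_sac <- function(frame, k = NULL, target_asr = NULL,
                      a = 2, b = 2, c = 1,
                      mode = c("strict", "stepwise"), margin = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "neck_frame"))
  if (is.null(k) == is.null(target_asr)) {
    abort_validation("give exactly one of k or target_asr")
  }
  if (is.null(k)) {
    k <- solve_k(measure_sac(frame)$ASR, target_asr, c = c)
  }
  if (!is.finite(k) || k <= 0) abort_validation("scaling factor k must be > 0")
  params1 <- params_from_frame(frame, k, a, b, c)
  feas <- validate_params(params1)
  if (!feas$feasible && mode == "strict") {
    failing <- c("apex lateral factor 1 + a(k-1)" = feas$lateral_x,
                 "apex lateral factor 1 + b(k-1)" = feas$lateral_y,
                 "z-map derivative 1 + 2c(k-1)" = feas$min_z_derivative)
    bad <- names(failing)[failing <= 0]
    abort_infeasible("infeasible scaling (k = %.6g): %s <= 0; use mode = \"stepwise\"",
                     k, paste(bad, collapse = ", "))
  }
  n_steps <- if (feas$feasible) 1L else stepwise_n(k, a, b, c, margin)
  ks <- k^(1 / n_steps)
  for (s in seq_len(n_steps)) {
    p <- if (s == 1L) {
      params_from_frame(frame, if (n_steps == 1L) k else ks, a, b, c)
    } else {
      params_from_frame(frame, ks, a, b, c)
    }
    sel <- frame$mesh$labels == "sac" &
      frame$mesh$vertices[, 3L] > p$z_m
    frame$mesh$vertices[sel, ] <-
      scale_points(frame$mesh$vertices[sel, , drop = FALSE], p)
    if (s == 1L) params1 <- p
  }
  attr(frame, "params") <- params1
  attr(frame, "steps") <- n_steps
  frame
}

#' Generate a longitudinal series of scaled models
#'
#' One model per schedule entry, each produced independently from the
#' original model (not chained), so entries are order-independent and the
#' height factor is exactly `target / current` (for `c = 1`).
#'
#' @param frame a measured `neck_frame`
#' @param asr_schedule vector of positive target ASRs; the default is the
#'   eight-value growth schedule 0.3 ... 2.0
#' @param a,b,c,mode,margin passed to [scale_sac()]
#' @param outdir optional directory: writes one binary STL per entry plus
#'   `manifest.csv`
#' @param check_self if `TRUE`, run the self-intersection scan per entry
#' @return list with `models` (list of scaled `neck_frame`s) and `manifest`
#'   (data.frame: target_asr, k, steps, measured_asr, watertight,
#'   self_intersecting)
#' @export
generate_series <- function(frame,
                            asr_schedule = c(0.3, 0.5, 0.7, 1.0, 1.3, 1.5, 1.7, 2.0),
                            a = 2, b = 2, c = 1,
                            mode = c("strict", "stepwise"), margin = 0.05,
                            outdir = NULL, check_self = TRUE) {
  mode <- match.arg(mode)
  if (length(asr_schedule) == 0L || any(!is.finite(asr_schedule)) ||
      any(asr_schedule <= 0)) {
    abort_validation("ASR schedule entries must be positive and finite")
  }
  cur <- measure_sac(frame)$ASR
  models <- vector("list", length(asr_schedule))
  rows <- vector("list", length(asr_schedule))
  for (i in seq_along(asr_schedule)) {
    tgt <- asr_schedule[i]
    scaled <- scale_sac(frame, target_asr = tgt, a = a, b = b, c = c,
                        mode = mode, margin = margin)
    m <- measure_sac(scaled)
    rep_ <- check_validity(scaled$mesh, self_intersection = check_self)
    if (isTRUE(rep_$self_intersecting)) {
      warning(sprintf("scaled model (target ASR %.4g) is self-intersecting", tgt),
              call. = FALSE)
    }
    models[[i]] <- scaled
    rows[[i]] <- data.frame(
      target_asr = tgt,
      k = solve_k(cur, tgt, c = c),
      steps = attr(scaled, "steps"),
      measured_asr = m$ASR,
      watertight = rep_$watertight,
      self_intersecting = if (check_self) rep_$self_intersecting else NA)
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      write_stl(scaled$mesh,
                file.path(outdir, sprintf("scaled_asr_%0.2f.stl", tgt)))
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(models = models, manifest = manifest)
}
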