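#' Indexed triangle surface mesh
#'
#' The geometric substrate for every operation in the package: a set of 3D
#' vertices (millimetres) and a set of faces indexing them.  Optional
#' per-vertex labels mark vertices as belonging to the aneurysm sac, the
#' parent vessel, or the neck ring.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param labels optional character vector of length n with values
#'   `"sac"`, `"vessel"` or `"neck"` (or `NA`).
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces` and `labels`.
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) abort_validation("vertices must be an n x 3 matrix")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0L && ncol(faces) != 3L) {
    abort_validation("faces must be an m x 3 matrix")
  }
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      abort_validation("face indices out of range [1, %d]", nrow(vertices))
    }
    degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    if (any(degen)) {
      abort_validation("%d face(s) reference a repeated vertex", sum(degen))
    }
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(vertices)) {
      abort_validation("labels must have one entry per vertex")
    }
    bad <- !is.na(labels) & !labels %in% c("sac", "vessel", "neck")
    if (any(bad)) abort_validation("labels must be sac, vessel or neck")
  }
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$labels)) {
                sprintf(", labels: %s",
                        paste(names(table(x$labels)), table(x$labels),
                              sep = "=", collapse = " "))
              } else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

# vertex coordinate triplets per face corner, as three n_face x 3 matrices
face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1L], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2L], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3L], , drop = FALSE])
}

#' Per-face areas of a mesh (mm^2)
#' @param mesh a `triangle_mesh`
#' @return numeric vector of length `nrow(mesh$faces)`
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  u <- fc$b - fc$a
  v <- fc$c - fc$a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# outward (orientation-defined) unit normals; zero-area faces get zero normal
face_normals <- function(mesh) {
  fc <- face_corners(mesh)
  u <- fc$b - fc$a
  v <- fc$c - fc$a
  n <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  len <- row_norms(n)
  len[len == 0] <- 1
  n / len
}

#' Signed enclosed volume of a closed oriented mesh (mm^3)
#'
#' Positive for consistently outward-oriented surfaces.  Meaningless for
#' open meshes.
#' @param mesh a `triangle_mesh`
#' @return scalar volume
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  a <- fc$a; b <- fc$b; ce <- fc$c
  det3 <- a[, 1L] * (b[, 2L] * ce[, 3L] - b[, 3L] * ce[, 2L]) -
    a[, 2L] * (b[, 1L] * ce[, 3L] - b[, 3L] * ce[, 1L]) +
    a[, 3L] * (b[, 1L] * ce[, 2L] - b[, 2L] * ce[, 1L])
  sum(det3) / 6
}

# directed and undirected edge bookkeeping shared by validity and cutting
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1L], f[, 2L], f[, 3L])
  to <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  # collision-free numeric key: vertex counts stay far below 2^26
  key <- lo * (n_vertices(mesh) + 1) + hi
  list(from = from, to = to, lo = lo, hi = hi, key = key,
       face = rep(seq_len(nrow(f)), 3L))
}

#' Validity report for a triangle mesh
#'
#' Reports, without throwing: `watertight` (every edge shared by exactly two
#' faces with opposite directed orientation), `manifold` (no edge bordered
#' by more than two faces), `oriented` (no directed edge repeated),
#' `min_face_area`, `n_components` (vertex-connectivity components) and
#' `n_boundary_edges`.  Optionally runs a triangle-triangle
#' self-intersection scan (see [check_self_intersection()]).
#'
#' @param mesh a `triangle_mesh`
#' @param self_intersection if `TRUE`, also report `self_intersecting`
#' @return named list, class `mesh_validity`
#' @export
check_validity <- function(mesh, self_intersection = FALSE) {
  if (n_faces(mesh) == 0L) {
    out <- list(watertight = FALSE, manifold = TRUE, oriented = TRUE,
                min_face_area = NA_real_, n_components = 0L,
                n_boundary_edges = 0L)
    if (self_intersection) out$self_intersecting <- FALSE
    class(out) <- "mesh_validity"
    return(out)
  }
  et <- mesh_edge_table(mesh)
  und_count <- table(et$key)
  cnt <- as.integer(und_count)
  manifold <- all(cnt <= 2L)
  n_boundary <- sum(cnt == 1L)
  dir_key <- et$from * (n_vertices(mesh) + 1) + et$to
  oriented <- !anyDuplicated(dir_key)
  watertight <- manifold && oriented && n_boundary == 0L
  comp <- connected_components(n_vertices(mesh), et$lo, et$hi)
  out <- list(watertight = watertight,
              manifold = manifold,
              oriented = oriented,
              min_face_area = min(face_areas(mesh)),
              n_components = max(comp),
              n_boundary_edges = n_boundary)
  if (self_intersection) {
    out$self_intersecting <- check_self_intersection(mesh)
  }
  class(out) <- "mesh_validity"
  out
}

#' @export
print.mesh_validity <- function(x, ...) {
  cat("<mesh_validity>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Apply a rigid transform to every vertex of a mesh
#'
#' Topology (faces, labels) is unchanged; only coordinates move.
#' @param mesh a `triangle_mesh`
#' @param transform a [rigid_transform()]
#' @return transformed `triangle_mesh`
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  v <- transform_points(transform, mesh$vertices)
  triangle_mesh(v, mesh$faces, mesh$labels)
}

# boundary vertex indices (vertices touching an edge with only one face)
boundary_vertices <- function(mesh) {
  if (n_faces(mesh) == 0L) return(integer(0))
  et <- mesh_edge_table(mesh)
  tab <- table(et$key)
  single <- names(tab)[tab == 1L]
  if (length(single) == 0L) return(integer(0))
  sel <- et$key %in% as.numeric(single)
  sort(unique(c(et$lo[sel], et$hi[sel])))
}
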