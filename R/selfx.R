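# Triangle-triangle self-intersection scan.
#
# Broad phase: uniform grid hashing of face bounding boxes.  Narrow phase:
# edge-versus-triangle crossing tests (Moller-Trumbore) in both directions;
# pairs sharing a vertex are skipped (they touch by construction).
# Exactly coplanar overlapping pairs are not detected; for the surfaces
# produced here, intersections arise from fold-over or collision of curved
# regions, which the edge tests catch.

#' Scan a mesh for self-intersections
#'
#' @param mesh a [triangle_mesh()]
#' @param tol intersection tolerance relative to segment parameter
#' @return `TRUE` if any two non-adjacent faces intersect
#' @export
check_self_intersection <- function(mesh, tol = 1e-10) {
  nf <- n_faces(mesh)
  if (nf < 2L) return(FALSE)
  fc <- face_corners(mesh)
  lo <- pmin(fc$a, pmin(fc$b, fc$c))
  hi <- pmax(fc$a, pmax(fc$b, fc$c))
  ext <- hi - lo
  cell <- stats::median(pmax(ext[, 1L], ext[, 2L], ext[, 3L])) * 1.01
  if (!is.finite(cell) || cell <= 0) cell <- max(ext, 1)
  origin <- apply(lo, 2L, min)
  ilo <- floor(sweep(lo, 2L, origin) / cell)
  ihi <- floor(sweep(hi, 2L, origin) / cell)
  # faces spanning many cells are re-listed per covered cell
  span <- (ihi[, 1L] - ilo[, 1L] + 1) * (ihi[, 2L] - ilo[, 2L] + 1) *
    (ihi[, 3L] - ilo[, 3L] + 1)
  face_of <- rep(seq_len(nf), span)
  keys <- character(sum(span))
  pos <- 1L
  for (i in seq_len(nf)) {
    g <- expand.grid(x = ilo[i, 1L]:ihi[i, 1L],
                     y = ilo[i, 2L]:ihi[i, 2L],
                     z = ilo[i, 3L]:ihi[i, 3L])
    k <- paste(g$x, g$y, g$z, sep = ",")
    keys[pos:(pos + length(k) - 1L)] <- k
    pos <- pos + length(k)
  }
  buckets <- split(face_of, keys)
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (bk in buckets) {
    if (length(bk) < 2L) next
    cmb <- utils::combn(sort(bk), 2L)
    pairs_i <- c(pairs_i, cmb[1L, ])
    pairs_j <- c(pairs_j, cmb[2L, ])
  }
  if (length(pairs_i) == 0L) return(FALSE)
  key <- pairs_i * (nf + 1) + pairs_j
  keep <- !duplicated(key)
  pairs_i <- pairs_i[keep]; pairs_j <- pairs_j[keep]
  # drop pairs sharing a vertex
  f <- mesh$faces
  share <- f[pairs_i, 1L] == f[pairs_j, 1L]
  for (ci in 1:3) for (cj in 1:3) {
    share <- share | f[pairs_i, ci] == f[pairs_j, cj]
  }
  pairs_i <- pairs_i[!share]; pairs_j <- pairs_j[!share]
  if (length(pairs_i) == 0L) return(FALSE)
  # bbox overlap prune
  ov <- lo[pairs_i, 1L] <= hi[pairs_j, 1L] & hi[pairs_i, 1L] >= lo[pairs_j, 1L] &
    lo[pairs_i, 2L] <= hi[pairs_j, 2L] & hi[pairs_i, 2L] >= lo[pairs_j, 2L] &
    lo[pairs_i, 3L] <= hi[pairs_j, 3L] & hi[pairs_i, 3L] >= lo[pairs_j, 3L]
  pairs_i <- pairs_i[ov]; pairs_j <- pairs_j[ov]
  if (length(pairs_i) == 0L) return(FALSE)
  any(edges_hit_triangles(mesh, fc, pairs_i, pairs_j, tol)) ||
    any(edges_hit_triangles(mesh, fc, pairs_j, pairs_i, tol))
}

# vectorised Moller-Trumbore: do any of the 3 edges of faces `ei` cross the
# interior of the triangles `tj`?  Returns a logical per pair.
edges_hit_triangles <- function(mesh, fc, ei, tj, tol) {
  hit <- logical(length(ei))
  ta <- fc$a[tj, , drop = FALSE]
  e1 <- fc$b[tj, , drop = FALSE] - ta
  e2 <- fc$c[tj, , drop = FALSE] - ta
  corners <- list(fc$a[ei, , drop = FALSE],
                  fc$b[ei, , drop = FALSE],
                  fc$c[ei, , drop = FALSE])
  for (e in 1:3) {
    p0 <- corners[[e]]
    p1 <- corners[[e %% 3L + 1L]]
    dirv <- p1 - p0
    pv <- rowcross(dirv, e2)
    det <- rowSums(e1 * pv)
    ok <- abs(det) > tol
    tv <- p0 - ta
    u <- rowSums(tv * pv) / det
    qv <- rowcross(tv, e1)
    v <- rowSums(dirv * qv) / det
    t_ <- rowSums(e2 * qv) / det
    inside <- ok & u > tol & v > tol & (u + v) < 1 - tol &
      t_ > tol & t_ < 1 - tol
    hit <- hit | (inside & !is.na(inside))
  }
  hit
}

rowcross <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}
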