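# Mesh-plane cross sections.
#
# All cutting happens in the neck frame, against horizontal planes {z = d}.
# Robustness: signed vertex distances with |s| < snap are pushed to the
# positive side (symbolic perturbation), so every face is strictly
# classified, vertices exactly on the plane never create degenerate
# segments, and coplanar patches fall wholly on one side.
#
# Segments are chained through shared *mesh edges*, not through coordinate
# matching: each crossing face contributes a segment between its two
# crossing edges, and on a manifold surface each crossing edge borders at
# most two crossing faces, giving well-defined closed loops.

SECTION_SNAP <- 1e-9  # mm

# returns a list of loops; each loop is a list(points = k x 3 matrix
# (open ring), perimeter, centroid). face_idx optionally restricts cutting
# to a subset of faces.
mesh_plane_loops <- function(mesh, d, face_idx = NULL, snap = SECTION_SNAP) {
  s <- mesh$vertices[, 3L] - d
  s[abs(s) < snap] <- snap
  f <- mesh$faces
  if (!is.null(face_idx)) f <- f[face_idx, , drop = FALSE]
  pos <- matrix(s[f] > 0, ncol = 3L)
  crossing <- rowSums(pos) %in% c(1L, 2L)
  if (!any(crossing)) return(list())
  f <- f[crossing, , drop = FALSE]
  nfc <- nrow(f)

  # per-face crossing edges: of (1,2), (2,3), (3,1) exactly two cross
  ea <- cbind(f[, 1L], f[, 2L], f[, 3L])
  eb <- cbind(f[, 2L], f[, 3L], f[, 1L])
  cross_e <- matrix(s[ea] * s[eb] < 0, ncol = 3L)
  stopifnot(all(rowSums(cross_e) == 2L))
  nv1 <- n_vertices(mesh) + 1
  ekey <- pmin(ea, eb) * nv1 + pmax(ea, eb)  # nfc x 3 undirected keys
  # two crossing-edge keys per face
  sel <- t(apply(cross_e, 1L, which))
  k1 <- ekey[cbind(seq_len(nfc), sel[, 1L])]
  k2 <- ekey[cbind(seq_len(nfc), sel[, 2L])]

  nodes <- unique(c(k1, k2))
  n1 <- match(k1, nodes)
  n2 <- match(k2, nodes)

  # intersection point per node (unique crossing edge)
  all_a <- c(ea)[c(cross_e)]
  all_b <- c(eb)[c(cross_e)]
  all_k <- c(ekey)[c(cross_e)]
  keep <- !duplicated(all_k)
  ord <- match(nodes, all_k[keep])
  va <- all_a[keep][ord]
  vb <- all_b[keep][ord]
  t_ <- s[va] / (s[va] - s[vb])
  pts <- mesh$vertices[va, , drop = FALSE] +
    t_ * (mesh$vertices[vb, , drop = FALSE] - mesh$vertices[va, , drop = FALSE])

  # chain: adjacency of nodes through faces
  nn <- length(nodes)
  deg <- tabulate(c(n1, n2), nbins = nn)
  if (any(deg > 2L)) {
    abort_validation("non-manifold cut: a mesh edge borders %d crossing faces",
                     max(deg))
  }
  if (any(deg < 2L)) {
    gap <- pts[which(deg < 2L)[1L], ]
    abort_validation(
      "open cross-section chain (non-watertight cut) near (%.4g, %.4g, %.4g)",
      gap[1L], gap[2L], gap[3L])
  }
  nb1 <- integer(nn); nb2 <- integer(nn)
  from <- c(n1, n2)
  to <- c(n2, n1)
  for (i in seq_along(from)) {
    v <- from[i]
    if (nb1[v] == 0L) nb1[v] <- to[i] else nb2[v] <- to[i]
  }

  visited <- logical(nn)
  loops <- list()
  for (start in seq_len(nn)) {
    if (visited[start]) next
    path <- integer(0)
    cur <- start
    prev <- 0L
    repeat {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- if (nb1[cur] != prev) nb1[cur] else nb2[cur]
      prev <- cur
      cur <- nxt
      if (cur == start) break
    }
    loop_pts <- pts[path, , drop = FALSE]
    seg <- loop_pts[c(seq_len(nrow(loop_pts))[-1L], 1L), , drop = FALSE] - loop_pts
    lens <- row_norms(seg)
    mids <- loop_pts + seg / 2
    per <- sum(lens)
    centroid <- colSums(mids * lens) / per
    loops[[length(loops) + 1L]] <-
      list(points = loop_pts, perimeter = per, centroid = centroid)
  }
  loops
}

# pick the loop whose in-plane polygon encloses the xy-projection of
# `inside_point`; errors if none does
select_loop <- function(loops, inside_point, what = "cross-section") {
  if (length(loops) == 0L) abort_validation("plane misses mesh (%s)", what)
  if (length(loops) == 1L) return(loops[[1L]])
  for (lp in loops) {
    if (point_in_polygon(inside_point[1:2], lp$points[, 1:2, drop = FALSE])) {
      return(lp)
    }
  }
  abort_validation("no %s loop encloses the reference point (%.4g, %.4g)",
                   what, inside_point[1L], inside_point[2L])
}
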