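# Shared fixtures and independent oracles, all built in code.

# regular icosahedron (closed, outward-oriented)
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(v, f)
}

# open tube of radius r along z in [z0, z1], n segments, m stations
open_cylinder <- function(r = 1, z0 = -1, z1 = 1, n = 32, m = 4) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  zs <- seq(z0, z1, length.out = m + 1)
  v <- do.call(rbind, lapply(zs, function(z) cbind(r * cos(theta), r * sin(theta), z)))
  fl <- list()
  nx <- c(2:n, 1)
  for (j in seq_len(m)) {
    lo <- (j - 1) * n + seq_len(n)
    hi <- j * n + seq_len(n)
    fl[[j]] <- rbind(cbind(lo, lo[nx], hi[nx]), cbind(lo, hi[nx], hi))
  }
  triangle_mesh(v, do.call(rbind, fl))
}

# canonical form for comparing meshes up to vertex/face reordering:
# sort vertices lexicographically, remap faces, rotate each face to start
# at its smallest index, sort faces
canonical_mesh <- function(mesh, digits = 5) {
  v <- round(mesh$vertices, digits)
  ord <- order(v[, 1], v[, 2], v[, 3])
  rank <- match(seq_len(nrow(v)), ord)
  f <- matrix(rank[mesh$faces], ncol = 3)
  rot <- apply(f, 1, function(tr) {
    i <- which.min(tr)
    tr[c(i, i %% 3 + 1, (i + 1) %% 3 + 1)]
  })
  f <- t(rot)
  f <- f[order(f[, 1], f[, 2], f[, 3]), , drop = FALSE]
  list(vertices = v[ord, , drop = FALSE], faces = f)
}

expect_mesh_equal <- function(a, b, tol = 1e-5) {
  ca <- canonical_mesh(a)
  cb <- canonical_mesh(b)
  expect_equal(dim(ca$vertices), dim(cb$vertices))
  expect_lt(max(abs(ca$vertices - cb$vertices)), tol)
  expect_identical(ca$faces, cb$faces)
}

# independent scalar oracle for the height-graded scaling map, coded
# directly from the per-coordinate formula (no shared code with the
# package implementation)
oracle_scale_one <- function(pt, a, b, c, k, x_m, y_m, z_m, h) {
  z <- pt[3]
  if (z <= z_m) return(pt)
  fx <- 1 + a * (z - z_m) * (k - 1) / h
  fy <- 1 + b * (z - z_m) * (k - 1) / h
  fz <- 1 + c * (z - z_m) * (k - 1) / h
  c(x_m + fx * (pt[1] - x_m),
    y_m + fy * (pt[2] - y_m),
    z_m + fz * (z - z_m))
}

# default hemisphere phantom, analysed; memoised per tessellation to keep
# the suite fast
analysed_phantom <- local({
  cache <- list()
  function(tess = 64, ...) {
    key <- paste0(tess, "/", paste(c(...), collapse = ","))
    if (is.null(cache[[key]])) {
      ph <- make_phantom(tess = tess, ...)
      fr <- analyze_aneurysm(ph$mesh, ph$plane, ph$apex_seed)
      cache[[key]] <<- list(phantom = ph, frame = fr)
    }
    cache[[key]]
  }
})
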