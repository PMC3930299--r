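# Mesh primitives, STL I/O, validity, rigid transforms.

test_that("ASCII STL of one triangle parses to 3 vertices, 1 face", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid one",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid one"), path)
  m <- read_stl(path)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_equal(m$vertices, cbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
               ignore_attr = TRUE)
})

test_that("duplicated facet corners weld to the distinct coordinate set", {
  # two triangles sharing an edge, written with duplicated coordinates the
  # way every STL writer does; the oracle is the count of distinct triples
  tris <- list(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  path <- withr::local_tempfile(fileext = ".stl")
  lines <- c("solid s")
  for (tr in tris) {
    lines <- c(lines, "facet normal 0 0 1", "outer loop",
               sprintf("vertex %g %g %g", tr[, 1], tr[, 2], tr[, 3]),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid s"), path)
  distinct <- unique(do.call(rbind, tris))
  m <- read_stl(path)
  expect_equal(nrow(m$vertices), nrow(distinct))
  expect_equal(nrow(m$faces), 2L)
  # shared edge is topological: the mesh has 5 unique undirected edges
  et <- aneumorph:::mesh_edge_table(m)
  expect_equal(length(unique(et$key)), 5L)
})

test_that("STL round-trips losslessly in both dialects", {
  ph <- make_phantom(tess = 24)
  for (dialect in c("binary", "ascii")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(ph$mesh, path, dialect)
    back <- read_stl(path)
    expect_mesh_equal(back, ph$mesh)
  }
  # a mesh that came from read_stl round-trips to identical topology and
  # float32-identical coordinates
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(ph$mesh, p1, "binary")
  m1 <- read_stl(p1)
  write_stl(m1, p2, "binary")
  m2 <- read_stl(p2)
  expect_identical(m1$faces, m2$faces)
  expect_identical(m1$vertices, m2$vertices)
})

test_that("binary STL writes are bit-stable for identical input", {
  ph <- make_phantom(tess = 20)
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(ph$mesh, p1)
  write_stl(ph$mesh, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("STL errors: missing, malformed, empty", {
  expect_error(read_stl(tempfile()), class = "aneumorph_io_error")
  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 zero", "vertex 0 1 0",
               "endloop", "endfacet", "endsolid x"), bad)
  expect_error(read_stl(bad), "line", class = "aneumorph_io_error")
  empty <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "endsolid x"), empty)
  expect_error(read_stl(empty), "empty", class = "aneumorph_io_error")
  expect_error(write_stl(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                         tempfile()),
               class = "aneumorph_validation_error")
})

test_that("validity: closed, holed, and two-component meshes", {
  ic <- icosahedron()
  rep1 <- check_validity(ic)
  expect_true(rep1$watertight)
  expect_true(rep1$manifold)
  expect_equal(rep1$n_components, 1L)

  holed <- triangle_mesh(ic$vertices, ic$faces[-1L, ])
  rep2 <- check_validity(holed)
  expect_false(rep2$watertight)
  expect_equal(rep2$n_boundary_edges, 3L)

  # union of two disjoint closed meshes stays watertight, 2 components
  shifted <- ic$vertices
  shifted[, 1L] <- shifted[, 1L] + 10
  both <- triangle_mesh(rbind(ic$vertices, shifted),
                        rbind(ic$faces, ic$faces + nrow(ic$vertices)))
  rep3 <- check_validity(both)
  expect_true(rep3$watertight)
  expect_equal(rep3$n_components, 2L)
})

test_that("rigid transforms preserve geometry and compose as printed", {
  tf_id <- rigid_transform()
  ic <- icosahedron()
  expect_identical(apply_transform(ic, tf_id)$vertices, ic$vertices)

  tf_t <- rigid_transform(p = 1, q = 2, r = 3)
  moved <- apply_transform(ic, tf_t)
  expect_equal(moved$vertices,
               sweep(ic$vertices, 2L, c(1, 2, 3), "+"), tolerance = 1e-15)

  # elemental blocks act on the axes implied by the matrix layout:
  # the phi block rotates about z, omega about y, theta about x
  ez <- c(0, 0, 1)
  expect_equal(transform_points(rigid_transform(phi = 1.2), ez), ez)
  expect_equal(transform_points(rigid_transform(omega = 0.4), c(0, 1, 0)),
               c(0, 1, 0))
  expect_equal(transform_points(rigid_transform(theta = -0.9), c(1, 0, 0)),
               c(1, 0, 0))

  set.seed(11)
  for (rep in 1:5) {
    tf <- rigid_transform(p = rnorm(1), q = rnorm(1), r = rnorm(1),
                          phi = runif(1, -pi, pi), omega = runif(1, -1.5, 1.5),
                          theta = runif(1, -pi, pi))
    P <- matrix(rnorm(30), 10L, 3L)
    d0 <- as.matrix(stats::dist(P))
    d1 <- as.matrix(stats::dist(transform_points(tf, P)))
    expect_lt(max(abs(d1 - d0) / (d0 + diag(10))), 1e-9)
    # rotation block orthonormal with det +1
    R <- tf$matrix[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    # angle decomposition reproduces the matrix
    ang <- tf$angles
    tf2 <- rigid_transform(tf$translation[1], tf$translation[2],
                           tf$translation[3], ang[1], ang[2], ang[3])
    expect_lt(max(abs(tf2$matrix - tf$matrix)), 1e-12)
    # inverse composes to identity
    P2 <- transform_points(transform_invert(tf), transform_points(tf, P))
    expect_lt(max(abs(P2 - P)), 1e-9)
  }
})

test_that("transforms preserve areas, volume and watertightness", {
  ph <- make_phantom(tess = 24)
  tf <- rigid_transform(0.3, -2, 5, phi = 0.5, omega = -0.3, theta = 1.1)
  moved <- apply_transform(ph$mesh, tf)
  expect_equal(face_areas(moved), face_areas(ph$mesh), tolerance = 1e-9)
  expect_equal(mesh_volume(moved), mesh_volume(ph$mesh), tolerance = 1e-9)
  expect_true(check_validity(moved)$watertight)
})

test_that("degenerate faces and bad indices are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(triangle_mesh(v, rbind(c(1L, 1L, 2L))),
               class = "aneumorph_validation_error")
  expect_error(triangle_mesh(v, rbind(c(1L, 2L, 4L))),
               class = "aneumorph_validation_error")
})

test_that("self-intersection scan flags overlapping components only", {
  ic <- icosahedron()
  expect_false(check_self_intersection(ic))
  # second icosahedron, generically rotated and shifted: interpenetrating
  tf <- rigid_transform(p = 1, q = 0.2, r = 0.3,
                        phi = 0.3, omega = 0.2, theta = 0.1)
  shifted <- transform_points(tf, ic$vertices)
  both <- triangle_mesh(rbind(ic$vertices, shifted),
                        rbind(ic$faces, ic$faces + nrow(ic$vertices)))
  expect_true(check_self_intersection(both))
  # far apart: clean
  shifted[, 1L] <- shifted[, 1L] + 20
  apart <- triangle_mesh(rbind(ic$vertices, shifted),
                         rbind(ic$faces, ic$faces + nrow(ic$vertices)))
  expect_false(check_self_intersection(apart))
})
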