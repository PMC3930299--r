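# Neck-frame construction, neck-curve extraction, sac/vessel separation.

test_that("build_neck_frame is the identity for an already-aligned plane", {
  ph <- make_phantom(tess = 24)
  fr <- build_neck_frame(ph$mesh, ph$plane)
  expect_equal(fr$d, 0)
  expect_identical(fr$mesh$vertices, ph$mesh$vertices)
  expect_equal(fr$transform$matrix, diag(4))
})

test_that("a flipped plane normal flips the sac to the +z side", {
  ph <- make_phantom(tess = 24)
  upside <- apply_transform(ph$mesh, rigid_transform(theta = pi))  # sac now -z
  pl <- plane3d(transform_points(rigid_transform(theta = pi), ph$plane$point),
                c(0, 0, -1))  # normal still toward the sac
  fr <- build_neck_frame(upside, pl)
  seed <- transform_points(fr$transform,
                           transform_points(rigid_transform(theta = pi), ph$apex_seed))
  expect_gt(seed[3], fr$d)
})

test_that("arbitrary planes map onto {z = d} within 1e-9", {
  set.seed(3)
  for (rep in 1:5) {
    pt <- rnorm(3, sd = 5)
    nrm <- rnorm(3)
    pl <- plane3d(pt, nrm)
    # sample points on the plane
    b1 <- aneumorph:::cross3(pl$normal, c(1, 0.3, -0.2))
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- aneumorph:::cross3(pl$normal, b1)
    samp <- t(sapply(1:20, function(i) pt + rnorm(1, sd = 3) * b1 + rnorm(1, sd = 3) * b2))
    mesh <- triangle_mesh(rbind(samp, samp + 1), cbind(1:10, 11:20, 21:30))
    fr <- build_neck_frame(mesh, pl)
    z <- transform_points(fr$transform, samp)[, 3]
    expect_lt(max(abs(z - fr$d)), 1e-9)
    # round trip through the inverse is the identity
    back <- transform_points(transform_invert(fr$transform),
                             fr$mesh$vertices)
    expect_lt(max(abs(back - mesh$vertices)), 1e-9)
  }
})

test_that("degenerate plane normal errors", {
  expect_error(plane3d(c(0, 0, 0), c(0, 0, 0)),
               class = "aneumorph_validation_error")
  expect_error(plane_from_points(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "aneumorph_validation_error")
})

test_that("neck curve of a cut cylinder recovers the tessellation perimeter", {
  # plane perpendicular to the axis of a radius-1 tube: the cut is the
  # inscribed n-gon of the unit circle, perimeter 2 n sin(pi/n) -> 2 pi
  perims <- sapply(c(16, 32, 64, 128), function(n) {
    cyl <- open_cylinder(r = 1, n = n)
    loops <- aneumorph:::mesh_plane_loops(cyl, 0.25)
    expect_length(loops, 1L)
    loops[[1]]$perimeter
  })
  expect_equal(perims, 2 * c(16, 32, 64, 128) * sin(pi / c(16, 32, 64, 128)),
               tolerance = 1e-12)
  # monotone convergence to 2*pi from below
  expect_true(all(diff(perims) > 0))
  expect_lt(abs(perims[4] - 2 * pi) / (2 * pi), 0.5 / 100)
})

test_that("hemisphere neck curve: perimeter ~ 2*pi*r, centroid at the center", {
  ap <- analysed_phantom(128)
  crv <- ap$frame$neck_curve
  expect_equal(crv$perimeter, ap$phantom$morphometry$polygon_perimeter,
               tolerance = 1e-7)
  expect_lt(abs(crv$perimeter - 2 * pi * 2) / (2 * pi * 2), 0.5 / 100)
  expect_equal(crv$centroid[1:2], c(10, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(max(abs(crv$points[, 3] - ap$frame$d)), 1e-6)
  # closed and simple
  expect_identical(crv$points[1, ], crv$points[nrow(crv$points), ])
})

test_that("a plane above the dome misses the mesh", {
  ph <- make_phantom(tess = 24)
  fr <- build_neck_frame(ph$mesh, plane3d(c(10, 0, 50), c(0, 0, 1)))
  expect_error(extract_neck_curve(fr), "misses",
               class = "aneumorph_validation_error")
})

test_that("an open cut chain is reported with its gap location", {
  # remove one crossing face from a tube so the section cannot close
  cyl <- open_cylinder(r = 1, n = 24, m = 2)
  zc <- 0.25  # cut between stations, away from any vertex ring
  crossing <- which(apply(matrix(cyl$vertices[cyl$faces, 3], ncol = 3), 1,
                          function(z) min(z) < zc && max(z) > zc))
  expect_gt(length(crossing), 0L)
  broken <- triangle_mesh(cyl$vertices, cyl$faces[-crossing[1], ])
  expect_error(aneumorph:::mesh_plane_loops(broken, zc), "open cross-section",
               class = "aneumorph_validation_error")
})

test_that("split_sac labels exactly the phantom's sac component", {
  ap <- analysed_phantom(32)
  labels <- ap$frame$mesh$labels
  n <- 32
  n_dome <- max(4, round(32 / 4))
  expect_equal(sum(labels == "sac"), (n_dome - 1) * n + 1)  # rings + apex
  expect_equal(sum(labels == "neck"), n)                    # base ring
  # all sac vertices are above the plane
  expect_true(all(ap$frame$mesh$vertices[labels == "sac", 3] > ap$frame$d))
})

test_that("split_sac rejects seeds on or below the plane", {
  ph <- make_phantom(tess = 24)
  fr <- extract_neck_curve(build_neck_frame(ph$mesh, ph$plane))
  expect_error(split_sac(fr, c(10, 0, -1)),
               class = "aneumorph_validation_error")
  expect_error(split_sac(fr, c(0, 0, 0)),
               class = "aneumorph_validation_error")
})

test_that("curved vessel above the plane stays out of the sac", {
  cp <- make_curved_phantom(bend_radius = 8, tess = 32)
  fr <- analyze_aneurysm(cp$mesh, cp$plane, cp$apex_seed)
  v <- fr$mesh$vertices
  f <- fr$mesh$faces
  above <- v[, 3] > fr$d + 1e-6
  af <- above[f[, 1]] & above[f[, 2]] & above[f[, 3]]
  fa <- f[af, , drop = FALSE]
  comp <- aneumorph:::connected_components(
    nrow(v), c(fa[, 1], fa[, 2], fa[, 3]), c(fa[, 2], fa[, 3], fa[, 1]))
  involved <- unique(as.vector(fa))
  expect_equal(length(unique(comp[involved])), 2L)  # sac + risen far tube
  # only the seeded component is sac
  sac_ids <- which(fr$mesh$labels == "sac")
  expect_true(all(sac_ids %in% involved))
  expect_equal(length(unique(comp[sac_ids])), 1L)
  expect_gt(sum(fr$mesh$labels == "vessel" & above), 0)
})

test_that("neck curve is equivariant under rigid motion of the input", {
  ph <- make_phantom(tess = 48)
  fr0 <- analyze_aneurysm(ph$mesh, ph$plane, ph$apex_seed)
  set.seed(9)
  tf <- rigid_transform(p = rnorm(1), q = rnorm(1), r = rnorm(1),
                        phi = 0.8, omega = -0.5, theta = 1.9)
  moved <- apply_transform(ph$mesh, tf)
  pl <- plane3d(transform_points(tf, ph$plane$point),
                transform_points(tf, ph$plane$point + ph$plane$normal) -
                  transform_points(tf, ph$plane$point))
  fr1 <- analyze_aneurysm(moved, pl, transform_points(tf, ph$apex_seed))
  expect_equal(fr1$neck_curve$perimeter, fr0$neck_curve$perimeter,
               tolerance = 1e-9)
  # centroid maps with the transform: compare in world coordinates
  c0 <- transform_points(transform_invert(fr0$transform), fr0$neck_curve$centroid)
  c1 <- transform_points(transform_invert(fr1$transform), fr1$neck_curve$centroid)
  expect_equal(transform_points(tf, c0), c1, tolerance = 1e-8)
})
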