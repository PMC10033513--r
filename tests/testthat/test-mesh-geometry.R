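test_that("mesh validation flags watertightness, winding and components", {
  cube <- unit_cube()
  r <- validate_mesh(cube)
  expect_true(r$watertight)
  expect_true(r$orientation_consistent)
  expect_equal(r$n_components, 1L)

  open_cube <- cube
  open_cube$faces <- open_cube$faces[-1, ]
  expect_false(validate_mesh(open_cube)$watertight)

  inverted <- cube
  inverted$faces <- inverted$faces[, c(1, 3, 2)]
  ri <- validate_mesh(inverted)
  expect_match(paste(ri$messages, collapse = " "), "inverted")
  expect_gt(mass_properties(ri$mesh, check = FALSE)$volume, 0)

  mixed <- cube
  mixed$faces[1, ] <- mixed$faces[1, c(1, 3, 2)]
  expect_false(validate_mesh(mixed)$orientation_consistent)
  expect_error(mass_properties(mixed), "mixed")

  expect_equal(validate_mesh(twin_cubes())$n_components, 2L)

  nonmanifold <- tri_mesh(rbind(cube$vertices, c(2, 2, 2)),
                          rbind(cube$faces, c(1, 2, 9)))
  expect_error(validate_mesh(nonmanifold), "non-manifold")
})

test_that("mass properties match closed forms exactly", {
  mp <- mass_properties(unit_cube(), density = 1000)
  expect_equal(mp$volume, 1, tolerance = 1e-12)
  expect_equal(mp$com, c(0.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(mp$mass, 1000, tolerance = 1e-12)

  tp <- mass_properties(unit_tetra())
  expect_equal(tp$volume, 1 / 6, tolerance = 1e-12)
  expect_equal(tp$com, c(0.25, 0.25, 0.25), tolerance = 1e-12)

  ic <- mesh_icosphere(1, 3)
  expect_lt(abs(mass_properties(ic)$volume - 4 * pi / 3) / (4 * pi / 3), 0.01)
})

test_that("volumes agree with the Monte-Carlo containment oracle", {
  ## five seeded meshes: convex and non-convex, one multi-component
  meshes <- list(mesh_icosphere(1, 2),
                 mesh_ellipsoid(1.2, 0.6, 0.9, centre = c(0.5, -0.3, 0.2),
                                resolution = 2),
                 bumpy_sphere(0.15),
                 bumpy_sphere(0.25, 3),
                 twin_cubes())
  for (i in seq_along(meshes)) {
    mc <- monte_carlo_volume(meshes[[i]], n = 2e4, seed = i)
    v <- mass_properties(meshes[[i]], check = FALSE)$volume
    expect_lt(abs(mc$volume - v), 3 * mc$se)
  }
})

test_that("mass properties transform covariantly under rigid motion", {
  m <- bumpy_sphere()
  mp <- mass_properties(m, check = FALSE)
  t <- c(3.2, -1.7, 0.4)
  mpt <- mass_properties(translate_mesh(m, t), check = FALSE)
  expect_equal(mpt$com, mp$com + t, tolerance = 1e-9)
  expect_equal(mpt$volume, mp$volume, tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mpr <- mass_properties(rotate_mesh(m, R), check = FALSE)
  expect_equal(mpr$com, as.numeric(R %*% mp$com), tolerance = 1e-9)
  expect_equal(mpr$volume, mp$volume, tolerance = 1e-9)
})

test_that("convex hull is correct, minimal and idempotent", {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  h <- convex_hull(corners)
  expect_equal(mass_properties(h)$volume, 1, tolerance = 1e-12)

  with_interior <- rbind(corners, c(0.5, 0.5, 0.5))
  h2 <- convex_hull(with_interior)
  expect_equal(nrow(h2$vertices), 8L)
  expect_equal(mass_properties(h2)$volume, 1, tolerance = 1e-12)

  ## seeded points in the unit ball: brute-force facet containment
  set.seed(42)
  P <- matrix(rnorm(600), ncol = 3)
  P <- P / sqrt(rowSums(P^2)) * runif(200)^(1 / 3)
  hb <- convex_hull(P)
  expect_true(all(hull_contains(hb, P)))
  vol <- mass_properties(hb)$volume
  expect_lt(vol, 4 * pi / 3)
  ## hull volume bounded by the AABB, bounded below by any inscribed
  ## tetrahedron of input points
  box <- apply(P, 2, max) - apply(P, 2, min)
  expect_lt(vol, prod(box))
  expect_gt(vol, abs(det(rbind(P[2, ] - P[1, ], P[3, ] - P[1, ],
                               P[4, ] - P[1, ]))) / 6)
  ## hull of the hull's vertices equals the hull
  expect_equal(mass_properties(convex_hull(hb$vertices))$volume, vol,
               tolerance = 1e-9)
})

test_that("hull of a convex mesh's vertices reproduces its volume", {
  for (m in list(mesh_icosphere(0.7, 2),
                 mesh_ellipsoid(0.3, 0.2, 0.15, resolution = 2))) {
    v <- mass_properties(m, check = FALSE)$volume
    hv <- mass_properties(convex_hull(m$vertices))$volume
    expect_equal(hv, v, tolerance = 1e-9)
  }
})

test_that("degenerate hull inputs fail with the rank named", {
  expect_error(convex_hull(matrix(rnorm(9), 3, 3)), ">= 4")
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(convex_hull(flat), "rank 2")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(convex_hull(line), "rank 1")
})

test_that("scale_to_volume hits the target and preserves the CoM", {
  cube <- unit_cube()
  s <- scale_to_volume(cube, 8)
  mp <- mass_properties(s)
  expect_equal(mp$volume, 8, tolerance = 1e-9)
  expect_equal(mp$com, c(0.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(max(s$vertices[, 1]) - min(s$vertices[, 1]), 2,
               tolerance = 1e-12)

  ic <- mesh_icosphere(1, 2)
  expect_equal(scale_to_volume(ic, mass_properties(ic)$volume)$vertices,
               ic$vertices, tolerance = 1e-12)
  v0 <- mass_properties(ic)$volume
  s2 <- scale_to_volume(ic, 2 * v0)
  expect_equal(mass_properties(s2)$volume, 2 * v0, tolerance = 1e-9)
  r0 <- sqrt(rowSums(ic$vertices^2))
  r2 <- sqrt(rowSums(s2$vertices^2))
  expect_equal(r2 / r0, rep(2^(1 / 3), length(r0)), tolerance = 1e-9)
  expect_error(scale_to_volume(ic, -1))
})
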