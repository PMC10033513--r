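test_that("primitive meshes approach their analytic volumes with resolution", {
  sph <- mesh_ellipsoid(0.1, 0.1, 0.1, resolution = 3)
  gt <- attr(sph, "ground_truth")
  expect_equal(gt$volume, 4 / 3 * pi * 1e-3, tolerance = 1e-12)
  expect_lt(abs(mass_properties(sph)$volume - gt$volume) / gt$volume, 0.01)

  ## coarse < medium < fine accuracy (inscribed solids underestimate)
  errs <- vapply(c("coarse", "medium", "fine"), function(rr) {
    m <- mesh_capsule(0.05, 0.3, resolution = rr)
    g <- attr(m, "ground_truth")
    (g$volume - mass_properties(m, check = FALSE)$volume) / g$volume
  }, numeric(1))
  expect_true(all(errs > 0))
  expect_true(all(diff(errs) < 0))

  fr <- mesh_frustum(0.2, 0.1, 0.5, base = c(1, 2, 3), axis = c(0, 1, 0),
                     resolution = "fine")
  g <- attr(fr, "ground_truth")
  mp <- mass_properties(fr)
  expect_lt(abs(mp$volume - g$volume) / g$volume, 0.02)
  expect_lt(sqrt(sum((mp$com - g$com)^2)), 0.01)
})

test_that("skeleton shrink gives exact hull:skin ratios", {
  plan <- body_plan("HLD", shrink = c(torso = 0.8))
  b <- build_body(plan, resolution = "coarse")
  seg <- Filter(function(s) s$name == "torso", b$segments)[[1]]
  ratio <- mass_properties(seg$skeleton_hull, check = FALSE)$volume /
    mass_properties(seg$skin_mesh, check = FALSE)$volume
  expect_equal(ratio, 0.8^3, tolerance = 1e-9)      # 0.512
  expect_equal(1 / ratio, 1.953125, tolerance = 1e-9)
})

test_that("every generated mesh validates and ground truth matches aggregation", {
  b <- build_body(body_plan("FLD"), resolution = "coarse")
  for (s in b$segments) {
    expect_true(validate_mesh(s$skin_mesh)$watertight)
    expect_true(validate_mesh(s$skeleton_hull)$watertight)
  }
  gt <- attr(b, "ground_truth")
  r <- whole_body_com(apply_density_scenario(b, density_scenario("homogeneous")))
  ## analytic (smooth) vs discretised CoM agree within the reported bound
  scale <- diff(range(gt$segments$com_x))
  expect_lt(abs(r$com_absolute[1] - gt$com[1]),
            gt$max_discretisation_error * scale)
  expect_lt(abs(r$com_absolute[2]), 1e-9)
  expect_equal(r$body_mass, gt$body_mass,
               tolerance = gt$max_discretisation_error)
})

test_that("pure-birth trees are ultrametric, reproducible and binary", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_true(ape::is.ultrametric(t2))
  expect_identical(write_newick(simulate_tree(7, seed = 9)),
                   write_newick(simulate_tree(7, seed = 9)))
  t50 <- simulate_tree(50, seed = 3)
  expect_equal(t50$Nnode, 49L)
  expect_true(ape::is.ultrametric(t50))
})

test_that("BM trait simulation obeys the variance and covariance laws", {
  ## zero rate: all tips equal the root
  tr <- simulate_tree(10, seed = 4)
  z <- simulate_traits(tr, c(x = 0), root = 2.5, seed = 1)
  expect_true(all(z$x == 2.5))

  ## star tree of depth T: tip variance ~ sigma^2 T across replicates
  st <- star_tree(n = 8, len = 2)
  tips <- do.call(rbind, lapply(1:500, function(i)
    simulate_traits(st, c(x = 1.5), seed = i)$x))
  v <- mean(apply(tips, 2, var))
  se <- sd(apply(tips, 2, var)) / sqrt(8)
  expect_lt(abs(v - 1.5 * 2), 4 * se)

  ## sister-tip covariance equals rate x shared path length
  chy <- read_newick("((A:1,B:1):2,C:3);")
  sims <- vapply(1:800, function(i) {
    z <- simulate_traits(chy, c(x = 1), seed = 1000 + i)$x
    z[1] * z[2]
  }, numeric(1))    # root at 0 so E[xA xB] = cov = sigma2 * 2
  expect_lt(abs(mean(sims) - 2), 4 * sd(sims) / sqrt(length(sims)))
})

test_that("fixture sets are deterministic and archetype-consistent", {
  fx1 <- make_fixture_set(sim_config(n_extant = 6, n_fossil = 2, seed = 7))
  fx2 <- make_fixture_set(sim_config(n_extant = 6, n_fossil = 2, seed = 7))
  expect_identical(fx1$traits, fx2$traits)
  expect_identical(write_newick(fx1$tree), write_newick(fx2$tree))
  expect_identical(fx1$answers, fx2$answers)

  ## FLD preset has larger normalised forelimbs than HLD by construction
  fx <- small_fixture()
  tt <- fx$traits
  expect_gt(mean(tt$forelimb_length_norm[tt$group == "FLD"]),
            mean(tt$forelimb_length_norm[tt$group == "HLD"]))
  expect_gt(mean(tt$tail_length_norm[tt$group == "HLD"]),
            mean(tt$tail_length_norm[tt$group == "FLD"]))

  ## fossils carry hulls only; answers hold the withheld truth
  expect_true(all(vapply(fx$fossils, function(f)
    all(vapply(f$segments, function(s) is.null(s$skin_mesh), logical(1))),
    logical(1))))
  expect_equal(nrow(fx$answers), 2L)
})
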