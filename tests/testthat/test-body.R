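test_that("density scenarios resolve the documented values", {
  fx <- small_fixture()
  b <- fx$extant[[2]]                      # an HLD bird
  dens <- function(body) {
    d <- vapply(body$segments, `[[`, numeric(1), "density")
    names(d) <- vapply(body$segments, `[[`, character(1), "name")
    d
  }
  std <- dens(apply_density_scenario(b, density_scenario("standard")))
  expect_equal(unname(std["neck"]), 800)
  expect_equal(unname(std["torso"]), 850)
  expect_true(all(std[!names(std) %in% c("neck", "torso")] == 1000))

  hom <- dens(apply_density_scenario(b, density_scenario("homogeneous")))
  expect_true(all(hom == 1000))

  gv_hld <- dens(apply_density_scenario(b, density_scenario("group_varying")))
  expect_equal(unname(gv_hld["neck"]), 825)
  expect_equal(unname(gv_hld["torso"]), 875)
  sau <- fx$extant[[1]]                   # non-avian sauropsid
  gv_sau <- dens(apply_density_scenario(sau, density_scenario("group_varying")))
  expect_equal(unname(gv_sau["neck"]), 850)
  expect_equal(unname(gv_sau["torso"]), 900)
  fld <- fx$extant[[3]]
  gv_fld <- dens(apply_density_scenario(fld, density_scenario("group_varying")))
  expect_equal(unname(gv_fld["neck"]), 800)
  expect_equal(unname(gv_fld["torso"]), 850)

  ## pure transformation: the input body is untouched
  expect_true(all(is.na(vapply(b$segments, `[[`, numeric(1), "density"))))
  expect_error(density_scenario("custom", c(wing = 900)), "unknown segment")
})

test_that("whole-body CoM is the mass-weighted mean of segment CoMs", {
  seg_at <- function(x, density, name, side = "axial")
    body_segment(name, side = side,
                 skin_mesh = mesh_box(c(x, 0, 0), c(0.1, 0.1, 0.1)),
                 density = density)
  two <- body_model("two", segments = list(seg_at(0, 1000, "head"),
                                           seg_at(1, 1000, "torso")),
                    hip_reference = c(0, 0, 0))
  r <- whole_body_com(two)
  expect_equal(r$com_absolute, c(0.5, 0, 0), tolerance = 1e-12)

  ## masses 1 : 3 at x = 0 and x = 1 -> com x = 0.75
  wtd <- body_model("wtd", segments = list(seg_at(0, 1000, "head"),
                                           seg_at(1, 3000, "torso")),
                    hip_reference = c(0, 0, 0))
  rw <- whole_body_com(wtd)
  expect_equal(rw$com_absolute[1], 0.75, tolerance = 1e-12)
  expect_equal(rw$cc_com, 0.75, tolerance = 1e-12)

  ## single segment: identity
  one <- body_model("one", segments = list(seg_at(0.4, 1000, "torso")),
                    hip_reference = c(0.1, 0, 0))
  ro <- whole_body_com(one)
  expect_equal(ro$com_absolute,
               mass_properties(one$segments[[1]]$skin_mesh)$com,
               tolerance = 1e-12)
  expect_equal(ro$cc_com, 0.3, tolerance = 1e-12)

  ## invariant to segment ordering
  r2 <- whole_body_com(body_model("wtd2",
                                  segments = rev(wtd$segments),
                                  hip_reference = c(0, 0, 0)))
  expect_equal(r2$com_absolute, rw$com_absolute, tolerance = 1e-14)

  ## normalisation identity is exact
  expect_equal(rw$cc_com_norm, rw$cc_com / rw$body_mass^(1 / 3))
})

test_that("splitting a segment into equal-union sub-meshes changes nothing", {
  whole <- body_model("whole", segments = list(
    body_segment("torso", skin_mesh = mesh_box(c(0, 0, 0), c(2, 1, 1)),
                 density = 1000)), hip_reference = c(0, 0, 0))
  split <- body_model("split", segments = list(
    body_segment("head", skin_mesh = mesh_box(c(-0.5, 0, 0), c(1, 1, 1)),
                 density = 1000),
    body_segment("torso", skin_mesh = mesh_box(c(0.5, 0, 0), c(1, 1, 1)),
                 density = 1000)), hip_reference = c(0, 0, 0))
  rw <- whole_body_com(whole); rs <- whole_body_com(split)
  expect_equal(rs$com_absolute, rw$com_absolute, tolerance = 1e-12)
  expect_equal(rs$body_mass, rw$body_mass, tolerance = 1e-9)
})

test_that("bilateral symmetry puts the CoM on the sagittal plane", {
  fx <- small_fixture()
  for (b in fx$extant[1:3]) {
    r <- whole_body_com(apply_density_scenario(b,
                                               density_scenario("standard")))
    body_length <- diff(range(vapply(b$segments, function(s)
      mass_properties(s$skin_mesh, check = FALSE)$com[1], numeric(1))))
    expect_lt(abs(r$com_absolute[2]), 1e-9 * body_length)
  }
})

test_that("density scaling moves mass but not geometry", {
  fx <- small_fixture()
  b <- apply_density_scenario(fx$extant[[2]], density_scenario("standard"))
  b2 <- b
  b2$segments <- lapply(b2$segments, function(s) { s$density <- 2 * s$density; s })
  r <- whole_body_com(b); r2 <- whole_body_com(b2)
  expect_equal(r2$body_mass, 2 * r$body_mass, tolerance = 1e-12)
  expect_equal(r2$cc_com, r$cc_com, tolerance = 1e-12)
  expect_equal(r2$dv_com, r$dv_com, tolerance = 1e-12)
  expect_equal(r2$cc_com_norm, r$cc_com_norm * 2^(-1 / 3), tolerance = 1e-12)
})

test_that("homogeneous-density whole body equals merged-geometry mass properties", {
  ## two boxes sharing a face form a valid closed union mesh
  merged <- mesh_box(c(0.5, 0, 0), c(3, 1, 1))
  split <- body_model("s", segments = list(
    body_segment("torso", skin_mesh = mesh_box(c(0, 0, 0), c(2, 1, 1)),
                 density = 1000),
    body_segment("tail", skin_mesh = mesh_box(c(1.5, 0, 0), c(1, 1, 1)),
                 density = 1000)), hip_reference = c(0, 0, 0))
  r <- whole_body_com(split)
  mp <- mass_properties(merged)
  expect_equal(r$com_absolute, mp$com, tolerance = 1e-12)
  expect_equal(r$body_mass, mp$mass, tolerance = 1e-9)
})

test_that("missing limb sides are reconstructed by mirroring", {
  fx <- small_fixture()
  b <- apply_density_scenario(fx$extant[[2]], density_scenario("standard"))
  full <- whole_body_com(b)
  onesided <- b
  onesided$segments <- Filter(function(s) s$side != "right", onesided$segments)
  half <- whole_body_com(onesided, mirror = TRUE)
  expect_equal(half$body_mass, full$body_mass, tolerance = 1e-9)
  expect_equal(half$com_absolute, full$com_absolute, tolerance = 1e-9)
  expect_gt(length(half$mirrored), 0)
  expect_error(whole_body_com(onesided, mirror = FALSE), NA)
})

test_that("segment summary reports lengths, fractions and sternum measures", {
  seg <- function(name, x, d, pj, dj)
    body_segment(name, skin_mesh = mesh_box(c(x, 0, 0), c(0.2, 0.2, 0.2)),
                 density = d, proximal_joint = pj, distal_joint = dj)
  lm <- rbind(cranial = c(0.2, 0, -0.1), caudal = c(-0.2, 0, -0.1),
              keel = c(0, 0, -0.25))
  b <- body_model("s", segments = list(
    seg("torso", 0, 1000, c(0, 0, 0), c(0.3, 0, 0)),
    seg("tail", -0.5, 1500, c(0, 0, 0), c(0, 0, -0.3))),
    hip_reference = c(0, 0, 0), sternum_landmarks = lm)
  ss <- segment_summary(b)
  expect_equal(ss$length, c(0.3, 0.3), tolerance = 1e-12)
  expect_equal(sum(ss$mass_fraction), 1, tolerance = 1e-9)
  expect_equal(ss$mass_fraction, c(1000, 1500) / 2500, tolerance = 1e-12)
  expect_equal(ss$length_norm, ss$length / attr(ss, "body_mass")^(1 / 3))
  expect_equal(attr(ss, "sternum_length"), 0.4, tolerance = 1e-12)
  expect_equal(attr(ss, "sternum_depth"), 0.15, tolerance = 1e-12)
})
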