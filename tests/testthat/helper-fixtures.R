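## Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

## unit cube with corner at the origin
unit_cube <- function() mesh_box(centre = c(0.5, 0.5, 0.5), dims = c(1, 1, 1))

## explicit outward-wound tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1)
unit_tetra <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

## smooth non-convex deformation of an icosphere (radial scaling by a
## smooth function of direction: star-shaped, never self-intersecting)
bumpy_sphere <- function(amp = 0.15, subdivisions = 2) {
  m <- mesh_icosphere(1, subdivisions)
  m$vertices <- m$vertices * (1 + amp * sin(2 * m$vertices[, 3]))
  m
}

## two disjoint cubes: watertight, 2 components, non-convex as a set
twin_cubes <- function() {
  a <- mesh_box(c(0, 0, 0)); b <- mesh_box(c(3, 0, 0))
  tri_mesh(rbind(a$vertices, b$vertices), rbind(a$faces, b$faces + 8L))
}

## single-segment body: a box "torso" of given volume/position
box_body <- function(taxon, skin_vol, hull_vol = NULL, centre = c(0, 0, 0),
                     class = "HLD", status = "extant") {
  mk <- function(v) mesh_box(centre, dims = rep(v^(1 / 3), 3))
  seg <- body_segment("torso", skin_mesh = mk(skin_vol),
                      skeleton_hull = if (!is.null(hull_vol)) mk(hull_vol),
                      density = 1000,
                      proximal_joint = centre + c(0.1, 0, 0),
                      distal_joint = centre - c(0.1, 0, 0))
  body_model(taxon, status = status, locomotor_class = class,
             segments = list(seg), hip_reference = c(0, 0, 0))
}

## small generated taxon set, reused by many tests
small_fixture <- function() cached("small_fixture", function()
  make_fixture_set(sim_config(n_extant = 9, n_fossil = 2,
                              ratio_noise_sd = 0, seed = 11)))

## same but with ratio noise
noisy_fixture <- function() cached("noisy_fixture", function()
  make_fixture_set(sim_config(n_extant = 9, n_fossil = 2,
                              ratio_noise_sd = 0.05, seed = 12)))

star_tree <- function(n = 20, len = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}

## brute-force BM log-likelihood in the internal node states (sigma^2
## and constants dropped: the argmax is invariant to them)
bm_profile_negloglik <- function(tree, x) {
  ntip <- length(tree$tip.label)
  function(z) {
    vals <- c(x[tree$tip.label], z)
    sum((vals[tree$edge[, 2]] - vals[tree$edge[, 1]])^2 / tree$edge.length)
  }
}
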