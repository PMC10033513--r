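## Primitive closed meshes used by the synthetic-body generator and the
## test-suite oracles. All are outward-wound and watertight by
## construction; named resolutions trade volume accuracy for speed
## (inscribed discretisations always under-estimate the smooth volume).

resolution_level <- function(resolution) {
  if (is.character(resolution))
    switch(match.arg(resolution, c("coarse", "medium", "fine")),
           coarse = 1L, medium = 2L, fine = 3L)
  else as.integer(resolution)
}

#' Axis-aligned box mesh
#'
#' @param centre Box centre (m).
#' @param dims Edge lengths (m), length 3.
#' @return A [tri_mesh()] with 8 vertices and 12 faces.
#' @export
mesh_box <- function(centre = c(0, 0, 0), dims = c(1, 1, 1)) {
  h <- dims / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  v <- sweep(v, 2, centre, "+")
  ## outward-wound faces of the unit cube in expand.grid vertex order
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = -h
             c(5, 6, 7), c(6, 8, 7),   # z = +h
             c(1, 2, 5), c(2, 6, 5),   # y = -h
             c(3, 7, 4), c(4, 7, 8),   # y = +h
             c(1, 5, 3), c(3, 5, 7),   # x = -h
             c(2, 4, 6), c(4, 8, 6))   # x = +h
  tri_mesh(v, f)
}

#' Icosphere (subdivided icosahedron)
#'
#' @param radius Sphere radius (m).
#' @param subdivisions Number of 4-to-1 triangle subdivisions (0 = raw
#'   icosahedron; 3 gives 1280 faces, volume within ~0.7% of the smooth
#'   sphere).
#' @param centre Sphere centre.
#' @return A [tri_mesh()].
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 3L, centre = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- vector("list", 0)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, vlist))
    f <- newf
  }
  tri_mesh(sweep(v * radius, 2, centre, "+"), f)
}

#' Ellipsoid mesh with analytic ground truth
#'
#' An icosphere anisotropically scaled to semi-axes `(a, b, c)`. The
#' attached `ground_truth` attribute carries the smooth-surface volume
#' `4/3 pi a b c` and centroid (= centre) used by the synthetic-data
#' oracles.
#'
#' @param a,b,c Semi-axes along x, y, z (m).
#' @param centre Ellipsoid centre.
#' @param resolution `"coarse"`, `"medium"`, `"fine"` or an integer
#'   subdivision count (1, 2, 3).
#' @return A [tri_mesh()] with attribute `ground_truth`
#'   (list: `volume`, `com`).
#' @export
mesh_ellipsoid <- function(a, b, c, centre = c(0, 0, 0),
                           resolution = "medium") {
  sub <- resolution_level(resolution)
  m <- mesh_icosphere(1, sub)
  m$vertices <- sweep(m$vertices %*% diag(c(a, b, c)), 2, centre, "+")
  attr(m, "ground_truth") <- list(volume = 4 / 3 * pi * a * b * c,
                                  com = as.numeric(centre))
  m
}

## Orthonormal frame whose third column is the unit axis.
frame_from_axis <- function(axis) {
  w <- axis / sqrt(sum(axis^2))
  up <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- crossp(up, w); u <- u / sqrt(sum(u^2))
  v <- crossp(w, u)
  cbind(u, v, w)
}

#' Capsule mesh (cylinder with hemispherical caps)
#'
#' Built along the z axis and rotated so its long axis is `axis`;
#' `centre` is the midpoint of the cylindrical part. Analytic volume
#' `pi r^2 L + 4/3 pi r^3`; centroid at `centre` by symmetry.
#'
#' @param r Radius (m).
#' @param length Cylinder length L (m, caps excluded).
#' @param centre Midpoint of the cylinder axis.
#' @param axis Direction of the long axis.
#' @param resolution Named resolution or integer level.
#' @return A [tri_mesh()] with attribute `ground_truth`.
#' @export
mesh_capsule <- function(r, length, centre = c(0, 0, 0), axis = c(0, 0, 1),
                         resolution = "medium") {
  lev <- resolution_level(resolution)
  ns <- c(10L, 16L, 28L)[min(lev, 3L)]       # sectors
  mh <- c(3L, 5L, 8L)[min(lev, 3L)]          # rings per hemisphere
  hl <- length / 2
  theta <- seq(0, 2 * pi, length.out = ns + 1L)[-(ns + 1L)]
  rings <- list()
  ## bottom hemisphere: phi from -pi/2 (pole) up to 0 (equator at -hl)
  for (i in seq_len(mh)) {
    phi <- -pi / 2 + (i / mh) * (pi / 2)
    rings[[length(rings) + 1L]] <-
      cbind(r * cos(phi) * cos(theta), r * cos(phi) * sin(theta),
            -hl + r * sin(phi))
  }
  ## top hemisphere: phi from 0 (equator at +hl) up to just below pole
  for (i in 0:(mh - 1L)) {
    phi <- (i / mh) * (pi / 2)
    rings[[length(rings) + 1L]] <-
      cbind(r * cos(phi) * cos(theta), r * cos(phi) * sin(theta),
            hl + r * sin(phi))
  }
  v <- rbind(c(0, 0, -hl - r), do.call(rbind, rings), c(0, 0, hl + r))
  nb <- 1L                       # bottom pole index
  nt <- nrow(v)                  # top pole index
  ring_idx <- function(k) 1L + (k - 1L) * ns + seq_len(ns)   # k-th ring
  nr <- length(rings)
  f <- list()
  rb <- ring_idx(1L)
  f[[length(f) + 1L]] <- cbind(nb, c(rb[-1], rb[1]), rb)
  for (k in seq_len(nr - 1L)) {
    lo <- ring_idx(k); hi <- ring_idx(k + 1L)
    lo2 <- c(lo[-1], lo[1]); hi2 <- c(hi[-1], hi[1])
    f[[length(f) + 1L]] <- cbind(lo, lo2, hi)
    f[[length(f) + 1L]] <- cbind(lo2, hi2, hi)
  }
  rt <- ring_idx(nr)
  f[[length(f) + 1L]] <- cbind(nt, rt, c(rt[-1], rt[1]))
  f <- do.call(rbind, f)
  R <- frame_from_axis(axis)
  m <- tri_mesh(sweep(v %*% t(R), 2, centre, "+"), f)
  attr(m, "ground_truth") <- list(volume = pi * r^2 * length + 4 / 3 * pi * r^3,
                                  com = as.numeric(centre))
  m
}

#' Conical frustum mesh
#'
#' A capped cone section from `base` towards `base + h * axis`, radius
#' `r1` at the base and `r2` at the top. Analytic (smooth-cone) volume
#' `pi h (r1^2 + r1 r2 + r2^2) / 3`; centroid on the axis at height
#' `h (r1^2 + 2 r1 r2 + 3 r2^2) / (4 (r1^2 + r1 r2 + r2^2))` from the
#' base.
#'
#' @param r1,r2 Base and top radii (m).
#' @param h Height (m).
#' @param base Base-centre point.
#' @param axis Direction from base to top.
#' @param resolution Named resolution or integer level.
#' @return A [tri_mesh()] with attribute `ground_truth`.
#' @export
mesh_frustum <- function(r1, r2, h, base = c(0, 0, 0), axis = c(0, 0, 1),
                         resolution = "medium") {
  lev <- resolution_level(resolution)
  ns <- c(10L, 18L, 32L)[min(lev, 3L)]
  theta <- seq(0, 2 * pi, length.out = ns + 1L)[-(ns + 1L)]
  ring1 <- cbind(r1 * cos(theta), r1 * sin(theta), 0)
  ring2 <- cbind(r2 * cos(theta), r2 * sin(theta), h)
  v <- rbind(c(0, 0, 0), ring1, ring2, c(0, 0, h))
  i1 <- 1L + seq_len(ns)
  i2 <- 1L + ns + seq_len(ns)
  ctop <- nrow(v)
  nxt <- function(idx) c(idx[-1], idx[1])
  f <- rbind(
    cbind(1L, nxt(i1), i1),                       # base cap (faces -z)
    cbind(i1, nxt(i1), i2),                       # side
    cbind(nxt(i1), nxt(i2), i2),
    cbind(ctop, i2, nxt(i2)))                     # top cap (faces +z)
  R <- frame_from_axis(axis)
  m <- tri_mesh(sweep(v %*% t(R), 2, base, "+"), f)
  q <- r1^2 + r1 * r2 + r2^2
  zc <- h * (r1^2 + 2 * r1 * r2 + 3 * r2^2) / (4 * q)
  attr(m, "ground_truth") <- list(volume = pi * h * q / 3,
                                  com = as.numeric(base + zc * axis /
                                                     sqrt(sum(axis^2))))
  m
}
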