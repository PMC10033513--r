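#' 3D convex hull of a point set
#'
#' Incremental (Quickhull-class) construction: an initial extreme
#' tetrahedron is grown by inserting each remaining point, deleting the
#' faces it can see and stitching a fan of new faces around the horizon.
#' The returned mesh is watertight, outward-wound and convex; every
#' input point lies inside or on it to within `tol` (relative to the
#' bounding-box diagonal). This is the "minimum convex hull" primitive
#' used to bound skeletal point sets.
#'
#' @param points Numeric matrix, n x 3 (n >= 4, not all coplanar).
#' @param tol Relative tolerance for visibility/containment decisions;
#'   default `1e-10` of the bounding-box diagonal.
#' @return A [tri_mesh()] whose vertices are the hull's extreme points
#'   only.
#' @export
convex_hull <- function(points, tol = 1e-10) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  points <- unique(points)
  n <- nrow(points)
  if (n < 4L)
    stop("convex hull needs >= 4 distinct points, got ", n)
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr, "-"))$d
  rank <- sum(sv > max(sv) * 1e-10)
  if (rank < 3L)
    stop("degenerate point set: affine rank ", rank,
         " (", c("all points identical", "collinear", "coplanar")[rank + 1L],
         "); a 3D hull is undefined")
  eps <- tol * bbox_diag(points)

  ## --- initial tetrahedron from extreme points --------------------------
  i1 <- which.min(points[, 1]); i2 <- which.max(points[, 1])
  if (i1 == i2) { i1 <- which.min(points[, 2]); i2 <- which.max(points[, 2]) }
  e <- points[i2, ] - points[i1, ]
  rel <- sweep(points, 2, points[i1, ], "-")
  cr <- row_cross(rel, matrix(e, n, 3, byrow = TRUE))
  i3 <- which.max(rowSums(cr^2))
  nrm0 <- crossp(points[i2, ] - points[i1, ], points[i3, ] - points[i1, ])
  i4 <- which.max(abs(rel %*% nrm0))
  simplex <- c(i1, i2, i3, i4)
  if (length(unique(simplex)) < 4L)
    stop("degenerate point set: could not find 4 affinely independent points")
  ## orient so signed volume positive
  if (det(rbind(points[i2, ] - points[i1, ],
                points[i3, ] - points[i1, ],
                points[i4, ] - points[i1, ])) < 0)
    simplex <- simplex[c(1, 3, 2, 4)]
  faces <- rbind(simplex[c(1, 3, 2)], simplex[c(1, 2, 4)],
                 simplex[c(2, 3, 4)], simplex[c(1, 4, 3)])
  interior <- colMeans(points[simplex, ])

  plane <- function(f) {
    a <- points[f[1], ]
    nrm <- crossp(points[f[2], ] - a, points[f[3], ] - a)
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm <- nrm / len
    off <- sum(nrm * a)
    ## outward: interior point strictly below
    if (sum(nrm * interior) - off > 0) {
      nrm <- -nrm; off <- -off; f <- f[c(1, 3, 2)]
    }
    list(f = f, nrm = nrm, off = off)
  }
  pls <- lapply(seq_len(nrow(faces)), function(i) plane(faces[i, ]))
  faces <- do.call(rbind, lapply(pls, `[[`, "f"))
  N <- do.call(rbind, lapply(pls, `[[`, "nrm"))
  d <- vapply(pls, `[[`, numeric(1), "off")

  remaining <- setdiff(seq_len(n), simplex)
  ## insert far points first: fewer total faces touched
  remaining <- remaining[order(-rowSums(sweep(points[remaining, , drop = FALSE],
                                              2, interior, "-")^2))]
  for (p in remaining) {
    dist <- as.numeric(N %*% points[p, ]) - d
    vis <- dist > eps
    if (!any(vis)) next
    vf <- faces[vis, , drop = FALSE]
    de <- directed_edges(vf)
    uk <- undirected_key(de)
    horizon <- de[!(uk %in% uk[duplicated(uk)]), , drop = FALSE]
    newf <- cbind(horizon, p)
    np <- lapply(seq_len(nrow(newf)), function(i) plane(newf[i, ]))
    faces <- rbind(faces[!vis, , drop = FALSE],
                   do.call(rbind, lapply(np, `[[`, "f")))
    N <- rbind(N[!vis, , drop = FALSE], do.call(rbind, lapply(np, `[[`, "nrm")))
    d <- c(d[!vis], vapply(np, `[[`, numeric(1), "off"))
  }

  ## compact to used vertices
  used <- sort(unique(as.vector(faces)))
  remap <- integer(n); remap[used] <- seq_along(used)
  tri_mesh(points[used, , drop = FALSE],
           matrix(remap[faces], ncol = 3))
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Test containment of points in a convex mesh
#'
#' Brute-force half-space test: a point is inside if it lies on or below
#' the plane of every facet. Intended as the independent correctness
#' check for [convex_hull()].
#'
#' @param mesh A convex, outward-wound [tri_mesh()].
#' @param points Numeric matrix, n x 3.
#' @param tol Relative tolerance (of the mesh bounding-box diagonal).
#' @return Logical vector, one entry per point.
#' @export
hull_contains <- function(mesh, points, tol = 1e-9) {
  points <- as.matrix(points)
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  nrm <- row_cross(V[F[, 2], , drop = FALSE] - a, V[F[, 3], , drop = FALSE] - a)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / len
  off <- rowSums(nrm * a)
  eps <- tol * bbox_diag(mesh)
  ## dist matrix: faces x points
  dmat <- nrm %*% t(points) - off
  apply(dmat <= eps, 2, all)
}

#' Point-in-mesh test by ray casting
#'
#' Parity ray casting along a fixed direction, valid for any watertight
#' mesh (convex or not). For each face the ray-triangle intersection is
#' an affine map of the query point, so the test is vectorised over
#' points. Used as the Monte-Carlo containment oracle that
#' cross-validates divergence-theorem volumes.
#'
#' @param mesh A watertight [tri_mesh()].
#' @param points Numeric matrix, n x 3.
#' @param direction Ray direction; default an arbitrary irrational-ish
#'   direction that avoids edge-grazing for axis-aligned geometry.
#' @return Logical vector, one entry per point.
#' @export
points_in_mesh <- function(mesh, points,
                           direction = c(0.57735027, 0.52573111, 0.62481053)) {
  points <- as.matrix(points)
  npt <- nrow(points)
  dir <- direction / sqrt(sum(direction^2))
  V <- mesh$vertices; F <- mesh$faces
  hits <- integer(npt)
  for (i in seq_len(nrow(F))) {
    v0 <- V[F[i, 1], ]; e1 <- V[F[i, 2], ] - v0; e2 <- V[F[i, 3], ] - v0
    M <- cbind(-dir, e1, e2)
    dt <- det(M)
    if (abs(dt) < 1e-300) next              # ray parallel to face plane
    Minv <- solve(M)
    tuv <- sweep(points, 2, v0, "-") %*% t(Minv)
    hit <- tuv[, 1] > 0 & tuv[, 2] >= 0 & tuv[, 3] >= 0 &
      (tuv[, 2] + tuv[, 3]) <= 1
    hits <- hits + hit
  }
  hits %% 2L == 1L
}

#' Monte-Carlo volume estimate
#'
#' Uniform rejection sampling in the axis-aligned bounding box with
#' [points_in_mesh()] containment; returns the estimate and its standard
#' error. This is a deliberately independent route to the volume: it
#' shares no code with the divergence-theorem computation in
#' [mass_properties()].
#'
#' @param mesh A watertight [tri_mesh()].
#' @param n Number of sample points.
#' @param seed Integer seed (the sampler is self-contained and does not
#'   disturb the global RNG stream).
#' @return List with `volume`, `se`, `n`, `n_inside`.
#' @export
monte_carlo_volume <- function(mesh, n = 1e5, seed = 1L) {
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  pts <- withr_seed(seed, {
    matrix(stats::runif(3 * n), ncol = 3)
  })
  pts <- sweep(sweep(pts, 2, hi - lo, "*"), 2, lo, "+")
  inside <- points_in_mesh(mesh, pts)
  vbox <- prod(hi - lo)
  phat <- mean(inside)
  list(volume = vbox * phat,
       se = vbox * sqrt(phat * (1 - phat) / n),
       n = n, n_inside = sum(inside))
}

## Evaluate `expr` under a local RNG state seeded with `seed`, restoring
## the caller's stream afterwards.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
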