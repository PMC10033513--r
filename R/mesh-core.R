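#' Construct a triangle mesh
#'
#' A `tri_mesh` is the carrier of all volumetric computation in hullcom:
#' a closed, consistently wound triangle surface in metres. Faces are
#' 1-based vertex index triples, counter-clockwise when viewed from
#' outside the solid.
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in metres.
#' @param faces Integer matrix, m x 3, vertex indices (1-based).
#' @return An object of class `tri_mesh` with elements `vertices` and
#'   `faces`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range [1, n_vertices]")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
    stop("degenerate faces (repeated vertex index)")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

## Bounding-box diagonal; all geometric tolerances are expressed relative
## to this so mm- and m-scale models behave identically.
bbox_diag <- function(x) {
  v <- if (inherits(x, "tri_mesh")) x$vertices else x
  sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Signed volume of the mesh (divergence theorem, tetrahedra against the
## origin). Positive for outward-wound closed surfaces.
signed_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  sum(rowSums(v1 * row_cross(v2, v3))) / 6
}

## Directed edge table: 2m x 2 matrix of (from, to) vertex indices.
directed_edges <- function(faces) {
  rbind(cbind(faces[, 1], faces[, 2]),
        cbind(faces[, 2], faces[, 3]),
        cbind(faces[, 3], faces[, 1]))
}

edge_key <- function(e) paste(e[, 1], e[, 2], sep = "-")
undirected_key <- function(e) paste(pmin(e[, 1], e[, 2]),
                                    pmax(e[, 1], e[, 2]), sep = "-")

## Connected components of the face graph (faces sharing a vertex).
n_mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    a <- find(f[1])
    for (j in 2:3) {
      b <- find(f[j])
      if (a != b) parent[b] <- a
    }
  }
  used <- sort(unique(as.vector(mesh$faces)))
  length(unique(vapply(used, find, integer(1))))
}

#' Validate a triangle mesh
#'
#' Checks watertightness (every undirected edge shared by exactly two
#' faces), winding consistency (each shared edge traversed once in each
#' direction) and connectivity. A globally inverted but otherwise
#' consistent mesh is repaired by flipping all faces; the repair is
#' recorded in `messages`. Mixed winding is deliberately NOT repaired:
#' it is reported so that volume computations can refuse such meshes.
#'
#' @param mesh A [tri_mesh()].
#' @return An object of class `mesh_report`: list with `watertight`,
#'   `orientation_consistent`, `n_components`, `messages`, and `mesh`
#'   (the possibly orientation-repaired input).
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  messages <- character(0)
  de <- directed_edges(mesh$faces)
  uk <- undirected_key(de)
  cnt <- table(uk)
  if (any(cnt > 2)) {
    bad <- names(cnt)[cnt > 2]
    stop("non-manifold edges (shared by > 2 faces): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" ... and %d more", length(bad) - 10))
  }
  watertight <- all(cnt == 2)
  if (!watertight)
    messages <- c(messages,
                  sprintf("%d boundary edges (open surface)", sum(cnt == 1)))
  ## consistent winding <=> no directed edge is repeated
  dk <- edge_key(de)
  orientation_consistent <- watertight && !anyDuplicated(dk)
  if (watertight && !orientation_consistent)
    messages <- c(messages, "mixed face winding detected")
  if (orientation_consistent) {
    sv <- signed_volume(mesh)
    if (sv < 0) {
      mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
      messages <- c(messages, "globally inverted orientation repaired (all faces flipped)")
    }
  }
  structure(list(watertight = watertight,
                 orientation_consistent = orientation_consistent,
                 n_components = n_mesh_components(mesh),
                 messages = messages,
                 mesh = mesh),
            class = "mesh_report")
}

#' @export
print.mesh_report <- function(x, ...) {
  cat("mesh_report:\n")
  cat("  watertight:            ", x$watertight, "\n")
  cat("  orientation_consistent:", x$orientation_consistent, "\n")
  cat("  n_components:          ", x$n_components, "\n")
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Mass properties of a closed mesh
#'
#' Volume and centre of mass by signed tetrahedron decomposition against
#' the coordinate origin (divergence theorem); exact for polyhedra. The
#' result is independent of the decomposition origin and transforms
#' covariantly under rigid-body motion.
#'
#' @param mesh A watertight [tri_mesh()].
#' @param density Segment density in kg m^-3 (default 1000, the density
#'   of water and the conventional whole-body reference for tetrapods).
#' @param check Validate (and orientation-repair) the mesh first. Set to
#'   `FALSE` only in inner loops over meshes already validated.
#' @return Object of class `mass_properties`: list with `volume` (m^3),
#'   `com` (length-3 numeric, m), `mass` (kg), `density`.
#' @export
mass_properties <- function(mesh, density = 1000, check = TRUE) {
  stopifnot(inherits(mesh, "tri_mesh"), is.numeric(density), density > 0)
  if (check) {
    rep <- validate_mesh(mesh)
    if (!rep$watertight)
      stop("mass_properties: mesh is not watertight; volume undefined")
    if (!rep$orientation_consistent)
      stop("mass_properties: mixed face winding; refusing to compute a signed volume")
    mesh <- rep$mesh
  }
  V <- mesh$vertices; F <- mesh$faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  w <- rowSums(v1 * row_cross(v2, v3)) / 6       # signed tetra volumes
  vol <- sum(w)
  if (vol <= 0)
    stop("mass_properties: non-positive volume after orientation check")
  com <- colSums((v1 + v2 + v3) / 4 * w) / vol   # 4th tetra vertex is origin
  structure(list(volume = vol, com = as.numeric(com),
                 mass = vol * density, density = density),
            class = "mass_properties")
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf("volume %.6g m^3, mass %.6g kg (density %g kg/m^3)\n",
              x$volume, x$mass, x$density))
  cat(sprintf("com (%.6g, %.6g, %.6g) m\n", x$com[1], x$com[2], x$com[3]))
  invisible(x)
}

#' Isotropically rescale a mesh to a target volume
#'
#' Scales the mesh about `centre` by `(target_volume / volume)^(1/3)`.
#' When `centre` is the mesh centre of mass (the default) the CoM is
#' unchanged — the property that makes per-segment hull expansion
#' direction-neutral.
#'
#' @param mesh A watertight [tri_mesh()].
#' @param target_volume Target volume in m^3 (> 0).
#' @param centre Point to scale about; default the mesh CoM.
#' @param check Passed on to [mass_properties()].
#' @return The rescaled `tri_mesh`.
#' @export
scale_to_volume <- function(mesh, target_volume, centre = NULL, check = TRUE) {
  stopifnot(is.numeric(target_volume), length(target_volume) == 1L,
            target_volume > 0)
  mp <- mass_properties(mesh, check = check)
  if (is.null(centre)) centre <- mp$com
  centre <- as.numeric(centre)
  f <- (target_volume / mp$volume)^(1 / 3)
  mesh$vertices <- sweep(sweep(mesh$vertices, 2, centre, "-") * f,
                         2, centre, "+")
  mesh
}

#' Rigid-body / mirror transforms of a mesh
#'
#' `translate_mesh` shifts all vertices; `rotate_mesh` applies a 3x3
#' rotation about the origin; `mirror_mesh` reflects across the sagittal
#' (y = 0) plane and re-flips the face winding so the result stays
#' outward-wound.
#'
#' @param mesh A [tri_mesh()].
#' @param t Length-3 translation (m).
#' @param R 3x3 rotation matrix.
#' @return The transformed `tri_mesh`.
#' @export
translate_mesh <- function(mesh, t) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(t), "+")
  mesh
}

#' @rdname translate_mesh
#' @export
rotate_mesh <- function(mesh, R) {
  mesh$vertices <- mesh$vertices %*% t(R)
  mesh
}

#' @rdname translate_mesh
#' @export
mirror_mesh <- function(mesh) {
  mesh$vertices[, 2] <- -mesh$vertices[, 2]
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]  # restore winding
  mesh
}
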