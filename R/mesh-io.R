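#' Read and write triangle meshes
#'
#' Minimal readers/writers for the three ascii interchange formats in
#' common use for volumetric models: Wavefront OBJ, ascii PLY and ascii
#' STL. Coordinates are converted to metres on load according to
#' `units` (scan-derived models are frequently in millimetres). STL
#' files carry no connectivity, so identical vertices are merged on
#' read.
#'
#' @param path File path; format inferred from the extension
#'   (`.obj`, `.ply`, `.stl`) unless `format` is given.
#' @param units Unit of the coordinates in the file: `"m"`, `"cm"` or
#'   `"mm"`. Converted to metres on read; on write the mesh (always in
#'   metres) is converted to `units`.
#' @param format Override the extension-based format choice.
#' @return `read_mesh`: a [tri_mesh()] in metres. `write_mesh`: the
#'   path, invisibly.
#' @export
read_mesh <- function(path, units = c("m", "mm", "cm"), format = NULL) {
  units <- match.arg(units)
  fmt <- tolower(format %||% tools::file_ext(path))
  mesh <- switch(fmt,
                 obj = read_obj(path),
                 ply = read_ply_ascii(path),
                 stl = read_stl_ascii(path),
                 stop("unsupported mesh format: ", fmt))
  mesh$vertices <- mesh$vertices * unit_scale(units)
  mesh
}

#' @rdname read_mesh
#' @param mesh A [tri_mesh()] (metres).
#' @export
write_mesh <- function(mesh, path, units = c("m", "mm", "cm"),
                       format = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  units <- match.arg(units)
  fmt <- tolower(format %||% tools::file_ext(path))
  out <- mesh
  out$vertices <- out$vertices / unit_scale(units)
  switch(fmt,
         obj = write_obj(out, path),
         ply = write_ply_ascii(out, path),
         stl = write_stl_ascii(out, path),
         stop("unsupported mesh format: ", fmt))
  invisible(path)
}

unit_scale <- function(units) c(m = 1, cm = 0.01, mm = 0.001)[[units]]

`%||%` <- function(a, b) if (is.null(a)) b else a

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("OBJ file has no v/f records: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  fidx <- lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    ii <- as.integer(sub("/.*", "", x))       # drop texture/normal refs
    if (length(ii) != 3L)
      stop("OBJ face with ", length(ii), " vertices; only triangles supported")
    ii
  })
  tri_mesh(v, do.call(rbind, fidx))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# hullcom OBJ export", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines)))
    stop("only ascii PLY supported (binary PLY is out of scope): ", path)
  hdr_end <- grep("^end_header", lines)[1]
  nv <- as.integer(sub(".*element vertex +", "",
                       grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face +", "",
                       grep("element face", lines, value = TRUE)[1]))
  body <- lines[(hdr_end + 1L):length(lines)]
  v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                             function(x) {
                               n <- as.integer(x[1])
                               if (n != 3L) stop("non-triangular PLY face")
                               as.integer(x[2:4]) + 1L   # PLY is 0-based
                             }))
  tri_mesh(v, f)
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ascii STL supported: ", path)
  vl <- grep("vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  if (nrow(coords) %% 3L != 0L) stop("malformed STL: vertex count not 3n")
  ## merge identical vertices to recover connectivity
  key <- apply(coords, 1, paste, collapse = " ")
  uid <- match(key, unique(key))
  v <- coords[!duplicated(key), , drop = FALSE]
  tri_mesh(v, matrix(uid, ncol = 3, byrow = TRUE))
}

write_stl_ascii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  nrm <- row_cross(V[F[, 2], , drop = FALSE] - a,
                   V[F[, 3], , drop = FALSE] - a)
  len <- pmax(sqrt(rowSums(nrm^2)), .Machine$double.xmin)
  nrm <- nrm / len
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid hullcom", con)
  blk <- sprintf(
    "facet normal %.9g %.9g %.9g\nouter loop\nvertex %.9g %.9g %.9g\nvertex %.9g %.9g %.9g\nvertex %.9g %.9g %.9g\nendloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    V[F[, 1], 1], V[F[, 1], 2], V[F[, 1], 3],
    V[F[, 2], 1], V[F[, 2], 2], V[F[, 2], 3],
    V[F[, 3], 1], V[F[, 3], 2], V[F[, 3], 3])
  writeLines(blk, con)
  writeLines("endsolid hullcom", con)
}
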