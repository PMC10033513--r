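## Body manifests: a YAML file describing, per taxon, the segment mesh
## files, joint centres, locomotor class and status. This is the
## on-disk interface between mesh preparation and the pipeline, and
## the format the fixture writer emits.

#' Read a body manifest
#'
#' @param path Path to a YAML manifest. Each entry of the top-level
#'   `taxa` list has fields `taxon`, `status`, `locomotor_class`,
#'   optional `units` (`m`/`cm`/`mm`, default `m`, applied to meshes
#'   and joint coordinates), optional `hip_reference` and
#'   `sternum_landmarks` (named `cranial`/`caudal`/`keel`), and a
#'   `segments` list with `name`, `side`, optional `skin`/`hull` mesh
#'   paths (relative to the manifest), optional `density`,
#'   `proximal_joint`, `distal_joint`.
#' @return List of [body_model()]s.
#' @export
read_body_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  if (is.null(man$taxa)) stop("manifest has no 'taxa' list: ", path)
  lapply(man$taxa, function(tx) {
    units <- tx$units %||% "m"
    sc <- unit_scale(units)
    segs <- lapply(tx$segments, function(sg) {
      rd <- function(p) if (is.null(p)) NULL
        else read_mesh(file.path(base, p), units = units)
      jt <- function(j) if (is.null(j)) NULL else as.numeric(j) * sc
      body_segment(sg$name, side = sg$side %||% "axial",
                   skin_mesh = rd(sg$skin), skeleton_hull = rd(sg$hull),
                   density = sg$density %||% NA_real_,
                   proximal_joint = jt(sg$proximal_joint),
                   distal_joint = jt(sg$distal_joint))
    })
    lm <- if (!is.null(tx$sternum_landmarks))
      do.call(rbind, lapply(tx$sternum_landmarks, function(v) as.numeric(v) * sc))
    body_model(taxon = tx$taxon, status = tx$status %||% "extant",
               locomotor_class = tx$locomotor_class %||% "HLD",
               segments = segs,
               hip_reference = if (!is.null(tx$hip_reference))
                 as.numeric(tx$hip_reference) * sc,
               sternum_landmarks = lm)
  })
}

#' Write a fixture set to disk
#'
#' Emits exactly what [read_body_manifest()] consumes — OBJ meshes per
#' segment plus `manifest.yaml` — together with the Newick tree, the
#' trait table and the fossils' withheld ground truth in a separate
#' `answers.csv` (kept apart from the pipeline inputs).
#'
#' @param fx A [make_fixture_set()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(fx, dir) {
  dir.create(file.path(dir, "meshes"), recursive = TRUE, showWarnings = FALSE)
  entry <- function(b) {
    segs <- lapply(b$segments, function(s) {
      base <- sprintf("%s_%s_%s", b$taxon, s$name, s$side)
      out <- list(name = s$name, side = s$side)
      if (!is.null(s$skin_mesh)) {
        write_mesh(s$skin_mesh, file.path(dir, "meshes",
                                          paste0(base, "_skin.obj")))
        out$skin <- file.path("meshes", paste0(base, "_skin.obj"))
      }
      if (!is.null(s$skeleton_hull)) {
        write_mesh(s$skeleton_hull, file.path(dir, "meshes",
                                              paste0(base, "_hull.obj")))
        out$hull <- file.path("meshes", paste0(base, "_hull.obj"))
      }
      if (!is.null(s$proximal_joint)) out$proximal_joint <- s$proximal_joint
      if (!is.null(s$distal_joint)) out$distal_joint <- s$distal_joint
      out
    })
    e <- list(taxon = b$taxon, status = b$status,
              locomotor_class = b$locomotor_class, units = "m",
              hip_reference = b$hip_reference, segments = segs)
    if (!is.null(b$sternum_landmarks))
      e$sternum_landmarks <- stats::setNames(
        lapply(seq_len(nrow(b$sternum_landmarks)),
               function(i) as.numeric(b$sternum_landmarks[i, ])),
        rownames(b$sternum_landmarks))
    e
  }
  man <- list(taxa = lapply(c(fx$extant, fx$fossils), entry))
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"), precision = 12)
  writeLines(write_newick(fx$tree), file.path(dir, "tree.nwk"))
  write_csv9(fx$traits, file.path(dir, "traits.csv"))
  write_csv9(fx$answers, file.path(dir, "answers.csv"))
  invisible(dir)
}

## CSV dialect used everywhere: UTF-8, comma, '.' decimal, header row,
## floats at 9 significant digits (stable across platforms, so
## identical runs produce byte-identical files).
write_csv9 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
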