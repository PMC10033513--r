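## Body segments and whole-body aggregation.
##
## Coordinate convention (fixed throughout the package): +x cranial,
## +z dorsal, +y left. The cranio-caudal CoM offset is
## cc_com = com_x - hip_x (positive = cranial to the hip) and the
## dorso-ventral offset is dv_com = hip_z - com_z (positive = ventral
## to the hip). The hip reference is the midpoint of the left and right
## acetabular joint centres.

#' Recognised body segment names
#'
#' The segmentation scheme: axial segments head, neck, torso, tail; the
#' three forelimb segments humerus, forearm, manus; the four hindlimb
#' segments thigh, shank, metatarsus, pes.
#' @export
SEGMENT_NAMES <- c("head", "neck", "torso", "tail",
                   "humerus", "forearm", "manus",
                   "thigh", "shank", "metatarsus", "pes")

#' @rdname SEGMENT_NAMES
#' @export
FORELIMB_SEGMENTS <- c("humerus", "forearm", "manus")

#' @rdname SEGMENT_NAMES
#' @export
HINDLIMB_SEGMENTS <- c("thigh", "shank", "metatarsus", "pes")

PAIRED_SEGMENTS <- c(FORELIMB_SEGMENTS, HINDLIMB_SEGMENTS)

#' Construct a body segment
#'
#' @param name One of [SEGMENT_NAMES].
#' @param side `"left"`, `"right"` or `"axial"` (midline segments).
#' @param skin_mesh Closed [tri_mesh()] of the segment's external (skin)
#'   surface, if available (extant specimens).
#' @param skeleton_hull Closed [tri_mesh()] of the minimum convex hull
#'   around the segment's skeletal elements (always available for
#'   fossils).
#' @param density Segment density, kg m^-3; usually assigned later via
#'   [apply_density_scenario()].
#' @param proximal_joint,distal_joint Joint-centre coordinates (m) used
#'   for segment lengths; optional for head/torso.
#' @return Object of class `body_segment`.
#' @export
body_segment <- function(name, side = "axial", skin_mesh = NULL,
                         skeleton_hull = NULL, density = NA_real_,
                         proximal_joint = NULL, distal_joint = NULL) {
  name <- match.arg(name, SEGMENT_NAMES)
  side <- match.arg(side, c("axial", "left", "right"))
  if (is.null(skin_mesh) && is.null(skeleton_hull))
    stop("segment '", name, "': at least one of skin_mesh/skeleton_hull required")
  if (!is.na(density) && density <= 0)
    stop("segment '", name, "': density must be > 0")
  if (!is.null(skin_mesh) && !is.null(skeleton_hull)) {
    vh <- mass_properties(skeleton_hull, check = FALSE)$volume
    vs <- mass_properties(skin_mesh, check = FALSE)$volume
    if (vh > vs * (1 + 1e-9))
      warning("segment '", name, "': hull volume exceeds skin volume (",
              signif(vh, 4), " > ", signif(vs, 4), ")")
  }
  structure(list(name = name, side = side, skin_mesh = skin_mesh,
                 skeleton_hull = skeleton_hull, density = density,
                 proximal_joint = if (!is.null(proximal_joint)) as.numeric(proximal_joint),
                 distal_joint = if (!is.null(distal_joint)) as.numeric(distal_joint)),
            class = "body_segment")
}

#' Construct a body model
#'
#' A taxon's posed body: its segments, the hip reference point all CoM
#' offsets are measured from, and its locomotor label.
#'
#' @param taxon Taxon name.
#' @param status `"extant"` or `"extinct"`.
#' @param locomotor_class `"HLD"` (hindlimb-dominated, predominantly
#'   terrestrial bird), `"FLD"` (forelimb-dominated, predominantly
#'   volant bird) or `"non-avian sauropsid"`.
#' @param segments List of [body_segment()] objects; names must be
#'   unique per side.
#' @param hip_reference Length-3 point (m). If `NULL`, the midpoint of
#'   the left and right thigh proximal (acetabular) joint centres.
#' @param sternum_landmarks Optional 3 x 3 matrix of labelled sternum
#'   landmarks, rows named `cranial`, `caudal`, `keel`.
#' @return Object of class `body_model`.
#' @export
body_model <- function(taxon, status = c("extant", "extinct"),
                       locomotor_class = c("HLD", "FLD", "non-avian sauropsid"),
                       segments, hip_reference = NULL,
                       sternum_landmarks = NULL) {
  status <- match.arg(status)
  locomotor_class <- match.arg(locomotor_class)
  stopifnot(length(segments) >= 1L,
            all(vapply(segments, inherits, logical(1), "body_segment")))
  ids <- vapply(segments, function(s) paste(s$name, s$side), character(1))
  if (anyDuplicated(ids))
    stop("duplicate segment name/side: ", ids[duplicated(ids)][1])
  if (is.null(hip_reference)) {
    hips <- Filter(function(s) s$name == "thigh" && !is.null(s$proximal_joint),
                   segments)
    if (!length(hips))
      stop("hip_reference not given and no thigh proximal joints to derive it from")
    hip_reference <- colMeans(do.call(rbind, lapply(hips, `[[`, "proximal_joint")))
  }
  hip_reference <- as.numeric(hip_reference)
  if (length(hip_reference) != 3L || any(!is.finite(hip_reference)))
    stop("hip_reference must be a finite 3D point")
  structure(list(taxon = taxon, status = status,
                 locomotor_class = locomotor_class,
                 segments = segments, hip_reference = hip_reference,
                 sternum_landmarks = sternum_landmarks),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("body_model '%s' (%s, %s): %d segments\n", x$taxon, x$status,
              x$locomotor_class, length(x$segments)))
  invisible(x)
}

#' Segment density scenarios
#'
#' The three density schemes applied in sensitivity iterations:
#' \describe{
#'   \item{standard}{1000 kg m^-3 everywhere except the neck
#'     (800 kg m^-3) and torso (850 kg m^-3), which are lightened for
#'     respiratory structures (lungs, air sacs).}
#'   \item{homogeneous}{1000 kg m^-3 in every segment, removing any
#'     investigator choice about density.}
#'   \item{group_varying}{heterogeneous densities that differ by
#'     locomotor group: non-avian sauropsids neck 850 / torso 900,
#'     HLD birds neck 825 / torso 875, FLD birds neck 800 / torso 850,
#'     all other segments 1000 kg m^-3.}
#' }
#' A custom scenario may be built by passing `densities`, a named
#' vector of kg m^-3 keyed by segment name (unnamed element `.default`
#' supplies the fallback).
#'
#' @param name Scenario name.
#' @param densities Optional custom named density vector.
#' @return Object of class `density_scenario`.
#' @export
density_scenario <- function(name = c("standard", "homogeneous",
                                      "group_varying", "custom"),
                             densities = NULL) {
  name <- match.arg(name)
  lookup <- switch(
    name,
    standard = function(seg, class)
      c(neck = 800, torso = 850)[seg] %|na|% 1000,
    homogeneous = function(seg, class) 1000,
    group_varying = function(seg, class) {
      tab <- switch(class,
                    "non-avian sauropsid" = c(neck = 850, torso = 900),
                    "HLD" = c(neck = 825, torso = 875),
                    "FLD" = c(neck = 800, torso = 850),
                    stop("unknown locomotor class: ", class))
      tab[seg] %|na|% 1000
    },
    custom = {
      if (is.null(densities) || is.null(names(densities)))
        stop("custom scenario requires a named 'densities' vector")
      bad <- setdiff(names(densities), c(SEGMENT_NAMES, ".default"))
      if (length(bad))
        stop("unknown segment name(s) in density scenario: ",
             paste(bad, collapse = ", "))
      if (any(densities <= 0)) stop("densities must be > 0")
      function(seg, class) {
        v <- densities[seg]
        if (is.na(v)) v <- densities[".default"]
        if (is.na(v)) stop("density scenario does not resolve segment '",
                           seg, "'")
        unname(v)
      }
    })
  structure(list(name = name, lookup = lookup), class = "density_scenario")
}

`%|na|%` <- function(x, default) {
  x <- unname(x)
  ifelse(is.na(x), default, x)
}

#' Apply a density scenario to a body
#'
#' Pure transformation: returns a copy of the body with every segment's
#' density set from the scenario; the input is untouched.
#'
#' @param body A [body_model()].
#' @param scenario A [density_scenario()].
#' @return A new `body_model`.
#' @export
apply_density_scenario <- function(body, scenario) {
  stopifnot(inherits(body, "body_model"), inherits(scenario, "density_scenario"))
  body$segments <- lapply(body$segments, function(s) {
    s$density <- scenario$lookup(s$name, body$locomotor_class)
    s
  })
  body$density_scenario <- scenario$name
  body
}

## Mirror missing limb sides: fossils are frequently preserved on one
## side only; the missing side is reconstructed by reflection across
## the sagittal plane. Returns the body plus a log of mirrored ids.
mirror_missing_sides <- function(body) {
  mirrored <- character(0)
  for (nm in PAIRED_SEGMENTS) {
    idx <- which(vapply(body$segments, function(s) s$name == nm, logical(1)))
    if (!length(idx)) next
    sides <- vapply(body$segments[idx], `[[`, character(1), "side")
    if (setequal(intersect(sides, c("left", "right")), c("left", "right")))
      next
    one <- intersect(sides, c("left", "right"))
    if (length(one) != 1L) next        # axial-only entry: leave as supplied
    src <- body$segments[[idx[sides == one][1]]]
    dup <- src
    dup$side <- setdiff(c("left", "right"), one)
    if (!is.null(dup$skin_mesh)) dup$skin_mesh <- mirror_mesh(dup$skin_mesh)
    if (!is.null(dup$skeleton_hull))
      dup$skeleton_hull <- mirror_mesh(dup$skeleton_hull)
    mirror_pt <- function(p) if (is.null(p)) NULL else p * c(1, -1, 1)
    dup$proximal_joint <- mirror_pt(dup$proximal_joint)
    dup$distal_joint <- mirror_pt(dup$distal_joint)
    body$segments <- c(body$segments, list(dup))
    mirrored <- c(mirrored, paste(nm, one, "->", dup$side))
  }
  attr(body, "mirrored") <- mirrored
  body
}

segment_mesh <- function(segment, source) {
  switch(source, skin = segment$skin_mesh, hull = segment$skeleton_hull)
}

#' Whole-body mass and centre of mass
#'
#' Aggregates segment mass properties: body mass is the sum of segment
#' masses and the whole-body CoM is the mass-weighted mean of segment
#' CoMs. Offsets are referenced to the hip and normalised by
#' body mass^(1/3) (the dimensional exponent for a length).
#'
#' @param body A [body_model()] with densities assigned.
#' @param source Which geometry to aggregate: `"skin"` (skin volume
#'   meshes) or `"hull"` (skeletal convex hulls, e.g. after expansion).
#' @param iteration_tag Free-form label recording which volume-model x
#'   density-scenario cell produced this result.
#' @param mirror Reconstruct missing limb sides by sagittal reflection
#'   (logged in the result's `mirrored` field).
#' @param check Validate meshes before integrating (disable in inner
#'   loops over generator output, which is validated at build time).
#' @param exponent Mass exponent used for normalisation (default 1/3,
#'   the dimensionally consistent value for a length).
#' @return Object of class `com_result`: `body_mass` (kg),
#'   `com_absolute` (m), `cc_com`, `dv_com` (m), `cc_com_norm`,
#'   `dv_com_norm` (m kg^-1/3), `iteration_tag`, plus a per-segment
#'   breakdown in `$segments`.
#' @export
whole_body_com <- function(body, source = c("skin", "hull"),
                           iteration_tag = source, mirror = TRUE,
                           check = FALSE, exponent = 1 / 3) {
  stopifnot(inherits(body, "body_model"))
  source <- match.arg(source)
  if (mirror) body <- mirror_missing_sides(body)
  missing_mesh <- vapply(body$segments,
                         function(s) is.null(segment_mesh(s, source)),
                         logical(1))
  if (any(missing_mesh))
    stop("segments missing '", source, "' geometry: ",
         paste(vapply(body$segments[missing_mesh],
                      function(s) paste0(s$name, "/", s$side), character(1)),
               collapse = ", "))
  dens <- vapply(body$segments, `[[`, numeric(1), "density")
  if (any(is.na(dens) | dens <= 0))
    stop("segments without a positive density: ",
         paste(vapply(body$segments[is.na(dens) | dens <= 0],
                      `[[`, character(1), "name"), collapse = ", "),
         " (apply a density scenario first)")
  props <- lapply(body$segments, function(s)
    mass_properties(segment_mesh(s, source), s$density, check = check))
  masses <- vapply(props, `[[`, numeric(1), "mass")
  coms <- do.call(rbind, lapply(props, `[[`, "com"))
  body_mass <- sum(masses)
  com <- colSums(coms * masses) / body_mass
  hip <- body$hip_reference
  cc <- com[1] - hip[1]
  dv <- hip[3] - com[3]
  seg_tab <- data.frame(
    name = vapply(body$segments, `[[`, character(1), "name"),
    side = vapply(body$segments, `[[`, character(1), "side"),
    volume = vapply(props, `[[`, numeric(1), "volume"),
    density = dens, mass = masses,
    com_x = coms[, 1], com_y = coms[, 2], com_z = coms[, 3],
    stringsAsFactors = FALSE)
  structure(list(taxon = body$taxon, body_mass = body_mass,
                 com_absolute = as.numeric(com),
                 cc_com = unname(cc), dv_com = unname(dv),
                 cc_com_norm = unname(cc / body_mass^exponent),
                 dv_com_norm = unname(dv / body_mass^exponent),
                 iteration_tag = iteration_tag,
                 mirrored = attr(body, "mirrored") %||% character(0),
                 segments = seg_tab),
            class = "com_result")
}

#' @export
print.com_result <- function(x, ...) {
  cat(sprintf("com_result [%s] '%s'\n", x$iteration_tag, x$taxon))
  cat(sprintf("  body mass %.4g kg; CoM (%.4g, %.4g, %.4g) m\n",
              x$body_mass, x$com_absolute[1], x$com_absolute[2],
              x$com_absolute[3]))
  cat(sprintf("  cc_com %.4g m (norm %.4g), dv_com %.4g m (norm %.4g)\n",
              x$cc_com, x$cc_com_norm, x$dv_com, x$dv_com_norm))
  invisible(x)
}

#' Per-segment summary: lengths, masses, fractions
#'
#' Segment lengths are Euclidean joint-centre to joint-centre distances,
#' normalised by body mass^(1/3); segment masses are reported as
#' fractions of body mass. When the body carries the three sternum
#' landmarks (`cranial`, `caudal`, `keel`), sternum length is the
#' cranial-caudal landmark distance and sternum depth the distance of
#' the keel landmark from the midpoint of the other two.
#'
#' @param body A [body_model()] with densities assigned.
#' @param source Geometry used for masses (see [whole_body_com()]).
#' @param mirror Mirror missing limb sides first.
#' @return A data.frame (one row per segment instance) with columns
#'   `name`, `side`, `length`, `mass`, `length_norm`, `mass_fraction`;
#'   sternum measures and body mass attached as attributes
#'   `sternum_length`, `sternum_depth`, `body_mass`.
#' @export
segment_summary <- function(body, source = c("skin", "hull"), mirror = TRUE) {
  source <- match.arg(source)
  res <- whole_body_com(body, source = source, mirror = mirror)
  if (mirror) body <- mirror_missing_sides(body)
  lens <- vapply(body$segments, function(s) {
    if (is.null(s$proximal_joint) || is.null(s$distal_joint)) {
      warning("segment '", s$name, "/", s$side,
              "': joint centre missing, length omitted")
      return(NA_real_)
    }
    sqrt(sum((s$proximal_joint - s$distal_joint)^2))
  }, numeric(1))
  out <- data.frame(name = res$segments$name, side = res$segments$side,
                    length = lens, mass = res$segments$mass,
                    length_norm = lens / res$body_mass^(1 / 3),
                    mass_fraction = res$segments$mass / res$body_mass,
                    stringsAsFactors = FALSE)
  if (!is.null(body$sternum_landmarks)) {
    lm <- body$sternum_landmarks
    need <- c("cranial", "caudal", "keel")
    if (!all(need %in% rownames(lm)))
      stop("sternum_landmarks must have rows cranial, caudal, keel")
    attr(out, "sternum_length") <- sqrt(sum((lm["cranial", ] - lm["caudal", ])^2))
    attr(out, "sternum_depth") <-
      sqrt(sum((lm["keel", ] - (lm["cranial", ] + lm["caudal", ]) / 2)^2))
  }
  attr(out, "body_mass") <- res$body_mass
  out
}

#' Per-taxon trait table for comparative analyses
#'
#' One row per body: normalised CoM coordinates, log10 body mass and
#' pooled normalised limb/axial lengths — the variables the downstream
#' comparative statistics consume. Pooled lengths sum the chain
#' segments of one side (forelimb = humerus + forearm + manus,
#' hindlimb = thigh + shank + metatarsus + pes).
#'
#' @param bodies List of [body_model()]s.
#' @param scenario Density scenario applied before aggregation.
#' @param source Geometry used ([whole_body_com()]).
#' @param exponent Normalisation mass exponent.
#' @return data.frame keyed by `taxon` with `status`, `group`,
#'   `body_mass`, `log10_mass`, `cc_com_norm`, `dv_com_norm` and
#'   `*_length_norm` columns.
#' @export
compute_trait_table <- function(bodies, scenario = density_scenario("standard"),
                                source = "skin", exponent = 1 / 3) {
  rows <- lapply(bodies, function(b) {
    bd <- apply_density_scenario(b, scenario)
    res <- whole_body_com(bd, source = source,
                          iteration_tag = paste(source, scenario$name, sep = "."),
                          exponent = exponent)
    ss <- segment_summary(bd, source = source)
    pooled_len <- function(set)
      sum(ss$length[ss$name %in% set & ss$side != "right"], na.rm = TRUE)
    norm <- res$body_mass^exponent
    data.frame(
      taxon = b$taxon, status = b$status, group = b$locomotor_class,
      body_mass = res$body_mass, log10_mass = log10(res$body_mass),
      cc_com = res$cc_com, dv_com = res$dv_com,
      cc_com_norm = res$cc_com_norm, dv_com_norm = res$dv_com_norm,
      forelimb_length_norm = pooled_len(FORELIMB_SEGMENTS) / norm,
      hindlimb_length_norm = pooled_len(HINDLIMB_SEGMENTS) / norm,
      tail_length_norm = pooled_len("tail") / norm,
      neck_length_norm = pooled_len("neck") / norm,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$taxon
  out
}
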