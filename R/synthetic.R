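## Synthetic digital taxa: multi-segment bilaterally organised bodies
## built from closed primitives (ellipsoids, capsules, frusta), with
## "skeletons" that are shrunken copies of the skin surface. Shrinking
## the skin by a factor s about the segment CoM makes the minimum
## convex hull of the skeletal points an exact scaled copy of the skin,
## so the hull:skin volume ratio is s^3 exactly -- the quantity the
## hull-expansion method estimates -- while every pipeline stage still
## runs on real meshes. Archetype presets are qualitative caricatures
## (terrestrial birds: long tail and hindlimbs; volant birds: large
## forelimbs and deep sternum), not calibrated to any real species.

#' Archetype body plan
#'
#' Parameterises a posed, bilaterally symmetric body whose hip is at
#' the origin, +x cranial, +z dorsal, +y left. All dimensions scale
#' linearly with `size`.
#'
#' @param archetype `"HLD"` (hindlimb-dominated terrestrial bird),
#'   `"FLD"` (forelimb-dominated volant bird) or
#'   `"non-avian sauropsid"` (long-tailed quadruped-ish outline).
#' @param size Characteristic body length scale in metres (default
#'   0.4; roughly a large-duck-sized bird).
#' @param modifiers Named multipliers applied to segment-group lengths,
#'   e.g. `c(forelimb = 1.2, hindlimb = 0.9, tail = 1.1, neck = 1,
#'   head = 1)`; used to drive proportions from evolved traits.
#' @param shrink Named per-segment skeleton shrink factors s in (0,1);
#'   hull:skin volume ratio is s^3. Defaults span expansion factors
#'   of roughly 1.5 (distal limb) to 2.9 (neck).
#' @return Object of class `body_plan`: per-segment primitive specs.
#' @export
body_plan <- function(archetype = c("HLD", "FLD", "non-avian sauropsid"),
                      size = 0.4, modifiers = NULL, shrink = NULL) {
  archetype <- match.arg(archetype)
  S <- size
  mod <- c(forelimb = 1, hindlimb = 1, tail = 1, neck = 1, head = 1)
  if (!is.null(modifiers)) {
    bad <- setdiff(names(modifiers), names(mod))
    if (length(bad)) stop("unknown modifier(s): ", paste(bad, collapse = ", "))
    mod[names(modifiers)] <- modifiers
  }
  shr <- c(head = 0.78, neck = 0.70, torso = 0.72, tail = 0.75,
           humerus = 0.85, forearm = 0.85, manus = 0.82,
           thigh = 0.82, shank = 0.85, metatarsus = 0.88, pes = 0.85)
  if (!is.null(shrink)) {
    bad <- setdiff(names(shrink), names(shr))
    if (length(bad)) stop("unknown shrink segment(s): ", paste(bad, collapse = ", "))
    if (any(shrink <= 0 | shrink >= 1)) stop("shrink factors must be in (0, 1)")
    shr[names(shrink)] <- shrink
  }
  ## archetype-specific dimensions (fractions of S)
  p <- switch(archetype,
    HLD = list(fl_len = c(0.12, 0.10, 0.07), fl_r = c(0.026, 0.018, 0.012),
               hl_len = c(0.18, 0.22, 0.16, 0.11),
               tail_len = 0.50, tail_r = 0.050, keel_extra = 0.03),
    FLD = list(fl_len = c(0.22, 0.20, 0.16), fl_r = c(0.034, 0.024, 0.016),
               hl_len = c(0.12, 0.15, 0.09, 0.08),
               tail_len = 0.15, tail_r = 0.030, keel_extra = 0.06),
    "non-avian sauropsid" =
          list(fl_len = c(0.14, 0.12, 0.08), fl_r = c(0.028, 0.020, 0.013),
               hl_len = c(0.14, 0.16, 0.10, 0.09),
               tail_len = 0.62, tail_r = 0.058, keel_extra = 0.02))
  hl_r1 <- c(0.045, 0.030, 0.018, 0.020)
  hl_r2 <- c(0.030, 0.020, 0.015, 0.012)
  unit <- function(v) v / sqrt(sum(v^2))

  segs <- list()
  add <- function(name, primitive, args, proximal = NULL, distal = NULL,
                  side = "axial") {
    segs[[length(segs) + 1L]] <<- list(name = name, side = side,
                                       primitive = primitive, args = args,
                                       proximal = proximal, distal = distal,
                                       shrink = unname(shr[name]))
  }

  hipL <- c(0, 0.05 * S, 0.06 * S)      # acetabula dorsal to torso centre
  shoulderL <- c(0.26 * S, 0.06 * S, 0.10 * S)
  ## torso
  add("torso", "ellipsoid",
      list(a = 0.20 * S, b = 0.10 * S, c = 0.12 * S,
           centre = c(0.12 * S, 0, 0.04 * S)),
      proximal = shoulderL * c(1, 0, 1), distal = c(0, 0, 0))
  ## neck + head
  neck_dir <- unit(c(0.8, 0, 0.6))
  neck_len <- 0.25 * S * mod[["neck"]]
  neck_base <- c(0.30 * S, 0, 0.08 * S)
  head_base <- neck_base + neck_len * neck_dir
  add("neck", "capsule",
      list(r = 0.040 * S, length = neck_len,
           centre = neck_base + neck_len / 2 * neck_dir, axis = neck_dir),
      proximal = neck_base, distal = head_base)
  ha <- 0.08 * S * mod[["head"]]
  head_ctr <- head_base + c(ha * 0.8, 0, 0.01 * S)
  add("head", "ellipsoid",
      list(a = ha, b = 0.045 * S, c = 0.05 * S, centre = head_ctr),
      proximal = head_base, distal = head_ctr + c(ha, 0, 0))
  ## tail
  tail_len <- p$tail_len * S * mod[["tail"]]
  tail_base <- c(-0.06 * S, 0, 0.06 * S)
  tail_dir <- c(-1, 0, 0)
  add("tail", "capsule",
      list(r = p$tail_r * S, length = tail_len,
           centre = tail_base + tail_len / 2 * tail_dir, axis = tail_dir),
      proximal = tail_base, distal = tail_base + tail_len * tail_dir)
  ## left forelimb chain (folded caudo-ventrally)
  fl_dirs <- list(unit(c(-1, 0, -0.3)), unit(c(-1, 0, 0.1)), c(-1, 0, 0))
  fl_names <- FORELIMB_SEGMENTS
  pos <- shoulderL
  for (i in 1:3) {
    len <- p$fl_len[i] * S * mod[["forelimb"]]
    nxt <- pos + len * fl_dirs[[i]]
    r1 <- p$fl_r[i] * S
    add(fl_names[i], "frustum",
        list(r1 = r1, r2 = r1 * 0.75, h = len, base = pos,
             axis = fl_dirs[[i]]),
        proximal = pos, distal = nxt, side = "left")
    pos <- nxt
  }
  ## left hindlimb chain
  hl_dirs <- list(unit(c(0.3, 0, -1)), unit(c(-0.15, 0, -1)),
                  unit(c(0.1, 0, -1)), unit(c(1, 0, -0.15)))
  hl_names <- HINDLIMB_SEGMENTS
  pos <- hipL
  for (i in 1:4) {
    len <- p$hl_len[i] * S * mod[["hindlimb"]]
    nxt <- pos + len * hl_dirs[[i]]
    add(hl_names[i], "frustum",
        list(r1 = hl_r1[i] * S, r2 = hl_r2[i] * S, h = len, base = pos,
             axis = hl_dirs[[i]]),
        proximal = pos, distal = nxt, side = "left")
    pos <- nxt
  }
  sternum <- rbind(cranial = c(0.28 * S, 0, -0.06 * S),
                   caudal = c(0.05 * S, 0, -0.08 * S),
                   keel = c(0.17 * S, 0, -(0.10 + p$keel_extra) * S))
  structure(list(archetype = archetype, size = S, segments = segs,
                 hip_left = hipL, hip_right = hipL * c(1, -1, 1),
                 sternum_landmarks = sternum),
            class = "body_plan")
}

build_primitive <- function(spec, resolution) {
  do.call(switch(spec$primitive,
                 ellipsoid = mesh_ellipsoid,
                 capsule = mesh_capsule,
                 frustum = mesh_frustum,
                 stop("unknown primitive: ", spec$primitive)),
          c(spec$args, list(resolution = resolution)))
}

#' Build a digital taxon from a body plan
#'
#' Discretises every segment primitive into a closed mesh, mirrors the
#' limb chains to the right side, derives each segment's skeletal
#' convex hull from the skin surface shrunk about its CoM, and attaches
#' analytic ground truth (smooth-primitive volumes and centroids, and
#' the exact hull:skin ratio per segment).
#'
#' @param plan A [body_plan()].
#' @param taxon Taxon name.
#' @param resolution `"coarse"`, `"medium"` or `"fine"` mesh
#'   resolution. Coarse meshes under-estimate smooth volumes by a few
#'   percent; the hull:skin ratio is exact at any resolution.
#' @param status,locomotor_class Passed to [body_model()]; the class
#'   defaults to the plan archetype.
#' @param shrink_noise_sd SD of log-normal noise applied to each
#'   segment's hull:skin volume ratio (0 = exact ratios).
#' @param seed Seed for the ratio noise.
#' @return A [body_model()] with both geometries per segment and
#'   attribute `ground_truth` (list with per-segment analytic table and
#'   whole-body mass/CoM under unit density 1000).
#' @export
build_body <- function(plan, taxon = "synth", resolution = "coarse",
                       status = "extant", locomotor_class = plan$archetype,
                       shrink_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(plan, "body_plan"))
  noise <- withr_seed(seed, stats::rnorm(length(plan$segments), 0,
                                         shrink_noise_sd))
  segments <- list()
  gt <- list()
  for (i in seq_along(plan$segments)) {
    spec <- plan$segments[[i]]
    skin <- build_primitive(spec, resolution)
    g <- attr(skin, "ground_truth")
    mp <- mass_properties(skin, check = FALSE)
    s_eff <- spec$shrink * exp(noise[i] / 3)
    if (s_eff >= 1) s_eff <- 0.99
    shrunk <- sweep(sweep(skin$vertices, 2, mp$com, "-") * s_eff, 2, mp$com, "+")
    hull <- convex_hull(shrunk)
    seg <- body_segment(spec$name, side = spec$side, skin_mesh = skin,
                        skeleton_hull = hull,
                        proximal_joint = spec$proximal,
                        distal_joint = spec$distal)
    segments[[length(segments) + 1L]] <- seg
    gt[[length(gt) + 1L]] <- data.frame(
      name = spec$name, side = spec$side,
      volume = g$volume, com_x = g$com[1], com_y = g$com[2],
      com_z = g$com[3], mesh_volume = mp$volume,
      discretisation_error = abs(mp$volume - g$volume) / g$volume,
      hull_ratio = s_eff^3, stringsAsFactors = FALSE)
    if (spec$side == "left") {
      segR <- seg
      segR$side <- "right"
      segR$skin_mesh <- mirror_mesh(seg$skin_mesh)
      segR$skeleton_hull <- mirror_mesh(seg$skeleton_hull)
      segR$proximal_joint <- seg$proximal_joint * c(1, -1, 1)
      segR$distal_joint <- seg$distal_joint * c(1, -1, 1)
      segments[[length(segments) + 1L]] <- segR
      gR <- gt[[length(gt)]]
      gR$side <- "right"; gR$com_y <- -gR$com_y
      gt[[length(gt) + 1L]] <- gR
    }
  }
  gt <- do.call(rbind, gt)
  body <- body_model(taxon = taxon, status = status,
                     locomotor_class = locomotor_class,
                     segments = segments,
                     hip_reference = (plan$hip_left + plan$hip_right) / 2,
                     sternum_landmarks = plan$sternum_landmarks)
  ## analytic whole-body ground truth at homogeneous density 1000
  m <- gt$volume * 1000
  com <- colSums(cbind(gt$com_x, gt$com_y, gt$com_z) * m) / sum(m)
  attr(body, "ground_truth") <- list(
    segments = gt,
    body_mass = sum(m),
    com = as.numeric(com),
    max_discretisation_error = max(gt$discretisation_error))
  body
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (per unit time).
#' @param seed Integer seed; reproducible and isolated from the global
#'   RNG stream.
#' @return An `ape` `phylo` object with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  stopifnot(n_tips >= 2)
  tree <- withr_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Simulate Brownian-motion traits on a tree
#'
#' Independent BM per trait: each branch contributes a Gaussian
#' increment with variance `sigma2 * branch length`, accumulated from
#' the root value.
#'
#' @param tree A `phylo` tree.
#' @param sigma2 Named vector of BM rates, one per trait.
#' @param root Root values (recycled).
#' @param seed Integer seed.
#' @param nodes Also return internal-node values (attribute `nodes`).
#' @return data.frame, rows = tips (rownames = tip labels), columns =
#'   traits.
#' @export
simulate_traits <- function(tree, sigma2, root = 0, seed = 1L, nodes = FALSE) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- rep_len(root, length(sigma2))
  ord <- ape::reorder.phylo(tree, "postorder")
  vals <- withr_seed(seed, {
    sapply(seq_along(sigma2), function(j) {
      x <- numeric(ntip + nnode)
      x[ntip + 1L] <- root[j]
      ee <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
      el <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
      for (k in seq_len(nrow(ee)))
        x[ee[k, 2]] <- x[ee[k, 1]] + stats::rnorm(1, 0, sqrt(sigma2[j] * el[k]))
      x
    })
  })
  colnames(vals) <- names(sigma2) %||% paste0("trait", seq_along(sigma2))
  out <- as.data.frame(vals[seq_len(ntip), , drop = FALSE])
  rownames(out) <- tree$tip.label
  if (nodes)
    attr(out, "nodes") <- vals[ntip + seq_len(nnode), , drop = FALSE]
  out
}

#' Simulation configuration for fixture sets
#'
#' @param n_extant,n_fossil Taxon counts (>= 1 each).
#' @param birth_rate Pure-birth rate for the tree.
#' @param bm_rates Named BM rates for the log10 proportion multipliers
#'   (`forelimb`, `hindlimb`, `tail`, `size`).
#' @param ratio_noise_sd SD of log-normal noise on per-segment
#'   hull:skin ratios.
#' @param base_size Archetype body length scale (m).
#' @param resolution Mesh resolution for all bodies.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_extant = 12, n_fossil = 3, birth_rate = 1,
                       bm_rates = c(forelimb = 0.02, hindlimb = 0.01,
                                    tail = 0.02, size = 0.04),
                       ratio_noise_sd = 0.05, base_size = 0.4,
                       resolution = "coarse", seed = 1L) {
  stopifnot(n_extant >= 1, n_fossil >= 1, !is.null(seed))
  structure(list(n_extant = n_extant, n_fossil = n_fossil,
                 birth_rate = birth_rate, bm_rates = bm_rates,
                 ratio_noise_sd = ratio_noise_sd, base_size = base_size,
                 resolution = resolution, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a complete fixture set
#'
#' Produces everything a pipeline run needs: extant training bodies
#' with both geometries, fossil bodies with skeletal hulls only, the
#' phylogeny, a trait table, and a separate answers table holding the
#' fossils' withheld ground truth (their true skin-volume CoM under the
#' standard density scenario).
#'
#' Extant taxa cycle through the three archetypes
#' (non-avian sauropsid, HLD, FLD); fossils use the non-avian
#' sauropsid archetype. Segment proportions are driven by BM-evolved
#' log10 multipliers so related taxa have related shapes.
#'
#' @param config A [sim_config()].
#' @return List with `extant` (body models), `fossils` (hull-only body
#'   models), `tree` (`phylo`), `traits` (data.frame keyed by taxon),
#'   `answers` (data.frame of fossil ground truth).
#' @export
make_fixture_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_extant + config$n_fossil
  tree <- simulate_tree(n, config$birth_rate, seed = config$seed)
  lp <- simulate_traits(tree, config$bm_rates, seed = config$seed + 1L)
  classes <- c(rep(c("non-avian sauropsid", "HLD", "FLD"),
                   length.out = config$n_extant),
               rep("non-avian sauropsid", config$n_fossil))
  status <- rep(c("extant", "extinct"), c(config$n_extant, config$n_fossil))
  clip <- function(x, lim = 0.25) pmin(pmax(x, -lim), lim)
  bodies <- vector("list", n)
  for (i in seq_len(n)) {
    tip <- tree$tip.label[i]
    plan <- body_plan(classes[i],
                      size = config$base_size * 10^clip(lp$size[i]),
                      modifiers = c(forelimb = 10^clip(lp$forelimb[i]),
                                    hindlimb = 10^clip(lp$hindlimb[i]),
                                    tail = 10^clip(lp$tail[i])))
    bodies[[i]] <- build_body(plan, taxon = tip,
                              resolution = config$resolution,
                              status = status[i], locomotor_class = classes[i],
                              shrink_noise_sd = config$ratio_noise_sd,
                              seed = config$seed + 100L + i)
  }
  traits <- compute_trait_table(bodies, density_scenario("standard"))
  fossil_rows <- traits[traits$status == "extinct", ]
  answers <- data.frame(taxon = fossil_rows$taxon,
                        true_body_mass = fossil_rows$body_mass,
                        true_cc_com_norm = fossil_rows$cc_com_norm,
                        true_dv_com_norm = fossil_rows$dv_com_norm,
                        stringsAsFactors = FALSE)
  fossils <- lapply(bodies[status == "extinct"], function(b) {
    b$segments <- lapply(b$segments, function(s) { s$skin_mesh <- NULL; s })
    attr(b, "ground_truth") <- NULL
    b
  })
  list(extant = bodies[status == "extant"], fossils = fossils,
       tree = tree, traits = traits, answers = answers)
}
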