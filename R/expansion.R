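## Segment-specific minimum-convex-hull (MCH) expansion: fit the
## hull-to-skin volume relationship per body segment on extant taxa
## with both geometries, then inflate fossil segment hulls to predicted
## skin volumes. Expansion is isotropic about each segment hull's own
## CoM, so a segment's CoM is invariant to its expansion and no
## directional shift is injected.

## Pooled per-taxon, per-segment volumes (left + right limb volumes
## pooled before ratio computation).
pooled_volumes <- function(body, source) {
  vols <- list()
  for (s in body$segments) {
    m <- segment_mesh(s, source)
    if (is.null(m)) next
    v <- mass_properties(m, check = FALSE)$volume
    vols[[s$name]] <- (vols[[s$name]] %||% 0) + v
  }
  vols
}

scope_filter <- function(bodies, scope) {
  keep <- switch(scope,
                 all_taxa = rep(TRUE, length(bodies)),
                 birds_only = vapply(bodies, function(b)
                   b$locomotor_class %in% c("HLD", "FLD"), logical(1)),
                 non_avian_only = vapply(bodies, function(b)
                   b$locomotor_class == "non-avian sauropsid", logical(1)))
  bodies[keep]
}

#' Fit per-segment hull-to-skin expansion models
#'
#' Three predictive model classes, fitted per body segment on a set of
#' training bodies carrying both the skeletal convex hull and the true
#' skin volume:
#' \describe{
#'   \item{mean_ratio}{arithmetic mean over taxa of the per-taxon
#'     skin:hull volume ratio (the raw expansion factor).}
#'   \item{ols_loglog}{ordinary least squares of
#'     `log10(skin) = a + b log10(hull)` (allometric form).}
#'   \item{pgls_loglog}{the same regression fitted by phylogenetic GLS
#'     under a Brownian-motion correlation structure on `tree`.}
#' }
#' Left and right limb volumes are pooled per taxon before the ratio or
#' regression is computed.
#'
#' @param training List of [body_model()]s with both geometries.
#' @param method Model class (above).
#' @param scope Training-set filter by locomotor class: `all_taxa`,
#'   `birds_only` (HLD + FLD), or `non_avian_only`.
#' @param tree Required for `pgls_loglog`; taxa absent from the tree
#'   are dropped with a warning.
#' @return Object of class `expansion_model` with a per-segment
#'   parameter table (`k` or `a`,`b`, plus `n` and residual/ratio SE).
#' @export
fit_expansion_models <- function(training,
                                 method = c("mean_ratio", "ols_loglog",
                                            "pgls_loglog"),
                                 scope = c("all_taxa", "birds_only",
                                           "non_avian_only"),
                                 tree = NULL) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  training <- scope_filter(training, scope)
  if (!length(training))
    stop("no training taxa left after applying scope '", scope, "'")
  taxa <- vapply(training, `[[`, character(1), "taxon")
  hull <- lapply(training, pooled_volumes, source = "hull")
  skin <- lapply(training, pooled_volumes, source = "skin")
  segs <- unique(unlist(lapply(hull, names)))
  rows <- list(); unfittable <- character(0)
  for (sg in segs) {
    hv <- vapply(hull, function(v) v[[sg]] %||% NA_real_, numeric(1))
    sv <- vapply(skin, function(v) v[[sg]] %||% NA_real_, numeric(1))
    ok <- is.finite(hv) & is.finite(sv) & hv > 0 & sv > 0
    if (sum(ok) < 3L) { unfittable <- c(unfittable, sg); next }
    tx <- taxa[ok]; hv <- hv[ok]; sv <- sv[ok]
    if (method == "mean_ratio") {
      r <- sv / hv
      rows[[sg]] <- data.frame(segment = sg, k = mean(r), a = NA_real_,
                               b = NA_real_, b_se = NA_real_, n = length(r),
                               se = stats::sd(r) / sqrt(length(r)))
    } else {
      x <- log10(hv); y <- log10(sv)
      if (method == "ols_loglog") {
        fit <- stats::lm(y ~ x)
        cf <- stats::coef(fit)
        b_se <- summary(fit)$coefficients[2, 2]
        se <- summary(fit)$sigma
      } else {
        if (is.null(tree)) stop("pgls_loglog requires a tree")
        common <- intersect(tx, tree$tip.label)
        if (length(common) < length(tx))
          warning("segment '", sg, "': ", length(tx) - length(common),
                  " training taxa absent from tree, dropped")
        if (length(common) < 3L) { unfittable <- c(unfittable, sg); next }
        i <- match(common, tx)
        fit <- pgls(y[i], cbind(1, x[i]), ape::keep.tip(tree, common),
                    taxa = common)
        cf <- fit$coefficients
        b_se <- unname(fit$se[2])
        se <- sqrt(fit$sigma2)
      }
      rows[[sg]] <- data.frame(segment = sg, k = NA_real_,
                               a = unname(cf[1]), b = unname(cf[2]),
                               b_se = b_se, n = length(hv), se = se)
    }
    if (method == "mean_ratio" && rows[[sg]]$k <= 1)
      warning("segment '", sg, "': mean expansion factor ",
              signif(rows[[sg]]$k, 4),
              " <= 1 (skin should enclose the skeleton)")
  }
  if (length(unfittable))
    stop("segments with < 3 usable training taxa: ",
         paste(unfittable, collapse = ", "))
  structure(list(method = method, scope = scope,
                 table = do.call(rbind, rows)),
            class = "expansion_model")
}

#' @export
print.expansion_model <- function(x, ...) {
  cat(sprintf("expansion_model (%s, %s): %d segments\n", x$method, x$scope,
              nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict a segment's skin volume from its hull volume
#'
#' `mean_ratio` models multiply by the segment's mean expansion factor
#' k; regression models evaluate `10^(a + b log10(hull))`. Strictly
#' monotone in `hull_volume` for positive slopes.
#'
#' @param hull_volume Hull volume(s), m^3.
#' @param segment Segment name.
#' @param model An [fit_expansion_models()] result.
#' @param correct_bias Apply the log-normal back-transform (smearing)
#'   correction `exp((s ln 10)^2 / 2)` to regression predictions,
#'   where s is the residual SE of the log10 fit. Off by default: the
#'   uncorrected form predicts the median response, the conventional
#'   choice in allometric volume reconstruction.
#' @return Predicted skin volume(s), m^3.
#' @export
predict_skin_volume <- function(hull_volume, segment, model,
                                correct_bias = FALSE) {
  stopifnot(inherits(model, "expansion_model"), all(hull_volume > 0))
  row <- model$table[model$table$segment == segment, ]
  if (nrow(row) != 1L)
    stop("segment '", segment, "' absent from expansion model")
  if (model$method == "mean_ratio") return(row$k * hull_volume)
  pred <- 10^(row$a + row$b * log10(hull_volume))
  if (correct_bias) pred <- pred * exp((row$se * log(10))^2 / 2)
  pred
}

## Expand every segment hull of `body` to its predicted skin volume
## (isotropic, about the hull's own CoM). Paired segments are pooled
## for prediction and the pooled prediction is split across sides in
## proportion to each side's hull volume.
expand_body_hulls <- function(body, model, target_volumes = NULL) {
  pooled <- pooled_volumes(body, "hull")
  for (i in seq_along(body$segments)) {
    s <- body$segments[[i]]
    if (is.null(s$skeleton_hull))
      stop("segment '", s$name, "/", s$side, "' has no skeleton hull")
    v <- mass_properties(s$skeleton_hull, check = FALSE)$volume
    pool <- pooled[[s$name]]
    pred_pool <- if (!is.null(target_volumes)) target_volumes[[s$name]]
                 else predict_skin_volume(pool, s$name, model)
    if (is.null(pred_pool))
      stop("no target volume for segment '", s$name, "'")
    body$segments[[i]]$skeleton_hull <-
      scale_to_volume(s$skeleton_hull, pred_pool * v / pool, check = FALSE)
  }
  body
}

#' Reconstruct a fossil taxon over the volume-model x density grid
#'
#' For every combination of expansion model and density scenario, each
#' segment hull is inflated to its predicted skin volume, the scenario
#' densities are applied, and whole-body mass and CoM are aggregated.
#' With 4 volume models and 3 density scenarios this yields the
#' standard 12 reconstruction iterations per taxon.
#'
#' @param fossil A [body_model()] with skeletal hulls (skin meshes are
#'   ignored if present).
#' @param volume_models Named list of [fit_expansion_models()] results.
#' @param density_scenarios Named list of [density_scenario()]s.
#' @return Object of class `reconstruction_grid`: `results` (list of
#'   `com_result`, tagged `<model>.<scenario>`), `skipped` (data.frame
#'   of skipped cells with reasons).
#' @export
reconstruct_taxon <- function(fossil, volume_models, density_scenarios) {
  stopifnot(inherits(fossil, "body_model"),
            length(volume_models) >= 1L, length(density_scenarios) >= 1L)
  if (is.null(names(volume_models)))
    names(volume_models) <- paste0("vm", seq_along(volume_models))
  if (is.null(names(density_scenarios)))
    names(density_scenarios) <- vapply(density_scenarios, `[[`,
                                       character(1), "name")
  fossil <- mirror_missing_sides(fossil)
  results <- list()
  skipped <- NULL
  for (vm in names(volume_models)) {
    expanded <- tryCatch(expand_body_hulls(fossil, volume_models[[vm]]),
                         error = function(e) e)
    for (ds in names(density_scenarios)) {
      tag <- paste(vm, ds, sep = ".")
      if (inherits(expanded, "error")) {
        skipped <- rbind(skipped, data.frame(
          taxon = fossil$taxon, cell = tag,
          reason = conditionMessage(expanded), stringsAsFactors = FALSE))
        next
      }
      body <- apply_density_scenario(expanded, density_scenarios[[ds]])
      results[[tag]] <- whole_body_com(body, source = "hull",
                                       iteration_tag = tag, mirror = FALSE)
    }
  }
  if (!length(results))
    stop("reconstruction of '", fossil$taxon, "' produced no grid cells: ",
         paste(unique(skipped$reason), collapse = "; "))
  structure(list(taxon = fossil$taxon, results = results, skipped = skipped),
            class = "reconstruction_grid")
}

#' @export
print.reconstruction_grid <- function(x, ...) {
  cat(sprintf("reconstruction_grid '%s': %d cells (%d skipped)\n", x$taxon,
              length(x$results), NROW(x$skipped)))
  invisible(x)
}

#' Flatten reconstruction results to a table
#'
#' @param x A `reconstruction_grid` (or list of them).
#' @param ... Unused.
#' @return data.frame with one row per grid cell.
#' @export
as.data.frame.reconstruction_grid <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r)
    data.frame(taxon = r$taxon, iteration_tag = r$iteration_tag,
               body_mass = r$body_mass,
               com_x = r$com_absolute[1], com_y = r$com_absolute[2],
               com_z = r$com_absolute[3],
               cc_com = r$cc_com, dv_com = r$dv_com,
               cc_com_norm = r$cc_com_norm, dv_com_norm = r$dv_com_norm,
               stringsAsFactors = FALSE)))
}

#' Validate expansion models against extant taxa
#'
#' Three validation modes:
#' \describe{
#'   \item{apply_to_self}{reconstruct each extant taxon from its hulls
#'     with the supplied model and compare to its true skin-volume
#'     CoM.}
#'   \item{leave_one_out}{as above, but the model is refitted without
#'     the focal taxon before predicting it.}
#'   \item{equal_volume_hull}{inflate each hull to the TRUE skin volume
#'     of its segment, isolating the pure hull-shape error from the
#'     volume-prediction error.}
#' }
#' Predicted and true CoM are both computed under the same density
#' scenario so errors reflect geometry, not density choices.
#'
#' @param model An [fit_expansion_models()] result (ignored for
#'   `equal_volume_hull`).
#' @param extant List of [body_model()]s with both geometries.
#' @param mode Validation mode.
#' @param tree,scenario Tree for refits (leave-one-out pGLS) and the
#'   density scenario applied to both pipelines.
#' @return data.frame of class `validation_report`: per taxon true and
#'   predicted body mass, `cc_com_norm`, `dv_com_norm` and their errors
#'   (predicted - true).
#' @export
validate_on_extant <- function(model, extant,
                               mode = c("apply_to_self", "leave_one_out",
                                        "equal_volume_hull"),
                               tree = NULL,
                               scenario = density_scenario("standard")) {
  mode <- match.arg(mode)
  if (mode == "leave_one_out" && length(extant) < 4L)
    stop("leave_one_out needs at least 4 training taxa")
  rows <- lapply(extant, function(b) {
    truth <- whole_body_com(apply_density_scenario(b, scenario), "skin",
                            iteration_tag = "truth")
    recon <- switch(mode,
      apply_to_self = expand_body_hulls(b, model),
      leave_one_out = {
        rest <- Filter(function(o) o$taxon != b$taxon, extant)
        m <- fit_expansion_models(rest, method = model$method,
                                  scope = model$scope, tree = tree)
        expand_body_hulls(b, m)
      },
      equal_volume_hull = expand_body_hulls(
        b, model = NULL, target_volumes = pooled_volumes(b, "skin")))
    pred <- whole_body_com(apply_density_scenario(recon, scenario), "hull",
                           iteration_tag = mode)
    data.frame(taxon = b$taxon, mode = mode,
               model = if (mode == "equal_volume_hull") "equal_volume"
                       else paste(model$method, model$scope, sep = "."),
               true_mass = truth$body_mass, pred_mass = pred$body_mass,
               true_cc_norm = truth$cc_com_norm,
               pred_cc_norm = pred$cc_com_norm,
               true_dv_norm = truth$dv_com_norm,
               pred_dv_norm = pred$dv_com_norm,
               mass_error = pred$body_mass - truth$body_mass,
               cc_error = pred$cc_com_norm - truth$cc_com_norm,
               dv_error = pred$dv_com_norm - truth$dv_com_norm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", class(out))
  out
}

#' Serialise expansion models to JSON
#'
#' @param model An `expansion_model`.
#' @param path Output (input) file path.
#' @return `read_expansion_model` returns the model; the writer the
#'   path, invisibly.
#' @export
write_expansion_model <- function(model, path) {
  stopifnot(inherits(model, "expansion_model"))
  jsonlite::write_json(list(method = model$method, scope = model$scope,
                            table = model$table),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_expansion_model
#' @export
read_expansion_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$table <- as.data.frame(x$table)
  for (cc in c("k", "a", "b", "b_se", "se"))
    x$table[[cc]] <- as.numeric(x$table[[cc]])
  structure(list(method = x$method, scope = x$scope, table = x$table),
            class = "expansion_model")
}
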