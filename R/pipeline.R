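## End-to-end orchestration: bodies -> CoM tables -> expansion fits ->
## fossil reconstruction grid -> comparative statistics, from a single
## seeded configuration. One master seed; per-stage seeds are derived
## from it by fixed offsets and recorded in the run log.

#' Pipeline configuration
#'
#' @param fixtures A [sim_config()] to generate inputs, or `NULL` when
#'   reading from disk.
#' @param manifest,tree_file Paths to a body manifest
#'   ([read_body_manifest()]) and Newick tree; used when `fixtures` is
#'   `NULL`.
#' @param density_scenarios Character vector of scenario names.
#' @param volume_models Named list; each element
#'   `list(method =, scope =)`. The default grid is the standard four:
#'   all-taxa, birds-only and non-avian-only allometric equations plus
#'   the all-taxa mean expansion factor.
#' @param stats_volume_model Which volume model feeds fossil rows of
#'   the statistical trait table (default the mean-ratio model, the
#'   iteration least sensitive to extrapolation beyond the training
#'   body-size range).
#' @param norm_exponent Mass exponent for normalisation (default 1/3).
#' @param response_traits,extra_traits Trait columns analysed.
#' @param compare_groups The two locomotor groups contrasted by the
#'   pANOVAs.
#' @param covariate Covariate column for allometry and slope tests.
#' @param isometric_slope Expected slope under isometry.
#' @param n_perm Permutations for pANOVA/phylANCOVA.
#' @param correlation `"BM"` or `"lambda"` for pGLS fits.
#' @param drop_taxa Named list of taxon vectors; each entry triggers a
#'   sensitivity rerun without those taxa, written to a suffixed
#'   subdirectory.
#' @param seed Master seed (mandatory).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fixtures = NULL, manifest = NULL,
                            tree_file = NULL,
                            density_scenarios = c("standard", "homogeneous",
                                                  "group_varying"),
                            volume_models = list(
                              eq_all = list(method = "ols_loglog",
                                            scope = "all_taxa"),
                              eq_birds = list(method = "ols_loglog",
                                              scope = "birds_only"),
                              eq_nonavian = list(method = "ols_loglog",
                                                 scope = "non_avian_only"),
                              ratio_all = list(method = "mean_ratio",
                                               scope = "all_taxa")),
                            stats_volume_model = "ratio_all",
                            norm_exponent = 1 / 3,
                            response_traits = c("cc_com_norm", "dv_com_norm"),
                            extra_traits = c("forelimb_length_norm",
                                             "hindlimb_length_norm",
                                             "tail_length_norm",
                                             "neck_length_norm"),
                            compare_groups = c("HLD", "FLD"),
                            covariate = "log10_mass",
                            isometric_slope = 1 / 3,
                            n_perm = 999, correlation = "BM",
                            drop_taxa = list(), seed = 1L) {
  if (is.null(fixtures) && (is.null(manifest) || is.null(tree_file)))
    stop("either `fixtures` or both `manifest` and `tree_file` are required")
  if (is.null(seed)) stop("a seed is mandatory")
  if (!stats_volume_model %in% names(volume_models))
    stop("stats_volume_model '", stats_volume_model,
         "' is not one of the volume models")
  structure(list(fixtures = fixtures, manifest = manifest,
                 tree_file = tree_file,
                 density_scenarios = density_scenarios,
                 volume_models = volume_models,
                 stats_volume_model = stats_volume_model,
                 norm_exponent = norm_exponent,
                 response_traits = response_traits,
                 extra_traits = extra_traits,
                 compare_groups = compare_groups, covariate = covariate,
                 isometric_slope = isometric_slope, n_perm = n_perm,
                 correlation = correlation, drop_taxa = drop_taxa,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes the numbered output tables to
#' `out_dir`: (01) per-taxon CoM table across density scenarios,
#' (02) expansion-model JSON per volume model, (03) fossil
#' reconstruction grid, (04) ancestral states, (05) pGLS/allometry
#' table, (06) pANOVA/phylANCOVA table, (07) phylogenetic PCA scores
#' and loadings, (08) phylomorphospace coordinates, (09) Spearman
#' matrices for tips and for nodes, (10) extant validation report,
#' plus the effective configuration and a run log (seed, versions,
#' stage timings). `drop_taxa` entries rerun the whole pipeline
#' without the listed taxa into `rerun_<name>/` subdirectories.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("hullcom pipeline run, seed %d", config$seed),
                 sprintf("R %s; hullcom %s", getRversion(),
                         tryCatch(as.character(utils::packageVersion("hullcom")),
                                  error = function(e) "dev")),
                 sprintf("started %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-16s %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    r
  }

  inputs <- t_stage("load_inputs", {
    if (!is.null(config$fixtures)) {
      fx <- make_fixture_set(config$fixtures)
      list(extant = fx$extant, fossils = fx$fossils, tree = fx$tree)
    } else {
      bodies <- read_body_manifest(config$manifest)
      status <- vapply(bodies, `[[`, character(1), "status")
      list(extant = bodies[status == "extant"],
           fossils = bodies[status == "extinct"],
           tree = read_newick(config$tree_file))
    }
  })
  run_pipeline_once(config, inputs, out_dir, log_lines)
  for (nm in names(config$drop_taxa)) {
    drop <- config$drop_taxa[[nm]]
    sub <- file.path(out_dir, paste0("rerun_", nm))
    dir.create(sub, showWarnings = FALSE)
    pruned <- list(
      extant = Filter(function(b) !(b$taxon %in% drop), inputs$extant),
      fossils = Filter(function(b) !(b$taxon %in% drop), inputs$fossils),
      tree = ape::drop.tip(inputs$tree, intersect(drop,
                                                  inputs$tree$tip.label)))
    run_pipeline_once(config, pruned, sub,
                      c(log_lines, sprintf("rerun without: %s",
                                           paste(drop, collapse = ", "))))
  }
  invisible(out_dir)
}

run_pipeline_once <- function(config, inputs, out_dir, log_lines) {
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-16s %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    r
  }
  extant <- inputs$extant; fossils <- inputs$fossils; tree <- inputs$tree
  scen <- lapply(stats::setNames(nm = config$density_scenarios),
                 density_scenario)
  expnt <- config$norm_exponent

  ## (01) per-taxon CoM across density scenarios
  com_tab <- t_stage("com_table", {
    rows <- list()
    for (b in extant) for (sn in names(scen)) {
      r <- whole_body_com(apply_density_scenario(b, scen[[sn]]), "skin",
                          iteration_tag = paste("skin", sn, sep = "."),
                          exponent = expnt)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = r$taxon, group = b$locomotor_class,
        iteration_tag = r$iteration_tag, body_mass = r$body_mass,
        cc_com = r$cc_com, dv_com = r$dv_com,
        cc_com_norm = r$cc_com_norm, dv_com_norm = r$dv_com_norm,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  write_csv9(com_tab, file.path(out_dir, "01_com_table.csv"))

  ## (02) expansion fits
  models <- t_stage("expansion_fit", {
    lapply(config$volume_models, function(vm)
      fit_expansion_models(extant, method = vm$method, scope = vm$scope,
                           tree = tree))
  })
  for (nm in names(models))
    write_expansion_model(models[[nm]],
                          file.path(out_dir, sprintf("02_expansion_%s.json", nm)))

  ## (03) fossil reconstruction grid
  grid_tab <- t_stage("reconstruction", {
    if (!length(fossils)) NULL
    else do.call(rbind, lapply(fossils, function(f)
      as.data.frame(reconstruct_taxon(f, models, scen))))
  })
  write_csv9(grid_tab %||%
               data.frame(taxon = character(0), iteration_tag = character(0)),
             file.path(out_dir, "03_reconstruction_grid.csv"))

  ## statistical trait table: extant truth + fossils under the stats
  ## volume model and the standard density scenario
  traits <- t_stage("trait_table", {
    tt <- compute_trait_table(extant, density_scenario("standard"),
                              exponent = expnt)
    if (length(fossils)) {
      fm <- models[[config$stats_volume_model]]
      ft <- compute_trait_table(
        lapply(fossils, expand_body_hulls, model = fm),
        density_scenario("standard"), source = "hull", exponent = expnt)
      tt <- rbind(tt, ft)
    }
    tt
  })
  stats_traits <- c(config$response_traits, config$extra_traits)
  X <- as.matrix(traits[, stats_traits])
  rownames(X) <- traits$taxon

  ## (04) ancestral states for all analysed traits
  anc <- t_stage("ancestral_states", ancestral_states_bm(tree, X))
  write_csv9(anc, file.path(out_dir, "04_ancestral_states.csv"))

  ## (05) pGLS allometry per response x bird grouping. Scaling is
  ## assessed on log10 of the raw hip-referenced offsets against log10
  ## body mass, so isometry corresponds to a slope of 1/3; taxa whose
  ## offset is on the wrong side of the hip (non-positive) cannot enter
  ## a log-log fit and are dropped.
  allo <- t_stage("pgls_allometry", {
    rows <- list()
    subsets <- list(all_birds = config$compare_groups)
    for (g in config$compare_groups) subsets[[g]] <- g
    raw_responses <- sub("_norm$", "", config$response_traits)
    for (resp in raw_responses) for (sn in names(subsets)) {
      keep <- traits$group %in% subsets[[sn]] & traits[[resp]] > 0
      if (sum(keep) < 4) next
      tx <- traits$taxon[keep]
      y <- stats::setNames(log10(traits[[resp]][keep]), tx)
      xv <- traits[[config$covariate]][keep]
      fit <- suppressWarnings(
        pgls(y, cbind(`(Intercept)` = 1, slope = xv), tree,
             correlation = config$correlation))
      cls <- allometry_classify(fit, config$isometric_slope, "slope")
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, subset = sn, n = fit$n,
        slope = cls$slope, ci_lower = cls$ci[["lower"]],
        ci_upper = cls$ci[["upper"]], sigma2 = fit$sigma2,
        logLik = fit$logLik, AICc = fit$AICc,
        correlation = fit$correlation,
        allometry = cls$classification, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  write_csv9(allo, file.path(out_dir, "05_pgls_allometry.csv"))

  ## (06) pANOVA / phylANCOVA between the two locomotor groups
  panova <- t_stage("panova", {
    keep <- traits$group %in% config$compare_groups
    tx <- traits$taxon[keep]
    gr <- stats::setNames(traits$group[keep], tx)
    cv <- stats::setNames(traits[[config$covariate]][keep], tx)
    rows <- list()
    for (j in seq_along(stats_traits)) {
      tr <- stats_traits[j]
      y <- stats::setNames(traits[[tr]][keep], tx)
      r <- suppressWarnings(
        phylo_anova(y, gr, tree, n_perm = config$n_perm,
                    seed = config$seed + 200L + j))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, test = "group", F = r$statistic, p = r$p,
        n_perm = r$n_perm, seed = r$seed, stringsAsFactors = FALSE)
    }
    for (j in seq_along(config$response_traits)) {
      tr <- config$response_traits[j]
      y <- stats::setNames(traits[[tr]][keep], tx)
      r <- suppressWarnings(
        phylo_anova(y, gr, tree, n_perm = config$n_perm,
                    seed = config$seed + 300L + j,
                    covariate = cv, test = "slopes"))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, test = "slopes", F = r$statistic, p = r$p,
        n_perm = r$n_perm, seed = r$seed, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  write_csv9(panova, file.path(out_dir, "06_panova.csv"))

  ## (07) phylogenetic PCA with node projection
  ppca <- t_stage("phylo_pca",
                  suppressWarnings(phylo_pca(X, tree, project_nodes = TRUE)))
  sc <- rbind(data.frame(id = rownames(ppca$scores), type = "tip",
                         as.data.frame(ppca$scores)),
              data.frame(id = rownames(ppca$node_scores), type = "node",
                         as.data.frame(ppca$node_scores)))
  write_csv9(sc, file.path(out_dir, "07_ppca_scores.csv"))
  write_csv9(data.frame(trait = rownames(ppca$loadings),
                        as.data.frame(ppca$loadings),
                        stringsAsFactors = FALSE),
             file.path(out_dir, "07_ppca_loadings.csv"))
  write_csv9(data.frame(PC = colnames(ppca$loadings),
                        eigenvalue = ppca$eigenvalues,
                        percent_variance = ppca$percent_variance),
             file.path(out_dir, "07_ppca_eigen.csv"))

  ## (08) CoM phylomorphospace
  pms <- t_stage("phylomorphospace", {
    phylomorphospace_coords(
      tree,
      stats::setNames(traits[[config$response_traits[1]]], traits$taxon),
      stats::setNames(traits[[config$response_traits[2]]], traits$taxon))
  })
  pms_tab <- rbind(
    data.frame(type = "tip", id = pms$tips$taxon, x = pms$tips$x,
               y = pms$tips$y, x_ci_lower = NA_real_, x_ci_upper = NA_real_,
               y_ci_lower = NA_real_, y_ci_upper = NA_real_),
    data.frame(type = "node", id = as.character(pms$nodes$node),
               x = pms$nodes$x, y = pms$nodes$y,
               x_ci_lower = pms$nodes$x_ci_lower,
               x_ci_upper = pms$nodes$x_ci_upper,
               y_ci_lower = pms$nodes$y_ci_lower,
               y_ci_upper = pms$nodes$y_ci_upper))
  write_csv9(pms_tab, file.path(out_dir, "08_phylomorphospace.csv"))
  write_csv9(pms$edges, file.path(out_dir, "08_phylomorphospace_edges.csv"))

  ## (09) Spearman matrices: tips and ancestral nodes separately
  t_stage("spearman", {
    sm_tips <- spearman_matrix(X)
    nodeX <- do.call(cbind, lapply(stats_traits, function(tr)
      anc$estimate[anc$trait == tr]))
    colnames(nodeX) <- stats_traits
    sm_nodes <- spearman_matrix(nodeX)
    flat <- function(sm, which) data.frame(
      trait = rownames(sm[[which]]), as.data.frame(sm[[which]]),
      stringsAsFactors = FALSE)
    write_csv9(flat(sm_tips, "rho"), file.path(out_dir, "09_spearman_tips_rho.csv"))
    write_csv9(flat(sm_tips, "p"), file.path(out_dir, "09_spearman_tips_p.csv"))
    write_csv9(flat(sm_nodes, "rho"), file.path(out_dir, "09_spearman_nodes_rho.csv"))
    write_csv9(flat(sm_nodes, "p"), file.path(out_dir, "09_spearman_nodes_p.csv"))
  })

  ## (10) extant validation
  val <- t_stage("validation", {
    v1 <- do.call(rbind, lapply(names(models), function(nm)
      validate_on_extant(models[[nm]], extant, mode = "apply_to_self")))
    v2 <- validate_on_extant(NULL, extant, mode = "equal_volume_hull")
    rbind(v1, v2)
  })
  write_csv9(as.data.frame(val), file.path(out_dir, "10_validation.csv"))

  ## effective config + run log
  cfg_out <- config
  cfg_out$fixtures <- if (!is.null(config$fixtures)) unclass(config$fixtures)
  yaml::write_yaml(unclass(cfg_out), file.path(out_dir, "effective_config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Summarise a pipeline results directory
#'
#' Writes `report.md`: the group contrasts, allometry classifications,
#' and per-fossil reconstruction ranges (min/median/max normalised
#' cranio-caudal CoM across the grid iterations), noting for each
#' fossil whether its median falls inside the extant HLD or FLD range.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @return Path to the report, invisibly.
#' @export
summarise_results <- function(out_dir) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  com <- rd("01_com_table.csv")
  grid <- rd("03_reconstruction_grid.csv")
  allo <- rd("05_pgls_allometry.csv")
  pan <- rd("06_panova.csv")
  lines <- c("# Pipeline summary", "")
  if (!is.null(pan) && nrow(pan)) {
    lines <- c(lines, "## Group contrasts (pANOVA / phylANCOVA)", "",
               "| trait | test | F | p |", "|---|---|---|---|",
               sprintf("| %s | %s | %.4g | %.4g |", pan$trait, pan$test,
                       pan$F, pan$p), "")
  }
  if (!is.null(allo) && nrow(allo)) {
    lines <- c(lines, "## Allometry of CoM position", "",
               "| response | subset | slope | 95% CI | class |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.4g | [%.4g, %.4g] | %s |",
                       allo$response, allo$subset, allo$slope,
                       allo$ci_lower, allo$ci_upper, allo$allometry), "")
  }
  lines <- c(lines, "## Fossil reconstructions", "")
  if (is.null(grid) || !nrow(grid)) {
    lines <- c(lines, "no fossil reconstructions", "")
  } else {
    std <- com[grepl("standard", com$iteration_tag), ]
    rng <- function(g) range(std$cc_com_norm[std$group == g])
    for (tx in unique(grid$taxon)) {
      v <- grid$cc_com_norm[grid$taxon == tx]
      med <- stats::median(v)
      inside <- vapply(c("HLD", "FLD"), function(g) {
        r <- rng(g); is.finite(r[1]) && med >= r[1] && med <= r[2]
      }, logical(1))
      verdict <- if (any(inside)) paste("inside extant",
                                        paste(names(inside)[inside],
                                              collapse = " and "), "range")
                 else "outside both extant group ranges"
      lines <- c(lines, sprintf(
        "- %s: cc_com_norm over %d iterations min %.4g / median %.4g / max %.4g — median %s",
        tx, length(v), min(v), med, max(v), verdict))
    }
    lines <- c(lines, "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
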