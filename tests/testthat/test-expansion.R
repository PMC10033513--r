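## Box-segment training populations let the fitting statistics run on
## thousands of meshes cheaply (8 vertices each) while still going
## through the full volumetric path.
ratio_population <- function(n, k, noise_sd = 0, seed = 1,
                             classes = rep("HLD", n)) {
  withr_seed <- get("withr_seed", asNamespace("hullcom"))
  eps <- withr_seed(seed, stats::rnorm(n, 0, noise_sd))
  lapply(seq_len(n), function(i) {
    hv <- 0.001 * (1 + i / n)               # deterministic volume spread
    box_body(paste0("t", i), skin_vol = hv * k * exp(eps[i]), hull_vol = hv,
             class = classes[i])
  })
}

test_that("constant-ratio populations are fitted exactly", {
  pop <- ratio_population(8, k = 2)
  mr <- fit_expansion_models(pop, method = "mean_ratio", scope = "all_taxa")
  expect_equal(mr$table$k, 2, tolerance = 1e-9)
  ols <- suppressWarnings(
    fit_expansion_models(pop, method = "ols_loglog", scope = "all_taxa"))
  expect_equal(ols$table$b, 1, tolerance = 1e-9)
  expect_equal(ols$table$a, log10(2), tolerance = 1e-9)
})

test_that("prediction evaluates the fitted forms and is monotone", {
  m <- structure(list(method = "mean_ratio", scope = "all_taxa",
                      table = data.frame(segment = "torso", k = 2, a = NA,
                                         b = NA, b_se = NA, n = 5, se = 0)),
                 class = "expansion_model")
  expect_equal(predict_skin_volume(0.005, "torso", m), 0.01)
  reg <- structure(list(method = "ols_loglog", scope = "all_taxa",
                        table = data.frame(segment = "torso", k = NA,
                                           a = log10(2), b = 1, b_se = 0,
                                           n = 5, se = 0)),
                   class = "expansion_model")
  expect_equal(predict_skin_volume(0.005, "torso", reg), 0.01,
               tolerance = 1e-12)
  reg$table$b <- 0.9
  p1 <- predict_skin_volume(0.001, "torso", reg)
  p10 <- predict_skin_volume(0.01, "torso", reg)
  expect_equal(p10 / p1, 10^0.9, tolerance = 1e-12)
  v <- predict_skin_volume(c(1, 2, 5) * 1e-3, "torso", reg)
  expect_true(all(diff(v) > 0))
  expect_error(predict_skin_volume(0.01, "wing", reg), "absent")
})

test_that("log-log slope is recovered with honest confidence intervals", {
  ## generating model: log10(skin) = 0.3 + 0.95 log10(hull) + N(0, 0.01)
  cover <- vapply(1:100, function(rep) {
    hv <- 10^seq(-3.5, -2, length.out = 30)
    eps <- get("withr_seed", asNamespace("hullcom"))(
      5000 + rep, stats::rnorm(30, 0, 0.1))
    pop <- lapply(seq_len(30), function(i)
      box_body(paste0("t", i), skin_vol = 10^(0.3 + 0.95 * log10(hv[i]) +
                                                eps[i]),
               hull_vol = hv[i]))
    fit <- fit_expansion_models(pop, method = "ols_loglog",
                                scope = "all_taxa")
    tcrit <- stats::qt(0.975, 28)
    abs(fit$table$b - 0.95) <= tcrit * fit$table$b_se
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("mean-ratio estimates are unbiased under multiplicative noise", {
  est <- vapply(1:200, function(rep) {
    pop <- ratio_population(10, k = 2, noise_sd = 0.1, seed = 300 + rep)
    fit_expansion_models(pop, "mean_ratio", "all_taxa")$table$k
  }, numeric(1))
  truth <- 2 * exp(0.1^2 / 2)       # E[k e^eps] for log-normal noise
  expect_lt(abs(mean(est) - truth), 3 * sd(est) / sqrt(length(est)))
})

test_that("pGLS expansion fit equals OLS on a star phylogeny", {
  pop <- ratio_population(12, k = 2, noise_sd = 0.15, seed = 7)
  st <- star_tree(12)
  st$tip.label <- vapply(pop, `[[`, character(1), "taxon")
  ols <- fit_expansion_models(pop, "ols_loglog", "all_taxa")
  pg <- fit_expansion_models(pop, "pgls_loglog", "all_taxa", tree = st)
  expect_equal(pg$table$a, ols$table$a, tolerance = 1e-8)
  expect_equal(pg$table$b, ols$table$b, tolerance = 1e-8)
})

test_that("scope filters partition the training set", {
  classes <- rep(c("HLD", "FLD", "non-avian sauropsid"), each = 3)
  pop <- ratio_population(9, k = 2, classes = classes)
  birds <- fit_expansion_models(pop, "mean_ratio", "birds_only")
  nonav <- fit_expansion_models(pop, "mean_ratio", "non_avian_only")
  all <- fit_expansion_models(pop, "mean_ratio", "all_taxa")
  expect_equal(birds$table$n + nonav$table$n, all$table$n)
  expect_equal(birds$table$n, 6)
  expect_equal(nonav$table$n, 3)
})

test_that("too-few training taxa fail naming the segment", {
  pop <- ratio_population(2, k = 2)
  expect_error(fit_expansion_models(pop, "mean_ratio", "all_taxa"),
               "torso")
})

test_that("fossil reconstruction recovers ground truth exactly without noise", {
  fx <- small_fixture()
  mr <- fit_expansion_models(fx$extant, "mean_ratio", "all_taxa")
  scen <- list(standard = density_scenario("standard"))
  for (i in seq_along(fx$fossils)) {
    grid <- reconstruct_taxon(fx$fossils[[i]], list(ratio = mr), scen)
    cell <- grid$results[["ratio.standard"]]
    ans <- fx$answers[fx$answers$taxon == grid$taxon, ]
    expect_equal(cell$body_mass, ans$true_body_mass, tolerance = 1e-6)
    expect_equal(cell$cc_com_norm, ans$true_cc_com_norm, tolerance = 1e-6)
    expect_equal(cell$dv_com_norm, ans$true_dv_com_norm, tolerance = 1e-6)
  }
})

test_that("uniform expansion at homogeneous density preserves the hull CoM", {
  ## equal shrink everywhere -> all per-segment factors identical; with
  ## homogeneous density the expanded-body CoM equals the hull-only CoM
  plan <- body_plan("HLD", shrink = structure(rep(0.8, 11),
                                              names = hullcom::SEGMENT_NAMES))
  b <- build_body(plan, taxon = "unif", resolution = "coarse")
  pop <- lapply(1:3, function(i) { b2 <- b; b2$taxon <- paste0("u", i); b2 })
  mr <- fit_expansion_models(pop, "mean_ratio", "all_taxa")
  expect_true(all(abs(mr$table$k - 0.8^-3) < 1e-9))
  fossil <- b
  fossil$segments <- lapply(fossil$segments, function(s) {
    s$skin_mesh <- NULL; s })
  grid <- reconstruct_taxon(fossil, list(mr = mr),
                            list(hom = density_scenario("homogeneous")))
  hull_only <- whole_body_com(
    apply_density_scenario(fossil, density_scenario("homogeneous")), "hull")
  cell <- grid$results[["mr.hom"]]
  expect_equal(cell$cc_com, hull_only$cc_com, tolerance = 1e-9)
  expect_equal(cell$dv_com, hull_only$dv_com, tolerance = 1e-9)
})

test_that("CoM moves toward (never past) an enlarged segment's CoM", {
  fx <- small_fixture()
  fossil <- fx$fossils[[1]]
  mr <- fit_expansion_models(fx$extant, "mean_ratio", "all_taxa")
  scen <- list(s = density_scenario("homogeneous"))
  base <- grid_cell <- reconstruct_taxon(fossil, list(m = mr), scen)$results[[1]]
  tail_idx <- which(vapply(fossil$segments, function(s) s$name == "tail",
                           logical(1)))[1]
  tail_com <- mass_properties(fossil$segments[[tail_idx]]$skeleton_hull,
                              check = FALSE)$com
  bigger <- fossil
  bigger$segments[[tail_idx]]$skeleton_hull <-
    scale_to_volume(bigger$segments[[tail_idx]]$skeleton_hull,
                    3 * mass_properties(bigger$segments[[tail_idx]]$skeleton_hull,
                                        check = FALSE)$volume)
  after <- reconstruct_taxon(bigger, list(m = mr), scen)$results[[1]]
  ## moved toward the tail CoM in x, but not beyond it
  expect_lt(abs(after$com_absolute[1] - tail_com[1]),
            abs(base$com_absolute[1] - tail_com[1]))
  expect_gt(after$com_absolute[1], tail_com[1])
})

test_that("extant validation modes behave as designed", {
  pop <- ratio_population(6, k = 2)
  mr <- fit_expansion_models(pop, "mean_ratio", "all_taxa")
  v1 <- validate_on_extant(mr, pop, mode = "apply_to_self")
  expect_true(all(abs(v1$cc_error) < 1e-6))
  expect_true(all(abs(v1$mass_error / v1$true_mass) < 1e-6))
  v2 <- validate_on_extant(mr, pop, mode = "leave_one_out")
  expect_equal(v2$cc_error, v1$cc_error, tolerance = 1e-9)
  expect_error(validate_on_extant(mr, pop[1:3], mode = "leave_one_out"),
               "4")
  fx <- small_fixture()
  v3 <- validate_on_extant(NULL, fx$extant[1:3], mode = "equal_volume_hull")
  ## pure shape error: tiny because hulls are scaled copies of the skin
  ga <- 0.4 * 0.28   # gleno-acetabular scale of the archetypes (m)
  expect_true(all(abs(v3$cc_error * v3$true_mass^(1 / 3)) < 0.02 * ga))
})

test_that("expansion models serialise to JSON and back", {
  pop <- ratio_population(8, k = 2, noise_sd = 0.1, seed = 3)
  for (meth in c("mean_ratio", "ols_loglog")) {
    m <- fit_expansion_models(pop, meth, "all_taxa")
    path <- withr::local_tempfile(fileext = ".json")
    write_expansion_model(m, path)
    back <- read_expansion_model(path)
    expect_equal(back$method, m$method)
    expect_equal(back$table$k, m$table$k, tolerance = 1e-12)
    expect_equal(back$table$b, m$table$b, tolerance = 1e-12)
  }
})
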