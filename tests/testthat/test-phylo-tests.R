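test_that("pANOVA degenerate cases behave predictably", {
  st <- star_tree(20)
  g <- setNames(rep(c("A", "B"), each = 10), st$tip.label)
  ## identical trait values: F = 0, p = 1
  same <- setNames(rep(5, 20), st$tip.label)
  r <- phylo_anova(same, g, st, n_perm = 199, seed = 1)
  expect_lt(r$statistic, 1e-10)
  expect_equal(r$p, 1)
  ## extreme separation: the attainable minimum p
  sep <- setNames(ifelse(g == "A", 100, 0) + seq(0, 1e-6, length.out = 20),
                  st$tip.label)
  r2 <- phylo_anova(sep, g, st, n_perm = 199, seed = 1)
  expect_equal(r2$p, 1 / 200)
})

test_that("pANOVA equals ordinary ANOVA on a star phylogeny", {
  st <- star_tree(24)
  set.seed(4)
  y <- setNames(rnorm(24) + rep(c(0, 0.8), each = 12), st$tip.label)
  g <- setNames(rep(c("A", "B"), each = 12), st$tip.label)
  r <- phylo_anova(y, g, st, n_perm = 499, seed = 2)
  f_classic <- anova(lm(y ~ factor(g)))[["F value"]][1]
  expect_equal(r$statistic, f_classic, tolerance = 1e-8)
})

test_that("pANOVA is seeded-reproducible and affine-invariant", {
  tr <- simulate_tree(16, seed = 9)
  y <- simulate_traits(tr, c(y = 1), seed = 10)$y
  names(y) <- tr$tip.label
  g <- setNames(rep(c("A", "B"), 8), tr$tip.label)
  r1 <- phylo_anova(y, g, tr, n_perm = 199, seed = 5)
  r2 <- phylo_anova(y, g, tr, n_perm = 199, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$statistic, r2$statistic)
  r3 <- phylo_anova(7 * y - 3, g, tr, n_perm = 199, seed = 5)
  expect_equal(r3$p, r1$p)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-10)
  ## p bounded below by 1/(n_perm + 1)
  expect_gte(r1$p, 1 / 200)
})

test_that("the slopes test detects heterogeneous allometries", {
  st <- star_tree(30)
  tx <- st$tip.label
  g <- setNames(rep(c("A", "B"), each = 15), tx)
  x <- setNames(rep(seq(-1, 1, length.out = 15), 2), tx)
  set.seed(11)
  same_slope <- setNames(2 * x + rnorm(30, 0, 0.1) +
                           ifelse(g == "A", 0, 1), tx)
  diff_slope <- setNames(x * ifelse(g == "A", 2, -2) + rnorm(30, 0, 0.1), tx)
  r_same <- phylo_anova(same_slope, g, st, n_perm = 199, seed = 3,
                        covariate = x, test = "slopes")
  r_diff <- phylo_anova(diff_slope, g, st, n_perm = 199, seed = 3,
                        covariate = x, test = "slopes")
  expect_gt(r_same$p, 0.05)
  expect_equal(r_diff$p, 1 / 200)
})

test_that("pANOVA guards its preconditions", {
  st <- star_tree(6)
  y <- setNames(rnorm(6), st$tip.label)
  expect_error(phylo_anova(y, setNames(rep("A", 6), names(y)), st,
                           n_perm = 199, seed = 1), "2 groups")
  expect_error(phylo_anova(y, setNames(c("A", rep("B", 5)), names(y)), st,
                           n_perm = 199, seed = 1), ">= 2 taxa")
  expect_error(phylo_anova(y, setNames(rep(c("A", "B"), 3), names(y)), st,
                           n_perm = 50, seed = 1), "99")
})

test_that("spearman handles monotone data, ties and small-sample exactness", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_error(spearman_cor(1:5, rep(2, 5)), "tied")

  ## ties: agree with the reference implementation's average ranking
  set.seed(2)
  x <- sample(rep(1:4, c(3, 2, 3, 2)))
  y <- rnorm(10)
  s <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)

  ## t-approximation p sanity against cor.test's t-based p under ties
  expect_equal(s$p, ref$p.value, tolerance = 0.2)

  ## exact enumeration agrees with cor.test's exact p (no ties, n = 6)
  xe <- c(1, 2, 3, 4, 5, 6); ye <- c(2, 1, 4, 3, 6, 5)
  se <- spearman_cor(xe, ye, p_method = "exact")
  refe <- cor.test(xe, ye, method = "spearman", exact = TRUE)
  expect_equal(se$p, refe$p.value, tolerance = 1e-10)
  expect_error(spearman_cor(1:9, rnorm(9), p_method = "exact"), "n <= 8")
})

test_that("spearman matrices are symmetric with unit diagonal", {
  fx <- small_fixture()
  X <- fx$traits[, c("cc_com_norm", "dv_com_norm", "forelimb_length_norm")]
  sm <- spearman_matrix(X)
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(diag(sm$rho), c(cc_com_norm = 1, dv_com_norm = 1,
                               forelimb_length_norm = 1))
  expect_true(all(sm$p >= 0 & sm$p <= 1))
})
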