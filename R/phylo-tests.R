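#' Phylogenetic ANOVA / ANCOVA by residual randomisation
#'
#' Group-difference (and slope-heterogeneity) tests performed in
#' phylogenetically transformed space: data and design are
#' premultiplied by `C^(-1/2)` (Cholesky factor of the BM covariance,
#' triangular solve), the F statistic for the term of interest is
#' computed, and significance comes from randomising the
#' reduced-model residuals (the RRPP scheme):
#' `p = (1 + #\{F* >= F\}) / (1 + n_perm)`.
#'
#' Without a covariate the test compares group means (pANOVA). With
#' `covariate` and `test = "group"` the group term is tested after the
#' covariate (phylogenetic ANCOVA); with `test = "slopes"` the
#' group-by-covariate interaction is tested, i.e. whether regression
#' slopes differ among groups.
#'
#' @param trait Named numeric response.
#' @param groups Named factor/character of group labels (>= 2 groups,
#'   each with >= 2 taxa).
#' @param tree `phylo` tree.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Mandatory integer seed; results are bit-reproducible.
#' @param covariate Optional named numeric covariate.
#' @param test `"group"` or `"slopes"` (the latter requires a
#'   covariate).
#' @return Object of class `perm_test_result`: `statistic` (observed
#'   F), `p`, `n_perm`, `seed`, `df`.
#' @export
phylo_anova <- function(trait, groups, tree, n_perm = 999, seed,
                        covariate = NULL, test = c("group", "slopes")) {
  test <- match.arg(test)
  if (missing(seed)) stop("a seed is required for reproducible permutation")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (test == "slopes" && is.null(covariate))
    stop("the slopes test requires a covariate")
  al <- align_to_tree(names(trait), tree)
  taxa <- al$taxa
  y <- as.numeric(trait[taxa])
  g <- factor(unname(groups[taxa]))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(is.na(g))) stop("groups absent for taxa: ",
                          paste(taxa[is.na(g)], collapse = ", "))
  if (any(table(g) < 2)) stop("every group needs >= 2 taxa")
  n <- length(y)
  L <- t(chol(bm_vcv(al$tree)))
  ty <- forwardsolve(L, y)
  TX <- function(X) forwardsolve(L, X)
  one <- rep(1, n)
  G <- stats::model.matrix(~g)[, -1, drop = FALSE]
  if (!is.null(covariate)) {
    cv <- as.numeric(covariate[taxa])
    if (any(!is.finite(cv))) stop("covariate missing for matched taxa")
  }
  if (test == "group") {
    Xr <- if (is.null(covariate)) cbind(one) else cbind(one, cv)
    Xf <- cbind(Xr, G)
  } else {
    Xr <- cbind(one, cv, G)
    Xf <- cbind(Xr, G * cv)
  }
  qr_r <- qr(TX(Xr)); qr_f <- qr(TX(Xf))
  df1 <- qr_f$rank - qr_r$rank
  df2 <- n - qr_f$rank
  f_tol <- 1e-20 * (sum(ty^2) + .Machine$double.xmin)
  f_stat <- function(v) {
    rss_r <- sum(qr.resid(qr_r, v)^2)
    if (rss_r < f_tol) return(0)   # reduced model already exact: no effect
    rss_f <- sum(qr.resid(qr_f, v)^2)
    ((rss_r - rss_f) / df1) / (rss_f / df2)
  }
  f_obs <- f_stat(ty)
  fit_r <- qr.fitted(qr_r, ty)
  res_r <- ty - fit_r
  f_perm <- withr_seed(seed, vapply(seq_len(n_perm), function(i)
    f_stat(fit_r + res_r[sample.int(n)]), numeric(1)))
  structure(list(statistic = f_obs,
                 p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, df = c(df1 = df1, df2 = df2),
                 test = test),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("permutation %s test: F(%d, %d) = %.4g, p = %.4g (%d perms, seed %d)\n",
              x$test, x$df[1], x$df[2], x$statistic, x$p, x$n_perm, x$seed))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; rho is the Pearson correlation of the
#' ranks. The default p-value uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on n-2 df (two-sided); for small
#' samples (n <= 8) an exact permutation p-value by full enumeration
#' is available.
#'
#' @param x,y Paired numeric vectors (n >= 3, finite).
#' @param p_method `"t"` or `"exact"` (exact limited to n <= 8, where
#'   full enumeration of the n! rank permutations is feasible).
#' @return List with `rho`, `p`, `n`, `p_method`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired finite values")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance (all values tied): rho undefined")
  rho <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 8) stop("exact permutation p limited to n <= 8 (n! enumeration)")
    perms <- permutations_all(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n, p_method = p_method)
}

## All permutations of 1..n as a matrix (n! rows); recursive, tiny n.
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))))
}

#' Spearman correlation matrix for a trait table
#'
#' Pairwise [spearman_cor()] over the columns of a trait table —
#' applied separately to raw tip values and ancestral-state node
#' values downstream.
#'
#' @param traits data.frame/matrix of numeric traits.
#' @param p_method Passed to [spearman_cor()].
#' @return List of matrices `rho` and `p`.
#' @export
spearman_matrix <- function(traits, p_method = "t") {
  tm <- as.matrix(traits)
  p <- ncol(tm)
  rho <- pmat <- matrix(NA_real_, p, p, dimnames = list(colnames(tm),
                                                        colnames(tm)))
  diag(rho) <- 1; diag(pmat) <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    s <- spearman_cor(tm[, i], tm[, j], p_method)
    rho[i, j] <- rho[j, i] <- s$rho
    pmat[i, j] <- pmat[j, i] <- s$p
  }
  list(rho = rho, p = pmat)
}
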