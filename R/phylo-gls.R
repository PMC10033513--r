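## Phylogenetic GLS under Brownian motion (optionally Pagel's lambda),
## with ML sigma^2, AICc and t-based coefficient intervals. The
## transformed-space machinery (C^(-1/2) by Cholesky + triangular
## solve) is shared with the permutation ANOVA and the phylogenetic
## PCA.

## Align named data to tree tips; returns index of rows and the pruned,
## ordered tree. Mismatches are dropped with a warning (intersection
## used).
align_to_tree <- function(values_names, tree) {
  common <- intersect(values_names, tree$tip.label)
  if (!length(common)) stop("no taxa shared between data and tree")
  if (length(common) < length(values_names) ||
        length(common) < length(tree$tip.label))
    warning("tree/data mismatch: using ", length(common), " shared taxa")
  tree <- ape::keep.tip(tree, common)
  list(tree = tree, taxa = tree$tip.label)
}

bm_vcv <- function(tree, lambda = 1) {
  C <- ape::vcv(tree)
  if (lambda != 1) {
    D <- diag(C)
    C <- C * lambda
    diag(C) <- D
  }
  C
}

gls_core <- function(y, X, C) {
  n <- length(y)
  L <- t(chol(C))                      # C = L L'
  z <- forwardsolve(L, y)
  W <- forwardsolve(L, X)
  qrW <- qr(W)
  beta <- qr.coef(qrW, z)
  resid <- qr.resid(qrW, z)
  rss <- sum(resid^2)
  logdetC <- 2 * sum(log(diag(L)))
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  list(beta = beta, rss = rss, logLik = ll, sigma2_ml = sigma2_ml,
       qrW = qrW, W = W, z = z, L = L, logdetC = logdetC)
}

#' Phylogenetic generalised least squares
#'
#' GLS regression with error covariance `sigma^2 C`, where C holds
#' shared branch lengths under Brownian motion; Pagel's lambda
#' (rescaling the off-diagonals) can be estimated by maximum
#' likelihood (coarse grid on \[0, 1\] followed by golden-section
#' refinement). Fitting is by ML so AICc is comparable across
#' fixed-effect structures. On a star phylogeny C is proportional to
#' the identity and the fit reduces exactly to OLS.
#'
#' @param y Response vector, named by taxon (or supply `taxa`).
#' @param X Design matrix including the intercept column; column names
#'   are kept for reporting.
#' @param tree `phylo` tree covering the taxa.
#' @param taxa Taxon labels for the rows of `y`/`X` (defaults to
#'   `names(y)`).
#' @param correlation `"BM"` or `"lambda"`.
#' @param level Confidence level for coefficient intervals (t
#'   distribution, n - p residual df).
#' @return Object of class `pgls_fit`: coefficients, `se`, `ci`
#'   (matrix), `sigma2` (ML), `logLik`, `AICc`, `n`, `k` (parameter
#'   count including sigma^2 and lambda when estimated), `lambda`,
#'   `correlation` tag.
#' @export
pgls <- function(y, X, tree, taxa = names(y),
                 correlation = c("BM", "lambda"), level = 0.95) {
  correlation <- match.arg(correlation)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  if (is.null(taxa)) stop("y must be named by taxon (or pass `taxa`)")
  al <- align_to_tree(taxa, tree)
  i <- match(al$taxa, taxa)
  y <- as.numeric(y)[i]; X <- X[i, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) {
    qx <- qr(X)
    stop("design matrix is rank deficient; collinear columns: ",
         paste(colnames(X)[-seq_len(qx$rank)], collapse = ", "))
  }
  fit_at <- function(lam) gls_core(y, X, bm_vcv(al$tree, lam))
  lambda_hat <- NA_real_
  if (correlation == "lambda") {
    grid <- seq(0, 1, by = 0.05)
    ll <- vapply(grid, function(l) fit_at(l)$logLik, numeric(1))
    j <- which.max(ll)
    lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
    opt <- stats::optimize(function(l) fit_at(l)$logLik, c(lo, hi),
                           maximum = TRUE, tol = 1e-8)
    lambda_hat <- if (opt$objective >= max(ll)) opt$maximum else grid[j]
    core <- fit_at(lambda_hat)
  } else core <- fit_at(1)
  ## coefficient covariance with the unbiased variance (matches OLS
  ## inference on a star tree)
  df <- n - p
  sigma2_hat <- core$rss / df
  XtX_inv <- chol2inv(qr.R(core$qrW))
  se <- sqrt(diag(XtX_inv) * sigma2_hat)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  ci <- cbind(lower = core$beta - tcrit * se, upper = core$beta + tcrit * se)
  rownames(ci) <- names(se) <- colnames(X)
  k <- p + 1L + (correlation == "lambda")
  aicc <- -2 * core$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(list(coefficients = stats::setNames(core$beta, colnames(X)),
                 se = se, ci = ci, sigma2 = core$sigma2_ml,
                 sigma2_unbiased = sigma2_hat,
                 logLik = core$logLik, AICc = aicc, n = n, k = k,
                 df.residual = df, lambda = lambda_hat,
                 correlation = if (correlation == "lambda")
                   sprintf("lambda(%.3f)", lambda_hat) else "BM",
                 taxa = al$taxa),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("pgls_fit (%s): n = %d, logLik = %.3f, AICc = %.3f\n",
              x$correlation, x$n, x$logLik, x$AICc))
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(round(tab, 5))
  invisible(x)
}

#' Classify a scaling slope against isometry
#'
#' Compares the confidence interval of a fitted slope with the
#' isometric expectation (1/3 for a linear dimension against body
#' mass): an interval wholly below is negative allometry, wholly above
#' positive, and one containing the expectation is isometric. The CI
#' bounds are returned so "narrowly includes isometry" cases remain
#' visible.
#'
#' @param fit A [pgls()] fit.
#' @param isometric_slope Expected slope under isometry.
#' @param coef Which coefficient is the slope (name or index; default
#'   the second column).
#' @return List with `classification` (`"negative"`, `"isometric"`,
#'   `"positive"`), `slope`, `ci`.
#' @export
allometry_classify <- function(fit, isometric_slope = 1 / 3, coef = 2L) {
  stopifnot(inherits(fit, "pgls_fit"))
  ci <- fit$ci[coef, ]
  cls <- if (ci[["upper"]] < isometric_slope) "negative"
         else if (ci[["lower"]] > isometric_slope) "positive"
         else "isometric"
  list(classification = cls, slope = unname(fit$coefficients[coef]),
       ci = ci, isometric_slope = isometric_slope)
}

#' Summarise an analysis across a distribution of trees
#'
#' Runs `fn(tree)` (returning a named numeric vector) on each tree of
#' a list and reports per-tree values plus the across-tree median and
#' 2.5/97.5 percentiles — the standard way to propagate topology
#' uncertainty from a supertree sample.
#'
#' @param trees List of `phylo` trees (or a `multiPhylo`).
#' @param fn Function of one tree returning a named numeric vector.
#' @return List with `per_tree` (matrix trees x quantities) and
#'   `summary` (data.frame with median, q2.5, q97.5).
#' @export
across_trees <- function(trees, fn) {
  vals <- do.call(rbind, lapply(trees, fn))
  qs <- apply(vals, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  list(per_tree = vals,
       summary = data.frame(quantity = colnames(vals),
                            median = qs[1, ], q2.5 = qs[2, ],
                            q97.5 = qs[3, ], row.names = NULL))
}
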