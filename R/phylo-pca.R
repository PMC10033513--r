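#' Phylogenetic principal component analysis
#'
#' PCA of the evolutionary (rate) covariance matrix: traits are centred
#' on the phylogenetic (GLS) mean and the covariance is estimated with
#' `C^-1` weighting, `R = (X - 1 a)' C^-1 (X - 1 a) / (n - 1)`. Tip
#' scores are the centred traits projected on the eigenvectors; node
#' scores (optional) are projected BM ancestral-state estimates, which
#' is what places reconstructed ancestors inside the tip morphospace.
#' On a star phylogeny the analysis reduces to ordinary covariance PCA
#' on centred data.
#'
#' @param traits Matrix/data.frame, taxa as rownames, >= 2 numeric
#'   columns, complete cases.
#' @param tree `phylo` tree.
#' @param project_nodes Also compute scores for internal nodes.
#' @return Object of class `ppca_result`: `eigenvalues`, `loadings`
#'   (trait x PC), `scores` (tips), `node_scores` (optional),
#'   `percent_variance`, `phylo_mean`.
#' @export
phylo_pca <- function(traits, tree, project_nodes = FALSE) {
  X <- as.matrix(traits)
  if (ncol(X) < 1L) stop("need at least one trait")
  if (any(!stats::complete.cases(X))) stop("traits contain missing values")
  al <- align_to_tree(rownames(X), tree)
  X <- X[al$taxa, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    warning("fewer taxa than traits + 1: covariance is rank deficient; ",
            "reporting ", min(n - 1, p), " components")
  C <- bm_vcv(al$tree)
  L <- t(chol(C))
  one <- rep(1, n)
  tone <- forwardsolve(L, one)
  tX <- forwardsolve(L, X)
  a <- crossprod(tone, tX) / sum(tone^2)          # phylogenetic mean (1 x p)
  Xc <- X - one %*% a
  tXc <- tX - tone %*% a
  R <- crossprod(tXc) / (n - 1)                   # evolutionary covariance
  eig <- eigen(R, symmetric = TRUE)
  npc <- min(n - 1, p)
  V <- eig$vectors[, seq_len(npc), drop = FALSE]
  lam <- eig$values[seq_len(npc)]
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(npc)))
  scores <- Xc %*% V
  rownames(scores) <- al$taxa
  out <- list(eigenvalues = lam, loadings = V, scores = scores,
              percent_variance = 100 * lam / sum(eig$values),
              total_variance = sum(diag(R)),
              phylo_mean = drop(a))
  if (project_nodes) {
    anc <- ancestral_states_bm(al$tree, X)
    A <- do.call(cbind, lapply(colnames(X), function(tr)
      anc$estimate[anc$trait == tr]))
    colnames(A) <- colnames(X)
    ns <- (A - matrix(a, nrow(A), p, byrow = TRUE)) %*% V
    rownames(ns) <- unique(anc$node)
    out$node_scores <- ns
  }
  structure(out, class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  cat("phylogenetic PCA:\n")
  print(data.frame(PC = colnames(x$loadings),
                   eigenvalue = round(x$eigenvalues, 5),
                   percent = round(x$percent_variance, 2)),
        row.names = FALSE)
  invisible(x)
}
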