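#' Newick tree input/output
#'
#' Thin wrappers over `ape`'s parser that accept either a Newick
#' string or a file path, and require branch lengths (the comparative
#' machinery is meaningless without them).
#'
#' @param x Newick string or path to a Newick file.
#' @return `read_newick`: a `phylo`; `write_newick`: a Newick string.
#' @export
read_newick <- function(x) {
  tree <- if (length(x) == 1L && !grepl("\\(", x) && file.exists(x))
    ape::read.tree(x)
  else ape::read.tree(text = x)
  if (is.null(tree))
    stop("failed to parse Newick input (unbalanced parentheses or empty?)")
  if (is.null(tree$edge.length))
    stop("Newick tree has no branch lengths; time-calibrated lengths required")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Brownian-motion ancestral states with confidence intervals
#'
#' Maximum-likelihood (equivalently joint GLS) ancestral estimates
#' under Brownian motion. Maximising the joint BM likelihood over all
#' internal states reduces to a weighted graph-Laplacian system: every
#' internal node's estimate is the 1/branch-length-weighted mean of
#' its neighbours' values, solved simultaneously. Estimate variances
#' are `sigma^2 (L_II^-1)_ii` with the rate estimated from the tips by
#' GLS (n - 1 denominator, the convention of the standard
#' implementations); 95% intervals are `estimate +/- 1.96
#' sqrt(variance)`. Polytomies (including star trees) are handled
#' natively.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param x Named numeric vector of tip values (single trait) or a
#'   matrix/data.frame with taxa as rownames (one column per trait).
#' @param on_missing `"error"` (default) or `"drop"`: what to do with
#'   tips lacking a value.
#' @return data.frame with columns `node` (ape node numbers,
#'   ntip+1 ... ), `trait`, `estimate`, `variance`, `ci_lower`,
#'   `ci_upper`.
#' @export
ancestral_states_bm <- function(tree, x, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  xm <- if (is.null(dim(x))) matrix(x, ncol = 1,
                                    dimnames = list(names(x), "trait"))
        else as.matrix(x)
  if (is.null(rownames(xm))) stop("tip values must be named by taxon")
  miss <- setdiff(tree$tip.label, rownames(xm))
  bad <- rownames(xm)[!stats::complete.cases(xm)]
  if (length(c(miss, bad))) {
    if (on_missing == "error")
      stop("tips without trait values: ",
           paste(unique(c(miss, bad)), collapse = ", "))
    tree <- ape::drop.tip(tree, c(miss, bad))
  }
  if (any(tree$edge.length <= 0)) stop("branch lengths must be > 0")
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  W <- matrix(0, N, N)
  for (k in seq_len(nrow(tree$edge))) {
    i <- tree$edge[k, 1]; j <- tree$edge[k, 2]
    w <- 1 / tree$edge.length[k]
    W[i, j] <- W[i, j] + w; W[j, i] <- W[j, i] + w
  }
  Lap <- diag(rowSums(W)) - W
  I <- (ntip + 1L):N; Tt <- seq_len(ntip)
  LII_inv <- solve(Lap[I, I, drop = FALSE])
  vdiag <- diag(LII_inv)
  ## GLS rate estimate from the tips
  C <- ape::vcv(tree)
  Lc <- t(chol(C))
  out <- lapply(colnames(xm), function(tr) {
    v <- xm[tree$tip.label, tr]
    z <- LII_inv %*% (W[I, Tt, drop = FALSE] %*% v)
    tv <- forwardsolve(Lc, v); tone <- forwardsolve(Lc, rep(1, ntip))
    mu <- sum(tone * tv) / sum(tone^2)
    sig2 <- sum((tv - mu * tone)^2) / (ntip - 1)
    va <- sig2 * vdiag
    data.frame(node = I, trait = tr, estimate = as.numeric(z),
               variance = va,
               ci_lower = as.numeric(z) - 1.96 * sqrt(va),
               ci_upper = as.numeric(z) + 1.96 * sqrt(va),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Phylomorphospace coordinates
#'
#' Coordinates for a bivariate trait-space plot containing the tips,
#' the ML ancestral nodes (with per-trait 95% CIs) and the branches
#' connecting parent to child — the standard device for tracking a
#' lineage's trajectory through e.g. CoM space.
#'
#' @param tree `phylo` tree.
#' @param trait_x,trait_y Named numeric tip vectors.
#' @return List with `tips` (taxon, x, y), `nodes` (node, x, y and CI
#'   columns) and `edges` (parent, child and segment endpoint
#'   coordinates).
#' @export
phylomorphospace_coords <- function(tree, trait_x, trait_y) {
  xm <- cbind(x = trait_x[tree$tip.label], y = trait_y[tree$tip.label])
  rownames(xm) <- tree$tip.label
  anc <- ancestral_states_bm(tree, xm)
  ntip <- length(tree$tip.label)
  nodes <- data.frame(node = unique(anc$node))
  for (tr in c("x", "y")) {
    a <- anc[anc$trait == tr, ]
    i <- match(nodes$node, a$node)
    nodes[[tr]] <- a$estimate[i]
    nodes[[paste0(tr, "_ci_lower")]] <- a$ci_lower[i]
    nodes[[paste0(tr, "_ci_upper")]] <- a$ci_upper[i]
  }
  coord <- function(id, tr) {
    out <- numeric(length(id))
    tip <- id <= ntip
    out[tip] <- xm[id[tip], tr]
    out[!tip] <- nodes[[tr]][match(id[!tip], nodes$node)]
    out
  }
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2])
  edges$x0 <- coord(edges$parent, "x"); edges$y0 <- coord(edges$parent, "y")
  edges$x1 <- coord(edges$child, "x"); edges$y1 <- coord(edges$child, "y")
  list(tips = data.frame(taxon = tree$tip.label, x = unname(xm[, "x"]),
                         y = unname(xm[, "y"]), stringsAsFactors = FALSE),
       nodes = nodes, edges = edges)
}
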