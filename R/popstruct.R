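#' Identity-by-state distance matrix
#'
#' For each sample pair, the IBS distance is one minus the fraction of
#' shared alleles over the loci called in both samples:
#' `d(i,j) = sum_l |d_i - d_j| / (2 * L_ij)` since a dosage difference of
#' 0/1/2 corresponds to 2/1/0 shared alleles. Pairs with no commonly called
#' locus get `NA` (flagged undefined).
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal, sample
#'   ids as dimnames.
#' @export
ibs_distance <- function(gm) {
  n <- n_samples(gm)
  if (n < 2) stop("need at least 2 samples for a distance matrix")
  d <- gm$dosage
  if (!anyNA(d)) {  # complete data: Manhattan distance over 2L alleles
    D <- as.matrix(stats::dist(d, method = "manhattan")) / (2 * ncol(d))
    dimnames(D) <- list(gm$samples, gm$samples)
    return(D)
  }
  D <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(d[i, ]) & !is.na(d[j, ])
      L <- sum(both)
      D[i, j] <- D[j, i] <- if (L == 0) NA_real_ else
        sum(abs(d[i, both] - d[j, both])) / (2 * L)
    }
  }
  D
}

#' Principal component analysis of a genotype matrix
#'
#' Mean-imputes missing dosages per locus, centers each locus at its mean,
#' and eigendecomposes the sample covariance of the centered matrix
#' (computed via SVD). Explained variance per component is its eigenvalue
#' as a percentage of the total, so the percentages sum to 100.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples and >= 1 polymorphic
#'   locus.
#' @param n_components number of components to keep in `scores` (default
#'   10, capped at the available rank).
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `explained` (percent per retained component over the full spectrum),
#'   `eigenvalues`.
#' @export
pca_genotypes <- function(gm, n_components = 10L) {
  d <- gm$dosage
  if (nrow(d) < 2) stop("need at least 2 samples for PCA")
  mu <- colMeans(d, na.rm = TRUE)
  X <- sweep(d, 2, mu)
  X[is.na(X)] <- 0  # mean imputation after centering
  storage.mode(X) <- "double"
  if (all(abs(X) < 1e-12)) stop("no polymorphism: zero total variance")
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  k <- min(n_components, sum(ev > 1e-12 * ev[1]))
  structure(list(
    scores = pr$x[, seq_len(k), drop = FALSE],
    explained = 100 * ev / sum(ev),
    eigenvalues = ev
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples; PC1 %.2f%%, PC2 %.2f%% of variance\n",
              nrow(x$scores), x$explained[1],
              if (length(x$explained) > 1) x$explained[2] else NA))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration: at each step the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, with ties
#' broken toward the smallest row-major index pair. Negative branch lengths
#' are clamped to zero and the deficit moved to the sibling branch, keeping
#' the joined pair's path length intact. Exact on additive distance
#' matrices.
#'
#' @param D symmetric distance matrix with dimnames (>= 3 taxa).
#' @return Newick string (unrooted, trifurcating root) with branch lengths.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor-joining needs at least 3 taxa")
  if (anyNA(D)) stop("distance matrix contains undefined entries")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  sub <- labels  # growing newick fragments
  repeat {
    m <- nrow(D)
    if (m == 3) break
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j), i < j, row-major
    Q[lower.tri(Q)] <- Inf
    hits <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_sub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], li, sub[j], lj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], sprintf("node%d", m))
    D <- D2
  }
  # final 3-taxon star: three-point closed form
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ln <- pmax(c(la, lb, lc), 0)
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[1], ln[1], sub[2], ln[2],
          sub[3], ln[3])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples loci with replacement `B` times, rebuilds the IBS
#' neighbor-joining tree for each replicate, and annotates each internal
#' bipartition of the original tree with the percentage of replicates
#' containing it (computed with `ape::prop.clades`). Deterministic for a
#' fixed seed.
#'
#' @param gm a [genotype_matrix()].
#' @param B number of bootstrap replicates (`B = 0` returns the original
#'   tree without supports).
#' @param seed integer seed (required).
#' @return An `ape::phylo` tree; internal node labels hold the support
#'   percentages when `B > 0`.
#' @export
bootstrap_support <- function(gm, B, seed) {
  if (missing(seed)) stop("a seed is required")
  tree <- ape::read.tree(text = nj_tree(ibs_distance(gm)))
  if (B == 0) return(tree)
  set.seed(seed)
  L <- n_loci(gm)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    reps[[b]] <- ape::read.tree(text = nj_tree(ibs_distance(
      subset_genotypes(gm, loci = idx))))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- as.character(round2(100 * counts / B))
  tree
}

#' VanRaden kinship matrix from centered dosages
#'
#' Centers each locus' dosages at twice its ALT frequency and scales the
#' cross-product by the total expected heterozygosity:
#' `K = Z Z' / (2 * sum_l p_l (1 - p_l))`, with missing dosages
#' contributing zero after centering. Loci with undefined frequency are
#' dropped; an all-monomorphic matrix is an error.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
kinship <- function(gm) {
  if (n_samples(gm) < 2) stop("need at least 2 samples for kinship")
  d <- gm$dosage
  called <- colSums(!is.na(d))
  p <- ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all loci monomorphic; kinship undefined")
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(d, 2, 2 * p)
  Z[is.na(Z)] <- 0
  storage.mode(Z) <- "double"
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(gm$samples, gm$samples)
  K
}
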