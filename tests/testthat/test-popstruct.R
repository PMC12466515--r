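test_that("IBS distance matches allele-sharing arithmetic", {
  gm <- make_gm(rbind(i = c(0L, 1L), j = c(1L, 1L)))
  D <- ibs_distance(gm)
  expect_equal(D["i", "j"], 0.25)   # shared alleles (1 + 2) of 4
  expect_equal(diag(D), c(i = 0, j = 0))
  gm2 <- make_gm(rbind(a = rep(0L, 5), b = rep(2L, 5)))
  expect_equal(ibs_distance(gm2)["a", "b"], 1)
  gm3 <- make_gm(rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L)))
  expect_equal(ibs_distance(gm3)["a", "b"], 0)
  expect_error(ibs_distance(make_gm(matrix(0L, 1, 3))), "2 samples")
  # missing loci drop out of the pairwise denominator
  gm4 <- make_gm(rbind(a = c(0L, NA, 2L), b = c(2L, 1L, NA)))
  expect_equal(ibs_distance(gm4)["a", "b"], 1)   # only locus 1 comparable
})

test_that("PCA explained variances are eigenvalue shares summing to 100", {
  gm <- make_gm(rbind(a = c(0L, 0L), b = c(2L, 2L)))
  p <- pca_genotypes(gm)
  expect_equal(p$explained[1], 100)
  # 3 x 2 toy: eigenvalues of the 2x2 covariance, closed form
  d <- rbind(a = c(0L, 0L), b = c(1L, 2L), c = c(2L, 0L))
  gm2 <- make_gm(d)
  p2 <- pca_genotypes(gm2)
  ev <- eigen(stats::cov(d))$values
  expect_equal(unname(p2$eigenvalues[1:2]), ev, tolerance = 1e-10)
  expect_equal(sum(p2$explained), 100, tolerance = 1e-9)
  expect_error(pca_genotypes(make_gm(matrix(1L, 3, 2))), "polymorphism")
})

test_that("PCA coordinates are invariant (up to sign) under sample reordering", {
  set.seed(41)
  d <- matrix(sample(0:2, 60, replace = TRUE), nrow = 6)
  gm <- make_gm(d, pos = 1:10)
  p1 <- pca_genotypes(gm)
  perm <- c(3, 1, 6, 2, 5, 4)
  gm2 <- genotype_matrix(d[perm, ], gm$loci, samples = gm$samples[perm])
  p2 <- pca_genotypes(gm2)
  for (k in 1:2) {
    a <- p1$scores[gm$samples, k]
    b <- p2$scores[gm$samples, k]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-8)) ||
                isTRUE(all.equal(a, -b, tolerance = 1e-8)))
  }
})

test_that("neighbor-joining inverts additive distance matrices exactly", {
  # 3 taxa: unique topology, three-point branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- ape::read.tree(text = nj_tree(D3))
  expect_equal(sort(cophenetic(t3)[c("A", "B", "C"), c("A", "B", "C")]),
               sort(D3))

  # 4-6 taxa: distances generated from random trees are recovered exactly
  set.seed(42)
  for (n in 4:6) {
    for (rep in 1:3) {
      gen <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
      gen$tip.label <- LETTERS[1:n]
      D <- cophenetic(gen)[LETTERS[1:n], LETTERS[1:n]]
      est <- ape::read.tree(text = nj_tree(D))
      expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(est)), 0,
                   ignore_attr = TRUE)
      expect_equal(sort(cophenetic(est)[LETTERS[1:n], LETTERS[1:n]]),
                   sort(D), tolerance = 1e-8)
    }
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("NJ topology matches exhaustive least-squares search on 5 taxa", {
  # brute-force oracle: score all 15 unrooted 5-taxon topologies by
  # least-squares branch fit to the distance matrix
  ls_best_topology <- function(D) {
    taxa <- rownames(D)
    trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
    score <- function(tr) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      X <- sapply(seq_len(nrow(tr$edge)), function(e) {
        tr2 <- tr; tr2$edge.length <- as.numeric(seq_len(nrow(tr$edge)) == e)
        as.vector(as.dist(cophenetic(tr2)[taxa, taxa]))
      })
      y <- as.vector(as.dist(D))
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }
    scores <- vapply(trees, score, numeric(1))
    trees[[which.min(scores)]]
  }
  set.seed(7)
  gen <- ape::rtree(5, br = function(k) stats::runif(k, 0.5, 2))
  gen$tip.label <- LETTERS[1:5]
  D <- cophenetic(gen)[LETTERS[1:5], LETTERS[1:5]]
  est <- ape::read.tree(text = nj_tree(D))
  oracle <- ls_best_topology(D)
  expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(oracle)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports are deterministic and strong for a clean split", {
  set.seed(61)
  # two sharply differentiated populations of 6 samples each
  L <- 300
  pA <- stats::runif(L, 0.05, 0.25)
  pB <- pmin(pA + 0.6, 0.95)
  d <- rbind(
    t(replicate(6, stats::rbinom(L, 2, pA))),
    t(replicate(6, stats::rbinom(L, 2, pB))))
  gm <- make_gm(d, pos = seq_len(L),
                samples = c(paste0("A", 1:6), paste0("B", 1:6)))
  t0 <- bootstrap_support(gm, B = 0, seed = 1)
  expect_null(t0$node.label)
  tr <- bootstrap_support(gm, B = 50, seed = 9)
  tr2 <- bootstrap_support(gm, B = 50, seed = 9)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # the A|B split must be an original bipartition with high support
  rooted <- ape::root(tr, outgroup = "B1", resolve.root = TRUE,
                      edgelabel = TRUE)
  expect_true(ape::is.monophyletic(rooted, paste0("A", 1:6)))
  mrca <- ape::getMRCA(rooted, paste0("A", 1:6))
  supp <- as.numeric(rooted$node.label[mrca - ape::Ntip(rooted)])
  expect_gte(supp, 95)
})

test_that("kinship is the scaled centered cross-product with sane structure", {
  # 2-sample 2-locus toy: p = (0.5, 0.5), Z = +/-1, scale = 2 * 0.5 = 1
  gm <- make_gm(rbind(a = c(0L, 2L), b = c(2L, 0L)))
  K <- kinship(gm)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  # clones share their self-kinship
  gm2 <- make_gm(rbind(c1 = c(0L, 1L, 2L, 1L), c2 = c(0L, 1L, 2L, 1L),
                       u = c(2L, 0L, 0L, 1L)))
  K2 <- kinship(gm2)
  expect_equal(K2["c1", "c2"], K2["c1", "c1"])
  expect_true(all(K2["c1", "c2"] >= K2["c1", "u"]))
  expect_equal(K2, t(K2))
  expect_error(kinship(make_gm(matrix(0L, 3, 4))), "monomorphic")
})

test_that("unrelated individuals from one population have near-zero kinship", {
  set.seed(71)
  L <- 2000; n <- 30
  p <- stats::runif(L, 0.1, 0.9)
  d <- t(replicate(n, stats::rbinom(L, 2, p)))
  K <- kinship(make_gm(d, pos = seq_len(L)))
  off <- K[upper.tri(K)]
  # with in-sample frequencies each row of K sums to zero, so the
  # off-diagonal mean is exactly -mean(diag)/(n-1): near zero for large n
  expect_equal(unname(rowSums(K)), rep(0, n), tolerance = 1e-8)
  expect_equal(mean(off), -mean(diag(K)) / (n - 1), tolerance = 1e-8)
  expect_lt(abs(mean(off)), 0.05)
  expect_gt(mean(diag(K)), mean(off))
})

test_that("PC1 fully separates simulated populations and the NJ tree is monophyletic", {
  cfg <- sim_config(n_loci = 400, n_per_pop = c(p1 = 20, p2 = 20),
                    fst = 0.15, missing_rate = 0.01, error_rate = 0.005,
                    seed = 424)
  sim <- simulate_cohort(cfg)
  gm <- sim$genotypes
  pc <- pca_genotypes(gm)
  s1 <- pc$scores[sim$groups[rownames(pc$scores)] == "p1", 1]
  s2 <- pc$scores[sim$groups[rownames(pc$scores)] == "p2", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  tree <- ape::read.tree(text = nj_tree(ibs_distance(gm)))
  rooted <- ape::root(tree, outgroup = names(sim$groups)[sim$groups == "p2"][1],
                      resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, names(sim$groups)[sim$groups == "p1"]))
})
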