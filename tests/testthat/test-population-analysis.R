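sites_for <- function(m, chrom = "chr1") {
  data.frame(locus_id = rownames(m), chrom = chrom,
             pos = seq_len(nrow(m)) * 1000L, stringsAsFactors = FALSE)
}

test_that("LD pruning drops later duplicates and respects the r2 threshold", {
  set.seed(3)
  base <- sample(0:2, 30, TRUE)
  indep <- sample(0:2, 30, TRUE)
  m <- rbind(L1 = base, L2 = base, L3 = indep)
  colnames(m) <- paste0("s", 1:30)
  kept <- ld_prune(m, sites_for(m), r2_threshold = 1)
  expect_setequal(kept, c("L1", "L3"))   # exact duplicate L2 removed

  # r2 = 0.75 pair: removed at threshold 0.5, kept at threshold 1
  x <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 0, 1, 2)
  y <- c(0, 0, 1, 1, 1, 1, 2, 2, 1, 0, 1, 2)
  r2 <- cor(x, y)^2
  expect_gt(r2, 0.5); expect_lt(r2, 1)
  m2 <- rbind(A = x, B = y)
  colnames(m2) <- paste0("s", seq_along(x))
  expect_identical(ld_prune(m2, sites_for(m2), 0.5), "A")
  expect_setequal(ld_prune(m2, sites_for(m2), 1), c("A", "B"))

  # monomorphic loci are retained and skipped in pairing
  m3 <- rbind(A = x, M = rep(1, 12), B = x)
  colnames(m3) <- paste0("s", seq_along(x))
  expect_setequal(ld_prune(m3, sites_for(m3), 1), c("A", "M"))
  expect_error(ld_prune(m3, sites_for(m3), 0), "r2_threshold")
})

test_that("at threshold 1 pruning never removes imperfectly correlated loci", {
  co <- structured_cohort()
  m <- co$truth_dip[1:300, ]
  sites <- co$cohort$variants$sites
  kept <- ld_prune(m, sites, r2_threshold = 1)
  removed <- setdiff(rownames(m), kept)
  expect_equal(length(kept) + length(removed), nrow(m))
  for (l in removed) {
    r2max <- max(vapply(kept, function(k) {
      suppressWarnings(cor(m[l, ], m[k, ]))^2
    }, numeric(1)), na.rm = TRUE)
    expect_gte(r2max, 1 - 1e-12)
  }
})

test_that("genotype PCA centres, imputes, and conserves variance", {
  co <- structured_cohort()
  m <- co$truth_dip[1:400, ]
  m[1, 3] <- NA                       # exercise mean imputation
  fit <- genotype_pca(m)
  expect_true(all(diff(fit$var_explained) <= 1e-12))
  # total PC variance equals total column variance of the imputed matrix
  X <- t(m)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  expect_equal(sum(apply(X, 2, var)),
               sum(fit$var_explained) * sum(apply(X, 2, var)))
  sdev2 <- apply(fit$scores, 2, var)
  expect_equal(sum(sdev2), sum(apply(X, 2, var)))

  # identical samples get identical coordinates
  m2 <- cbind(m[, 1:5], dup = m[, 1])
  colnames(m2) <- c(colnames(m)[1:5], "dup")
  fit2 <- genotype_pca(m2)
  expect_equal(fit2$scores["dup", ], fit2$scores[1, ], ignore_attr = TRUE)
  expect_error(genotype_pca(matrix(1, 3, 4)), "degenerate|constant")
})

test_that("PCA k-means recovers three planted groups perfectly", {
  co <- structured_cohort()
  fit <- genotype_pca(co$truth_dip)
  km <- kmeans(fit$scores[, 1:2], centers = 3, nstart = 25)
  grp <- co$cohort$samples$group[match(rownames(fit$scores),
                                       co$cohort$samples$sample_id)]
  tab <- table(km$cluster, grp)
  # perfect recovery up to label permutation: one nonzero cell per row/col
  expect_equal(sum(apply(tab, 1, max)), ncol(co$truth_dip))
})

test_that("allele-sharing distance matches its closed-form cases", {
  m <- matrix(c(0L, 0L, 2L, 2L, 1L, 0L), 2, 3,
              dimnames = list(c("L1", "L2"), c("a", "b", "c")))
  d <- allele_sharing_distance(m)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d["a", "b"], 1)              # opposite homozygotes at both loci
  expect_equal(d, t(d))
  one <- matrix(c(1L, 0L), 1, 2, dimnames = list("L1", c("x", "y")))
  expect_equal(allele_sharing_distance(one)["x", "y"], 0.5)  # het vs hom
  # identical samples at distance zero
  dup <- matrix(c(0L, 1L, 0L, 1L), 2, 2,
                dimnames = list(c("L1", "L2"), c("x", "y")))
  expect_equal(allele_sharing_distance(dup)["x", "y"], 0)
  # haploid loci contribute a single allele
  hap <- matrix(c(1L, 0L), 1, 2, dimnames = list("L1", c("x", "y")))
  expect_equal(allele_sharing_distance(hap, ploidy = 1L)["x", "y"], 1)
})

test_that("neighbor joining reconstructs additive trees exactly", {
  set.seed(17)
  for (n in 4:8) {
    for (rep in 1:5) {
      tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
      D <- ape::cophenetic.phylo(tr)     # patristic distances: the oracle
      rec <- neighbor_joining(D)
      expect_equal(rf_distance(rec, tr), 0)
      # branch lengths are recovered too: path distances match the input
      expect_equal(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)], D,
                   tolerance = 1e-8)
    }
  }
})

test_that("a 3-taxon matrix resolves to the closed-form star", {
  D <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(unname(tr$edge.length), rep(1, 3))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ topology is invariant to input order and matches ape's NJ", {
  co <- structured_cohort()
  m <- co$truth_dip[1:500, 1:12]
  D <- allele_sharing_distance(m)
  t1 <- neighbor_joining(D)
  perm <- sample(nrow(D))
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(rf_distance(t1, t2), 0)
  t_ape <- ape::nj(D)                   # independent implementation
  expect_equal(rf_distance(t1, t_ape), 0)
})

test_that("Robinson-Foulds distance matches enumeration and phangorn", {
  t1 <- ape::read.tree(text = "(((a,b),c),d,e);")
  t2 <- ape::read.tree(text = "(((a,c),e),b,d);")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 4)  # maximally different 5-taxon trees
  expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,f),e);")),
               "leaf sets")
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (rep in 1:10) {
    a <- ape::rtree(8)
    b <- ape::rtree(8)
    expect_equal(rf_distance(a, b), phangorn::RF.dist(a, b))
  }
})

test_that("bootstrap support is seeded and saturates on clean structure", {
  co <- structured_cohort()
  m <- co$truth_dip[1:400, ]
  bs1 <- bootstrap_support(m, n_replicates = 30, seed = 21)
  bs2 <- bootstrap_support(m, n_replicates = 30, seed = 21)
  expect_identical(bs1$support, bs2$support)
  grp <- co$cohort$samples$group[match(colnames(m),
                                       co$cohort$samples$sample_id)]
  for (g in c("1", "2", "3")) {
    expect_true(is_monophyletic_group(bs1$tree, colnames(m)[grp == g]))
  }
  expect_error(bootstrap_support(matrix(1L, 5, 4,
                                        dimnames = list(paste0("L", 1:5),
                                                        paste0("s", 1:4))),
                                 n_replicates = 5),
               "variable")
})
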