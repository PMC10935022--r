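#' Prune loci in high linkage disequilibrium
#'
#' Scans each chromosome in position order and drops the later locus of any
#' pair whose squared Pearson correlation (over jointly-called samples)
#' meets `r2_threshold`. Comparison is against the most recent `window`
#' retained loci on the same chromosome. At the default threshold of 1 only
#' perfectly correlated duplicates are removed. Monomorphic loci (undefined
#' r-squared) are retained and skipped in pairing.
#'
#' @param m loci x samples dosage matrix.
#' @param sites site table with `locus_id`, `chrom`, `pos` covering the
#'   rows of `m`.
#' @param r2_threshold drop threshold in (0, 1]; pairs with r^2 >= threshold
#'   lose the later locus.
#' @param window number of preceding retained loci compared against.
#' @return Character vector of retained locus ids (position order within
#'   chromosome).
#' @export
ld_prune <- function(m, sites, r2_threshold = 1, window = 50) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]")
  }
  idx <- match(rownames(m), sites$locus_id)
  if (anyNA(idx)) stop("sites do not cover all loci in m")
  sites <- sites[idx, ]
  retained <- character(0)
  for (ch in unique(sites$chrom)) {
    ord <- which(sites$chrom == ch)[order(sites$pos[sites$chrom == ch])]
    kept <- integer(0)           # row indices of retained polymorphic loci
    for (i in ord) {
      xi <- m[i, ]
      vi <- var(xi, na.rm = TRUE)
      if (is.na(vi) || vi == 0) {      # monomorphic: keep, skip pairing
        retained <- c(retained, sites$locus_id[i])
        next
      }
      cmp <- tail(kept, window)
      drop <- FALSE
      for (j in cmp) {
        both <- !is.na(xi) & !is.na(m[j, ])
        if (sum(both) < 2) next
        r <- suppressWarnings(cor(xi[both], m[j, both]))
        if (!is.na(r) && r * r >= r2_threshold) {
          drop <- TRUE
          break
        }
      }
      if (!drop) {
        retained <- c(retained, sites$locus_id[i])
        kept <- c(kept, i)
      }
    }
  }
  retained
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes are coded as allele dosages; missing calls are imputed to the
#' locus mean; loci with no calls are dropped; columns (loci) are centered
#' and the sample covariance eigendecomposed (no scaling), the standard
#' coding for genotype PCA.
#'
#' @param m loci x samples dosage matrix.
#' @return list of class `genotype_pca` with `scores` (samples x
#'   components), `var_explained` (fractions, non-increasing), `rotation`,
#'   `center`, and `loci` (locus ids used, in order).
#' @export
genotype_pca <- function(m) {
  if (ncol(m) < 2L) stop("need at least 2 samples")
  keep <- rowSums(!is.na(m)) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 loci with calls")
  X <- t(m)                                  # samples x loci
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  if (all(apply(X, 2, var) == 0)) stop("degenerate (constant) matrix")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(scores = p$x,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 rotation = p$rotation, center = p$center,
                 loci = rownames(m)),
            class = "genotype_pca")
}

#' Project a genotype matrix onto an existing PCA basis
#'
#' Imputes missing calls to the fitted locus means, centers with the fitted
#' centers, and applies the fitted rotation, so coordinates are directly
#' comparable with the fit's scores.
#'
#' @param fit a [genotype_pca()] result.
#' @param m loci x samples dosage matrix covering the fit's loci.
#' @return samples x components score matrix.
#' @export
project_pca <- function(fit, m) {
  if (!all(fit$loci %in% rownames(m))) stop("m does not cover the fitted loci")
  X <- t(m[fit$loci, , drop = FALSE])
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- fit$center[j]
  sweep(X, 2, fit$center) %*% fit$rotation
}

#' Allele-sharing distance matrix
#'
#' For each sample pair, d = 1 - (shared alleles) / (total alleles) over
#' jointly-called loci; per diploid locus the shared count is
#' 2 - |g_a - g_b|, so identical samples are at distance 0 and opposite
#' homozygotes at 1. Haploid loci contribute one allele each.
#'
#' @param m loci x samples dosage matrix.
#' @param ploidy per-locus ploidy vector (default all diploid).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
allele_sharing_distance <- function(m, ploidy = rep(2L, nrow(m))) {
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  pl <- as.numeric(ploidy)
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      both <- !is.na(m[, a]) & !is.na(m[, b])
      if (!any(both)) {
        stop("zero jointly-called loci for pair ", colnames(m)[a], ", ",
             colnames(m)[b])
      }
      diff <- abs(m[both, a] - m[both, b])
      d[a, b] <- d[b, a] <- sum(diff) / sum(pl[both])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining on a symmetric distance matrix.
#' Ties in the Q-criterion are broken by the smallest (row, column) index
#' pair, so the result is deterministic; negative branch lengths are
#' clamped to zero with the excess transferred to the adjacent branch of
#' the join (preserving the pair distance).
#'
#' @param d symmetric distance matrix with sample ids as dimnames; at
#'   least 3 taxa (4 or more for a resolved unrooted topology).
#' @return An unrooted `phylo` tree (from \pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node carries its Newick subtree string
  nwk <- labels
  D <- d
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest index pair among minima: scan column-major over i < j
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (j in 2:nn) for (i in 1:(j - 1)) {
      if (Q[i, j] < qmin - 1e-12) {
        qmin <- Q[i, j]
        best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    D <- D2
  }
  # final three-node star with closed-form branch lengths
  l1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(l1), nwk[2], fmt(l2),
                 nwk[3], fmt(l3))
  ape::read.tree(text = txt)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalised
#' as the sorted labels of the side not containing the alphabetically first
#' leaf, pasted with `"|"`. Trivial splits (single leaf) are dropped.
#'
#' @param tree a `phylo` object.
#' @return Character vector of canonical split strings (unique).
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  ref <- sort(tips)[1]
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tips[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= n) next                     # trivial split
    side <- sets[[ch]]
    if (length(side) >= n - 1L) next      # trivial complement
    if (ref %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' trees; 0 means identical unrooted topology.
#'
#' @param tree_a,tree_b `phylo` objects over the same leaf set.
#' @return Integer count.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees have different leaf sets")
  }
  a <- tree_bipartitions(tree_a)
  b <- tree_bipartitions(tree_b)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples loci with replacement, rebuilds the allele-sharing
#' neighbor-joining tree per replicate, and scores each internal edge of
#' the full-data tree by the percentage of replicates containing the same
#' bipartition.
#'
#' @param m loci x samples dosage matrix.
#' @param n_replicates number of bootstrap replicates (the reference
#'   analysis used 1000).
#' @param seed integer seed.
#' @param ploidy per-locus ploidy (default all diploid).
#' @return list with `tree` (the full-data `phylo`), `support` (data.frame
#'   `split`, `percent`), and `n_replicates`.
#' @export
bootstrap_support <- function(m, n_replicates = 1000, seed = 1L,
                              ploidy = rep(2L, nrow(m))) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  poly <- apply(m, 1, function(x) {
    v <- var(x, na.rm = TRUE)
    !is.na(v) && v > 0
  })
  if (!any(poly)) stop("no variable loci")
  tree <- neighbor_joining(allele_sharing_distance(m, ploidy))
  splits <- tree_bipartitions(tree)
  hits <- setNames(numeric(length(splits)), splits)
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    rep_tree <- neighbor_joining(
      allele_sharing_distance(m[idx, , drop = FALSE], ploidy[idx]))
    rep_splits <- tree_bipartitions(rep_tree)
    found <- splits %in% rep_splits
    hits[found] <- hits[found] + 1
  }
  list(tree = tree,
       support = data.frame(split = splits,
                            percent = 100 * hits / n_replicates,
                            row.names = NULL, stringsAsFactors = FALSE),
       n_replicates = n_replicates)
}

#' Is a set of leaves monophyletic in an unrooted tree?
#'
#' True when the leaf set (or its complement) forms one of the tree's
#' bipartitions, i.e. the group can be separated from everything else by
#' cutting a single edge. Groups of one leaf or all leaves are trivially
#' monophyletic.
#'
#' @param tree a `phylo` object.
#' @param leaves character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic_group <- function(tree, leaves) {
  tips <- tree$tip.label
  if (!all(leaves %in% tips)) stop("unknown leaves")
  k <- length(unique(leaves))
  if (k <= 1L || k >= length(tips) - 1L) return(TRUE)
  ref <- sort(tips)[1]
  side <- if (ref %in% leaves) setdiff(tips, leaves) else leaves
  paste(sort(side), collapse = "|") %in% tree_bipartitions(tree)
}
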