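#' Locus universe for the genotyping-error simulation
#'
#' The error-free baseline uses only loci where every target sample has a
#' call in both the array and the sequence matrix and the two calls agree
#' (missing calls and array/sequence disagreements are excluded).
#'
#' @param matrix_array,matrix_sequence loci x samples dosage matrices
#'   sharing dimnames.
#' @param target_samples sample ids the errors will be injected into.
#' @return Character vector of locus ids.
#' @export
build_error_universe <- function(matrix_array, matrix_sequence,
                                 target_samples) {
  if (!identical(dimnames(matrix_array), dimnames(matrix_sequence))) {
    stop("matrices must share locus and sample indices")
  }
  if (!all(target_samples %in% colnames(matrix_array))) {
    stop("unknown target sample")
  }
  a <- matrix_array[, target_samples, drop = FALSE]
  s <- matrix_sequence[, target_samples, drop = FALSE]
  ok <- !is.na(a) & !is.na(s) & a == s
  universe <- rownames(matrix_array)[rowSums(ok) == length(target_samples)]
  if (!length(universe)) stop("empty error universe")
  universe
}

#' Inject genotyping errors into designated samples
#'
#' Per target sample, exactly `floor(rate x |universe|)` loci are sampled
#' without replacement (independently per sample) and flipped: a
#' heterozygous call becomes a homozygote (reference or alternate with
#' equal probability), and a homozygous call becomes heterozygous. Only
#' target samples are touched; every change is recorded in the flip log.
#'
#' @param m loci x samples dosage matrix (diploid loci).
#' @param target_samples sample ids to perturb.
#' @param rate error rate in `[0, 1]` (the reference study used 0, 0.03,
#'   0.05).
#' @param universe locus ids eligible for flipping (see
#'   [build_error_universe()]); defaults to all loci.
#' @param seed integer seed.
#' @param shared_loci draw one shared error-locus set for all targets
#'   instead of independent draws (default `FALSE`).
#' @return list with `matrix` (perturbed copy) and `flips` (data.frame
#'   `sample_id`, `locus_id`, `from`, `to`).
#' @export
inject_errors <- function(m, target_samples, rate, universe = rownames(m),
                          seed = 1L, shared_loci = FALSE) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!all(target_samples %in% colnames(m))) stop("unknown target sample")
  if (!all(universe %in% rownames(m))) stop("universe loci absent from matrix")
  n_flip <- floor(rate * length(universe))
  if (n_flip > length(universe)) stop("flip count exceeds universe size")
  set.seed(seed)
  out <- m
  logs <- list()
  shared <- if (shared_loci && n_flip > 0) sample(universe, n_flip) else NULL
  for (s in target_samples) {
    if (n_flip == 0) next
    loci <- if (shared_loci) shared else sample(universe, n_flip)
    old <- out[loci, s]
    hom_dir <- sample(c(0L, 2L), n_flip, replace = TRUE)
    new <- ifelse(is.na(old), NA_integer_,
                  ifelse(old == 1L, hom_dir, 1L))
    out[loci, s] <- new
    logs[[s]] <- data.frame(sample_id = s, locus_id = loci, from = old,
                            to = new, stringsAsFactors = FALSE)
  }
  flips <- if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE))
           else data.frame(sample_id = character(), locus_id = character(),
                           from = integer(), to = integer(),
                           stringsAsFactors = FALSE)
  list(matrix = out, flips = flips)
}

#' Stability of PCA and phylogeny under injected genotyping errors
#'
#' Quantifies how much the population analyses move when errors are
#' injected: (a) the Robinson-Foulds distance between the baseline and
#' perturbed neighbor-joining trees, (b) whether each target sample's
#' nearest group centroid in PC1-PC3 is unchanged, and (c) the maximum
#' displacement of the targets in PC space, normalised by the mean
#' between-group centroid distance. Perturbed genotypes are projected onto
#' the baseline PCA basis so both analyses share one coordinate system
#' (rate 0 therefore gives exactly zero displacement and RF = 0).
#'
#' @param m_baseline,m_perturbed loci x samples dosage matrices sharing
#'   dimnames.
#' @param target_samples perturbed sample ids.
#' @param samples sample table with `sample_id` and `group`; group
#'   centroids are computed from non-target samples with groups in
#'   `centroid_groups`.
#' @param centroid_groups group labels defining centroids (default
#'   `c("1","2","3")`).
#' @param n_pc number of leading components used (default 3).
#' @return list with `rf`, `assignments` (data.frame `sample_id`,
#'   `baseline_group`, `perturbed_group`, `unchanged`), `max_displacement`
#'   (normalised), and the two trees.
#' @export
stability_report <- function(m_baseline, m_perturbed, target_samples,
                             samples, centroid_groups = c("1", "2", "3"),
                             n_pc = 3) {
  if (!identical(dimnames(m_baseline), dimnames(m_perturbed))) {
    stop("baseline and perturbed matrices must share dimnames")
  }
  base_tree <- neighbor_joining(allele_sharing_distance(m_baseline))
  pert_tree <- neighbor_joining(allele_sharing_distance(m_perturbed))
  rf <- rf_distance(base_tree, pert_tree)

  fit <- genotype_pca(m_baseline)
  n_pc <- min(n_pc, ncol(fit$scores))
  base_sc <- fit$scores[, seq_len(n_pc), drop = FALSE]
  pert_sc <- project_pca(fit, m_perturbed)[, seq_len(n_pc), drop = FALSE]

  grp <- samples$group[match(rownames(base_sc), samples$sample_id)]
  anchor <- !is.na(grp) & grp %in% centroid_groups &
    !rownames(base_sc) %in% target_samples
  cent <- do.call(rbind, lapply(centroid_groups, function(g) {
    colMeans(base_sc[anchor & grp == g, , drop = FALSE])
  }))
  rownames(cent) <- centroid_groups
  nearest <- function(x) {
    centroid_groups[which.min(colSums((t(cent) - x)^2))]
  }
  between <- as.matrix(dist(cent))
  norm_scale <- mean(between[upper.tri(between)])

  assignments <- do.call(rbind, lapply(target_samples, function(s) {
    data.frame(sample_id = s,
               baseline_group = nearest(base_sc[s, ]),
               perturbed_group = nearest(pert_sc[s, ]),
               stringsAsFactors = FALSE)
  }))
  assignments$unchanged <-
    assignments$baseline_group == assignments$perturbed_group
  disp <- vapply(target_samples, function(s) {
    sqrt(sum((pert_sc[s, ] - base_sc[s, ])^2))
  }, numeric(1))
  list(rf = rf, assignments = assignments,
       max_displacement = max(disp) / norm_scale,
       baseline_tree = base_tree, perturbed_tree = pert_tree)
}
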