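#' Percent heterozygosity of one sample
#'
#' 100 x (heterozygous calls) / (called loci), over diploid loci only;
#' missing calls are excluded from the denominator and haploid loci are
#' excluded entirely.
#'
#' @param m loci x samples dosage matrix.
#' @param sample_id sample to summarise.
#' @param ploidy per-locus ploidy vector (default all diploid).
#' @return Percent heterozygosity (numeric scalar).
#' @export
heterozygosity <- function(m, sample_id, ploidy = rep(2L, nrow(m))) {
  if (!sample_id %in% colnames(m)) stop("sample not present: ", sample_id)
  x <- m[ploidy == 2L, sample_id]
  called <- !is.na(x)
  if (!any(called)) stop("zero called loci for sample ", sample_id)
  100 * sum(x[called] == 1L) / sum(called)
}

#' Percent concordance between two call vectors
#'
#' 100 x (jointly-called loci with equal calls) / (jointly-called loci);
#' loci with a NoCall in either vector are excluded from the calculation.
#'
#' @param calls_a,calls_b dosage vectors over the same locus index.
#' @return Percent concordance (numeric scalar).
#' @export
concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors must share a locus index")
  }
  both <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(both)) stop("zero jointly-called loci")
  100 * sum(calls_a[both] == calls_b[both]) / sum(both)
}

#' Percent identity within clonal groups
#'
#' Computes all pairwise concordances within each clone group (a source
#' sample plus every sample whose `clone_of` chain leads to it) and reports
#' the minimum, maximum, and mean percent identity per group, optionally
#' restricted to a locus subset (e.g. PHR loci). Singleton groups are
#' skipped with a warning.
#'
#' @param m loci x samples dosage matrix.
#' @param samples sample table with `sample_id`, `role`, `clone_of`.
#' @param loci optional locus ids to restrict to.
#' @return list with `groups` (data.frame: `group`, `n_samples`, `n_pairs`,
#'   `min_identity`, `max_identity`, `mean_identity`) and `pairs`
#'   (data.frame of every pairwise comparison).
#' @export
clonal_identity_report <- function(m, samples, loci = NULL) {
  if (!is.null(loci)) m <- m[loci, , drop = FALSE]
  root_of <- function(id) {
    while (TRUE) {
      src <- samples$clone_of[samples$sample_id == id]
      if (length(src) != 1L || is.na(src)) return(id)
      id <- src
    }
  }
  members <- samples$sample_id[samples$role == "clone" |
                                 samples$sample_id %in% samples$clone_of]
  members <- members[members %in% colnames(m)]
  if (!length(members)) stop("no clone groups defined")
  key <- vapply(members, root_of, "")
  grp_rows <- list()
  pair_rows <- list()
  for (g in unique(key)) {
    ids <- members[key == g]
    if (length(ids) < 2L) {
      warning("singleton clone group skipped: ", g)
      next
    }
    cmb <- utils::combn(ids, 2)
    vals <- apply(cmb, 2, function(p) concordance(m[, p[1]], m[, p[2]]))
    pair_rows[[g]] <- data.frame(group = g, sample_a = cmb[1, ],
                                 sample_b = cmb[2, ], identity = vals,
                                 stringsAsFactors = FALSE)
    grp_rows[[g]] <- data.frame(group = g, n_samples = length(ids),
                                n_pairs = ncol(cmb),
                                min_identity = min(vals),
                                max_identity = max(vals),
                                mean_identity = mean(vals),
                                stringsAsFactors = FALSE)
  }
  if (!length(grp_rows)) stop("no clone group with two or more members")
  list(groups = do.call(rbind, c(grp_rows, make.row.names = FALSE)),
       pairs = do.call(rbind, c(pair_rows, make.row.names = FALSE)))
}
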